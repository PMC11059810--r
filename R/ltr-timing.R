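# Kimura two-parameter dating of LTR retrotransposon insertions.  The two
# long terminal repeats of an element are identical at insertion and
# diverge independently afterwards, so the element's age is T = K / (2 mu)
# for K2P distance K between the paired LTRs and per-site per-year
# substitution rate mu.

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing a gap or ambiguity character in either sequence are
#' excluded pairwise.  With transition fraction `P` and transversion
#' fraction `Q` over the remaining columns,
#' `K = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`.  When the logarithm's
#' argument is non-positive the distance is saturated and an error of class
#' `discordia_saturation` is thrown.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings (case-insensitive).
#' @return The K2P distance, with attributes `P`, `Q` and `n_sites`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length", call. = FALSE)
  ok <- a %in% names(TRANSITION) & b %in% names(TRANSITION)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 1) stop("no comparable (ungapped, unambiguous) sites",
                  call. = FALSE)
  diff <- a != b
  ts <- diff & TRANSITION[a] == b
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("discordia_saturation", "error", "condition"),
                   list(message = "K2P distance is saturated",
                        call = sys.call(-1))))
  K <- -0.5 * log(w1 * sqrt(w2))
  attr(K, "P") <- P
  attr(K, "Q") <- Q
  attr(K, "n_sites") <- n
  K
}

#' LTR insertion time from K2P divergence
#'
#' @param K K2P distance between the paired LTRs.
#' @param mu Substitution rate per site per year (> 0).  No default: the
#'   rate is lineage-specific and must be chosen by the user (plant LTR
#'   studies commonly use values around 1e-8).
#' @return Insertion time in years, `K / (2 * mu)`.
#' @export
insertion_time <- function(K, mu) {
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  as.numeric(K) / (2 * mu)
}

#' Read paired LTR sequences from FASTA
#'
#' Sequence ids carry `/5` and `/3` suffixes marking the two long terminal
#' repeats of an element.
#'
#' @param path FASTA path.
#' @return Data frame with `element`, `ltr5`, `ltr3` (as strings).
#' @export
read_ltr_pairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  side <- sub("^.*/", "", ids)
  elem <- sub("/[53]$", "", ids)
  if (!all(side %in% c("5", "3")))
    stop("every sequence id must end in /5 or /3", call. = FALSE)
  e5 <- elem[side == "5"]
  e3 <- elem[side == "3"]
  if (!setequal(e5, e3) || anyDuplicated(e5) || anyDuplicated(e3))
    stop("unpaired LTR sequences in ", path, call. = FALSE)
  s5 <- as.character(seqs[side == "5"])
  s3 <- as.character(seqs[side == "3"])
  data.frame(element = e5, ltr5 = unname(s5),
             ltr3 = unname(s3[match(e5, e3)]), stringsAsFactors = FALSE)
}

#' Date a cohort of LTR elements
#'
#' Computes the K2P distance between each element's paired LTRs and the
#' implied insertion time.  Saturated elements are flagged and carry `NA`
#' estimates rather than stopping the run.
#'
#' @param pairs Data frame with `element`, `ltr5`, `ltr3` (e.g. from
#'   [read_ltr_pairs()]), optionally a `superfamily` column.
#' @param mu Substitution rate per site per year.
#' @return Data frame with `element`, `superfamily`, `P`, `Q`, `K`, `T`
#'   (years) and `saturated`.
#' @export
ltr_insertion_times <- function(pairs, mu) {
  stopifnot(nrow(pairs) >= 1)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  sf <- if ("superfamily" %in% names(pairs)) pairs$superfamily
        else rep("unknown", nrow(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    K <- tryCatch(k2p_distance(pairs$ltr5[i], pairs$ltr3[i]),
                  discordia_saturation = function(e) NA_real_)
    data.frame(element = pairs$element[i], superfamily = sf[i],
               P = attr(K, "P") %||% NA_real_,
               Q = attr(K, "Q") %||% NA_real_,
               K = as.numeric(K),
               T = if (is.na(K)) NA_real_ else insertion_time(K, mu),
               saturated = is.na(K), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Insertion-time density profile per superfamily
#'
#' Kernel density (and histogram counts) of insertion times per
#' superfamily, with modes picked as local maxima of the density whose
#' height reaches at least 20% of the global maximum.  Densities integrate
#' to one per superfamily; a superfamily with a single dated element is
#' reported as a degenerate spike at its time.
#'
#' @param dated Data frame from [ltr_insertion_times()] (saturated elements
#'   are dropped).
#' @param bandwidth Optional kernel bandwidth in years (default
#'   `stats::bw.nrd0`).
#' @param n_breaks Number of histogram bins.
#' @return Named list per superfamily: `n`, `modes` (years), `density`
#'   (data frame `x`, `y`) and `histogram`.
#' @export
timing_profile <- function(dated, bandwidth = NULL, n_breaks = 30) {
  ok <- dated[!dated$saturated & !is.na(dated$T), , drop = FALSE]
  if (!nrow(ok)) stop("all elements are saturated; nothing to profile",
                      call. = FALSE)
  lapply(split(ok$T, ok$superfamily), function(times) {
    if (length(times) == 1L) {
      return(list(n = 1L, modes = times,
                  density = data.frame(x = times, y = Inf),
                  histogram = NULL, degenerate = TRUE))
    }
    d <- if (is.null(bandwidth)) stats::density(times)
         else stats::density(times, bw = bandwidth)
    peak <- which(d$y > c(-Inf, d$y[-length(d$y)]) &
                    d$y >= c(d$y[-1], -Inf) &
                    d$y >= 0.2 * max(d$y))
    h <- graphics::hist(times, breaks = n_breaks, plot = FALSE)
    list(n = length(times), modes = d$x[peak],
         density = data.frame(x = d$x, y = d$y),
         histogram = data.frame(mid = h$mids, density = h$density),
         degenerate = FALSE)
  })
}

# Evolve one sequence for `time` years under the K2P substitution process.
# `mu` is the total substitution rate per site per year; `ti_tv_ratio` is
# the expected transition:transversion count ratio (kappa/2 in rate terms),
# so equal per-type rates give 0.5 and twice as many transversions.
evolve_k2p <- function(seq_chars, time, mu, ti_tv_ratio) {
  R <- ti_tv_ratio
  alpha <- mu * R / (1 + R)        # transition rate
  beta <- mu / (2 * (1 + R))       # rate per transversion target
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * time) -
    0.5 * exp(-2 * (alpha + beta) * time)
  p_tv <- 2 * (0.25 - 0.25 * exp(-4 * beta * time))
  n <- length(seq_chars)
  u <- stats::runif(n)
  out <- seq_chars
  ts_idx <- which(u < p_ts)
  out[ts_idx] <- TRANSITION[seq_chars[ts_idx]]
  tv_idx <- which(u >= p_ts & u < p_ts + p_tv)
  if (length(tv_idx)) {
    tv_targets <- rbind(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
    pick <- sample.int(2L, length(tv_idx), replace = TRUE)
    rows <- match(seq_chars[tv_idx], rownames(tv_targets))
    out[tv_idx] <- tv_targets[cbind(rows, pick)]
  }
  out
}

#' Generate a diverged LTR pair with known insertion time
#'
#' Draws a random ancestral sequence and mutates two copies independently
#' for `true_time` years under a Kimura two-parameter process with total
#' rate `mu` per site per year, emulating the post-insertion divergence of
#' an element's paired LTRs.  The expected K2P distance between the copies
#' is `2 * mu * true_time`, so [insertion_time()] recovers `true_time` on
#' average.
#'
#' @param length Sequence length in bp (>= 100).
#' @param true_time Insertion age in years (>= 0).
#' @param mu Substitution rate per site per year (> 0).
#' @param ti_tv_ratio Expected transition:transversion count ratio (0.5 =
#'   equal per-type rates; default 2, a typical nuclear value).
#' @param seed Integer seed or `NULL`.
#' @return List with `ltr5`, `ltr3` (strings), `true_time` and `ancestral`.
#' @export
mutate_ltr_pair <- function(length, true_time, mu, ti_tv_ratio = 2,
                            seed = NULL) {
  stopifnot(length >= 100, true_time >= 0, ti_tv_ratio > 0)
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  with_seed(seed, {
    anc <- sample(names(TRANSITION), length, replace = TRUE)
    list(ltr5 = paste(evolve_k2p(anc, true_time, mu, ti_tv_ratio),
                      collapse = ""),
         ltr3 = paste(evolve_k2p(anc, true_time, mu, ti_tv_ratio),
                      collapse = ""),
         true_time = true_time,
         ancestral = paste(anc, collapse = ""))
  })
}
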