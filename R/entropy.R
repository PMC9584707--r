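#' Entropy estimator configuration
#'
#' Bundles the parameters of the multivariate multiscale modified
#' distribution entropy. Defaults are the configuration used for EEG
#' analysis: embedding dimension m = 3, delay tau = 1, fuzzy tolerance
#' r = 0.2 x signal SD, fuzzy exponent n = 2, 64 histogram bins, scales
#' 1 through 15.
#'
#' @param m Embedding dimension (positive integer). Each composite vector
#'   holds `m` samples per channel.
#' @param tau Time delay between embedded samples (positive integer).
#' @param r_coeff Tolerance coefficient; the fuzzy tolerance is
#'   `r = r_coeff * sd(coarse-grained data)`. Must be > 0.
#' @param n Fuzzy exponent (> 0). Larger n sharpens the similarity cutoff
#'   around r; smaller n softens it.
#' @param B Number of equal-width histogram bins over the similarity
#'   codomain \[0, 1\] (integer >= 2).
#' @param scales Integer vector of coarse-graining scale factors.
#' @param metric Vector-pair distance: `"chebyshev"` (max coordinate
#'   difference, the distribution-entropy convention) or `"euclidean"`.
#' @param sd_pooling `"pooled"` computes one SD over the whole
#'   coarse-grained matrix (all channels); `"per_channel"` averages
#'   per-channel SDs. Population convention (divide by count) either way.
#'
#' @return A list of class `"entropy_config"`.
#' @examples
#' entropy_config()
#' entropy_config(scales = 1:5, B = 32)
#' @export
entropy_config <- function(m = 3L, tau = 1L, r_coeff = 0.2, n = 2,
                           B = 64L, scales = 1:15,
                           metric = c("chebyshev", "euclidean"),
                           sd_pooling = c("pooled", "per_channel")) {
  metric <- match.arg(metric)
  sd_pooling <- match.arg(sd_pooling)
  m <- as.integer(m); tau <- as.integer(tau); B <- as.integer(B)
  scales <- as.integer(scales)
  if (m < 1L) stop("entropy_config: m must be a positive integer", call. = FALSE)
  if (tau < 1L) stop("entropy_config: tau must be a positive integer", call. = FALSE)
  if (!is.finite(r_coeff) || r_coeff <= 0) stop("entropy_config: r_coeff must be > 0", call. = FALSE)
  if (!is.finite(n) || n <= 0) stop("entropy_config: n must be > 0", call. = FALSE)
  if (B < 2L) stop("entropy_config: B must be >= 2", call. = FALSE)
  if (length(scales) < 1L || any(scales < 1L)) {
    stop("entropy_config: scales must be positive integers", call. = FALSE)
  }
  structure(list(m = m, tau = tau, r_coeff = r_coeff, n = n, B = B,
                 scales = scales, metric = metric, sd_pooling = sd_pooling),
            class = "entropy_config")
}

#' @export
print.entropy_config <- function(x, ...) {
  cat(sprintf("<entropy_config> m=%d tau=%d r_coeff=%g n=%g B=%d scales=%s metric=%s sd=%s\n",
              x$m, x$tau, x$r_coeff, x$n, x$B,
              paste(range(x$scales), collapse = ".."), x$metric, x$sd_pooling))
  invisible(x)
}

# smallest sample count a signal needs so that scale s leaves >= 2 vectors
min_samples_for <- function(cfg, s) {
  s * ((cfg$m - 1L) * cfg$tau + 2L)
}

check_scale_feasible <- function(N, cfg, s) {
  Ns <- N %/% s
  V <- Ns - (cfg$m - 1L) * cfg$tau
  if (V < 2L) {
    stop(sprintf(
      "scale %d infeasible: floor(%d/%d) - (%d-1)*%d = %d embedded vectors (need >= 2)",
      s, N, s, cfg$m, cfg$tau, V), call. = FALSE)
  }
  invisible(V)
}

#' Coarse-grain a multichannel signal
#'
#' Replaces each channel by the means of non-overlapping windows of width
#' `s` (scale factor). The trailing `N mod s` samples are discarded, so the
#' output has `floor(N / s)` samples per channel. `s = 1` is the identity.
#'
#' @param x A [multichannel_signal()].
#' @param s Scale factor (positive integer, at most `N / 2`).
#' @return A [multichannel_signal()] of `floor(N/s)` samples per channel,
#'   with attribute `scale = s`.
#' @examples
#' coarse_grain(multichannel_signal(c(1, 2, 3, 4, 5, 6)), 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, s) {
  stopifnot(is_multichannel_signal(x))
  s <- as.integer(s)
  N <- ncol(x)
  if (s < 1L) stop("coarse_grain: scale must be >= 1", call. = FALSE)
  Ns <- N %/% s
  if (Ns < 2L) stop("coarse_grain: scale ", s, " leaves fewer than 2 samples", call. = FALSE)
  if (s == 1L) {
    out <- x
  } else {
    kept <- unclass(x)[, seq_len(Ns * s), drop = FALSE]
    # window means: fold each row into an s x Ns block and column-average
    out <- t(apply(kept, 1, function(row) colMeans(matrix(row, nrow = s))))
    out <- multichannel_signal(out, sample_rate = attr(x, "sample_rate"),
                               channel_names = rownames(x))
  }
  attr(out, "scale") <- s
  out
}

#' Delay-embed a signal into composite phase-space vectors
#'
#' Builds the phase-space reconstruction: vector `j` concatenates, channel
#' by channel, the `m` samples `x[c, j], x[c, j + tau], ...,
#' x[c, j + (m-1) tau]`. All channels share one time index, so each of the
#' `V = N - (m-1) tau` rows is a single `(channels * m)`-dimensional state
#' of the whole recording. `m` and `tau` are uniform across channels.
#'
#' @param x A [multichannel_signal()] (typically coarse-grained).
#' @param m Embedding dimension.
#' @param tau Time delay.
#' @return A `V x (channels * m)` numeric matrix, channel-major columns.
#' @examples
#' phase_space(multichannel_signal(c(1, 2, 3, 4)), m = 2, tau = 1)
#' @export
phase_space <- function(x, m, tau) {
  stopifnot(is_multichannel_signal(x))
  m <- as.integer(m); tau <- as.integer(tau)
  Ns <- ncol(x)
  V <- Ns - (m - 1L) * tau
  if (V < 2L) {
    stop(sprintf("phase_space: %d samples with m=%d, tau=%d give %d vectors (need >= 2)",
                 Ns, m, tau, V), call. = FALSE)
  }
  xm <- unclass(x)
  cols <- vector("list", nrow(xm) * m)
  k <- 1L
  for (ch in seq_len(nrow(xm))) {
    for (d in seq_len(m)) {
      start <- (d - 1L) * tau + 1L
      cols[[k]] <- xm[ch, start:(start + V - 1L)]
      k <- k + 1L
    }
  }
  do.call(cbind, cols)
}

#' Pairwise distances between composite vectors
#'
#' Distances between all distinct pairs of phase-space vectors (upper
#' triangle; self-distances excluded). Chebyshev (maximum coordinate
#' difference) is the default, following the distribution-entropy
#' convention.
#'
#' @param ps A phase-space matrix from [phase_space()].
#' @param metric `"chebyshev"` or `"euclidean"`.
#' @return Numeric vector of `V (V - 1) / 2` non-negative distances.
#' @export
pairwise_distances <- function(ps, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(ps) < 2L) stop("pairwise_distances: need >= 2 vectors", call. = FALSE)
  method <- if (metric == "chebyshev") "maximum" else "euclidean"
  as.numeric(stats::dist(ps, method = method))
}

#' Fuzzy exponential similarity
#'
#' Maps each distance `d` to the membership degree
#' `mu = exp(-(d / r)^n)`, a similarity in (0, 1]: 1 for identical vectors,
#' decaying monotonically with distance. `r` sets the breadth of the fuzzy
#' exponential and `n` its step (steepness).
#'
#' @param d Non-negative distances.
#' @param r Tolerance (> 0), typically `r_coeff * sd(signal)`.
#' @param n Exponent (> 0).
#' @return Similarities in (0, 1], same length as `d`.
#' @examples
#' fuzzy_similarity(c(0, 1), r = 1, n = 2)  # 1, exp(-1)
#' @export
fuzzy_similarity <- function(d, r, n) {
  if (!is.finite(r) || r <= 0) stop("fuzzy_similarity: r must be > 0", call. = FALSE)
  if (!is.finite(n) || n <= 0) stop("fuzzy_similarity: n must be > 0", call. = FALSE)
  if (any(d < 0)) stop("fuzzy_similarity: distances must be >= 0", call. = FALSE)
  exp(-(d / r)^n)
}

#' Empirical probability density over [0, 1]
#'
#' Histograms values into `B` equal-width bins spanning the fixed interval
#' \[0, 1\] and normalizes the counts to probabilities. The fixed support
#' (not a data-dependent range) is what makes the entropy amplitude-scale
#' invariant. Values on an interior bin edge go to the higher bin; 1.0
#' falls in the last bin.
#'
#' @param values Numeric values in \[0, 1\] (typically fuzzy similarities).
#' @param B Number of bins (>= 2).
#' @return Probability vector of length `B` summing to 1.
#' @examples
#' empirical_pdf(c(0.1, 0.9), B = 2)  # 0.5 0.5
#' @export
empirical_pdf <- function(values, B) {
  B <- as.integer(B)
  if (length(values) < 1L) stop("empirical_pdf: need at least one value", call. = FALSE)
  if (B < 2L) stop("empirical_pdf: B must be >= 2", call. = FALSE)
  if (any(values < 0 | values > 1)) {
    stop("empirical_pdf: values must lie in [0, 1]", call. = FALSE)
  }
  idx <- pmin(floor(values * B) + 1L, B)
  p <- tabulate(idx, nbins = B) / length(values)
  p
}

shannon_bits <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

# population SD of the coarse-grained data, per the configured pooling
tolerance_r <- function(cg, cfg) {
  m <- unclass(cg)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sdv <- switch(cfg$sd_pooling,
                pooled = pop_sd(as.numeric(m)),
                per_channel = mean(apply(m, 1, pop_sd)))
  r <- cfg$r_coeff * sdv
  if (!is.finite(r) || r <= 0) {
    stop("degenerate input: zero-variance signal gives tolerance r = 0",
         call. = FALSE)
  }
  r
}

#' Multivariate multiscale modified distribution entropy at one scale
#'
#' The full estimator for a single scale factor: coarse-grain, delay-embed
#' all channels into composite vectors, take all pairwise distances, map
#' them through the fuzzy exponential similarity with tolerance
#' `r = r_coeff * SD(coarse-grained data)`, histogram the similarities into
#' `B` bins over \[0, 1\], and return the Shannon entropy of that
#' distribution normalized by `log2(B)`. The result is dimensionless and
#' lies in \[0, 1\]: higher values mean the similarity mass is spread over
#' more histogram bins, i.e. the signal's phase-space trajectory shows a
#' richer mix of near- and partial recurrences at the tolerance `r`.
#'
#' @param x A [multichannel_signal()].
#' @param s Scale factor (default 1).
#' @param config An [entropy_config()].
#' @return A single entropy value in \[0, 1\].
#' @examples
#' set.seed(1)
#' x <- multichannel_signal(rnorm(400))
#' mm_mdisten(x, s = 1)
#' @export
mm_mdisten <- function(x, s = 1L, config = entropy_config()) {
  stopifnot(is_multichannel_signal(x), inherits(config, "entropy_config"))
  check_scale_feasible(ncol(x), config, as.integer(s))
  cg <- coarse_grain(x, s)
  r <- tolerance_r(cg, config)
  ps <- phase_space(cg, config$m, config$tau)
  d <- pairwise_distances(ps, config$metric)
  mu <- fuzzy_similarity(d, r, config$n)
  p <- empirical_pdf(mu, config$B)
  shannon_bits(p) / log2(config$B)
}

#' Entropy profile across scales
#'
#' Computes [mm_mdisten()] at every scale in the configuration, yielding
#' the per-recording feature vector: one entropy value per coarse-graining
#' scale.
#'
#' @inheritParams mm_mdisten
#' @return A tibble of class `"entropy_profile"` with columns `scale`
#'   (integer) and `entropy` (double in \[0, 1\]), one row per scale, and
#'   the configuration stored in attribute `"config"`.
#' @examples
#' set.seed(1)
#' x <- multichannel_signal(matrix(rnorm(2 * 400), nrow = 2))
#' entropy_profile(x, entropy_config(scales = 1:5))
#' @export
entropy_profile <- function(x, config = entropy_config()) {
  stopifnot(is_multichannel_signal(x), inherits(config, "entropy_config"))
  for (s in config$scales) check_scale_feasible(ncol(x), config, s)
  out <- tibble::tibble(
    scale = config$scales,
    entropy = vapply(config$scales, function(s) mm_mdisten(x, s, config), numeric(1))
  )
  attr(out, "config") <- config
  class(out) <- c("entropy_profile", class(out))
  out
}

#' Write an entropy profile as CSV
#'
#' @param profile An [entropy_profile()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile[c("scale", "entropy")]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
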