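#' Generate a synthetic test series
#'
#' Seeded generators for the signal kinds used to validate the entropy
#' estimator: Gaussian white noise, 1/f (pink) noise, the chaotic logistic
#' map, and a sinusoid. Each channel is drawn independently (sinusoid
#' channels get independent random phases). Identical arguments always
#' produce an identical signal.
#'
#' @param kind One of `"gaussian_white"`, `"pink_1overf"`,
#'   `"logistic_chaotic"`, `"sinusoid"`.
#' @param n_samples Samples per channel (default 400, the length used for
#'   parameter-selection simulations).
#' @param n_channels Number of channels (default 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param sample_rate Sampling rate in Hz attached as metadata (default 128).
#' @param sd Standard deviation of Gaussian / pink noise (default 1).
#' @param rho Logistic-map growth rate (default 4, fully chaotic regime).
#' @param freq Sinusoid frequency in Hz (default 10).
#' @param amplitude Sinusoid amplitude (default 1).
#' @param phase Sinusoid phase in radians, or `NULL` to draw one uniformly
#'   per channel.
#' @param pink_exponent Spectral exponent of pink noise (power ~ 1/f^a,
#'   default a = 1).
#'
#' @return A [multichannel_signal()], `n_channels x n_samples`.
#' @examples
#' generate_series("logistic_chaotic", n_samples = 400, seed = 7)
#' generate_series("sinusoid", n_channels = 2, seed = 1, freq = 8)
#' @export
generate_series <- function(kind, n_samples = 400L, n_channels = 1L, seed = 1L,
                            sample_rate = 128, sd = 1, rho = 4,
                            freq = 10, amplitude = 1, phase = NULL,
                            pink_exponent = 1) {
  kinds <- c("gaussian_white", "pink_1overf", "logistic_chaotic", "sinusoid")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop("generate_series: kind must be one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  n_channels <- as.integer(n_channels)
  stopifnot(n_samples >= 2L, n_channels >= 1L)
  data <- withr::with_seed(as.integer(seed), {
    switch(kind,
      gaussian_white = matrix(stats::rnorm(n_channels * n_samples, sd = sd),
                              nrow = n_channels),
      pink_1overf = t(vapply(seq_len(n_channels),
                             function(i) pink_noise(n_samples, sd, pink_exponent),
                             numeric(n_samples))),
      logistic_chaotic = t(vapply(seq_len(n_channels),
                                  function(i) logistic_orbit(n_samples, rho),
                                  numeric(n_samples))),
      sinusoid = {
        tt <- (seq_len(n_samples) - 1L) / sample_rate
        t(vapply(seq_len(n_channels), function(i) {
          ph <- if (is.null(phase)) stats::runif(1, 0, 2 * pi) else phase
          amplitude * sin(2 * pi * freq * tt + ph)
        }, numeric(n_samples)))
      })
  })
  multichannel_signal(data, sample_rate = sample_rate)
}

# logistic map x_{t+1} = rho x_t (1 - x_t), 100-iteration burn-in;
# initial conditions whose orbit collapses onto a fixed point are redrawn
logistic_orbit <- function(n, rho, burn_in = 100L, max_tries = 50L) {
  fixed <- c(0, 1 - 1 / rho)
  for (try in seq_len(max_tries)) {
    x <- stats::runif(1, 0.05, 0.95)
    ok <- TRUE
    for (i in seq_len(burn_in)) {
      x <- rho * x * (1 - x)
      if (min(abs(x - fixed)) < 1e-12 || x <= 0 || x >= 1) { ok <- FALSE; break }
    }
    if (!ok) next
    out <- numeric(n)
    for (i in seq_len(n)) {
      out[i] <- x
      x <- rho * x * (1 - x)
      if (min(abs(x - fixed)) < 1e-12 || x < 0 || x > 1) { ok <- FALSE; break }
    }
    if (ok) return(out)
  }
  stop("logistic_orbit: could not find a non-degenerate orbit", call. = FALSE)
}

# 1/f^a noise via spectral shaping of white noise (FFT filter), rescaled
# to zero mean and the requested SD
pink_noise <- function(n, sd = 1, exponent = 1) {
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  k <- c(1, seq_len(n - 1))           # DC term left alone via index 1
  scale <- 1 / (pmin(k, n - k + 1))^(exponent / 2)
  scale[1] <- 0                        # drop DC: zero-mean output
  x <- Re(stats::fft(f * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sqrt(mean(x^2)) * sd
}

#' Generate a labeled two-class multichannel dataset
#'
#' Builds a balanced synthetic dataset shaped like a multi-subject emotion
#' EEG study: each subject contributes `trials_per_class` trials of each of
#' two classes whose signals differ in irregularity, plus a continuous
#' rating on a 1-9 scale that straddles the 4.5 binarization threshold.
#'
#' Trials follow a shared-source model of multichannel recordings: one
#' source waveform per trial is projected onto all channels with random
#' per-channel gains (uniform on 0.6-1.4, mimicking volume conduction)
#' and independent Gaussian sensor noise is added. Class 0 ("low") uses a
#' narrowband sinusoid source (frequency uniform on 8-12 Hz, random
#' phase); class 1 ("high") uses a broadband 1/f-noise source. The two
#' classes therefore differ sharply in recurrence structure: the periodic
#' source revisits its phase-space trajectory every cycle, spreading the
#' similarity histogram over many bins (high distribution entropy), while
#' broadband-source vectors are mostly far apart relative to the fuzzy
#' tolerance, concentrating similarity near zero (low entropy).
#' Ratings are drawn from truncated normals, N(3, 0.8) on \[1, 4.4\] for
#' class 0 and N(7, 0.8) on \[4.6, 9\] for class 1, so every rating lands
#' on the correct side of 4.5.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param trials_per_class Trials per class per subject (default 10).
#' @param n_channels Channels per trial (default 14).
#' @param n_samples Samples per trial (default 384, i.e. 3 s at 128 Hz).
#' @param sample_rate Sampling rate in Hz (default 128).
#' @param noise_sd Per-channel sensor-noise SD relative to the unit-SD
#'   source (default 0.05, i.e. 5% sensor noise on a strongly
#'   volume-conducted source).
#' @param seed Integer seed; the dataset is a pure function of its spec.
#'
#' @return A tibble with one row per trial: `subject_id`, `trial_id`,
#'   `class` (0/1), `rating` (1-9), and `signal` (list-column of
#'   [multichannel_signal()]).
#' @examples
#' ds <- generate_labeled_dataset(n_subjects = 2, trials_per_class = 3,
#'                                n_channels = 2, n_samples = 128, seed = 1)
#' table(ds$class)
#' @export
generate_labeled_dataset <- function(n_subjects = 28L, trials_per_class = 10L,
                                     n_channels = 14L, n_samples = 384L,
                                     sample_rate = 128, noise_sd = 0.05,
                                     seed = 1L) {
  stopifnot(n_subjects >= 1L, trials_per_class >= 1L,
            n_channels >= 1L, n_samples >= 2L)
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    class = c(0L, 1L),
    rep = seq_len(trials_per_class)
  )
  grid$trial_id <- sprintf("%s_c%d_t%02d", grid$subject_id, grid$class, grid$rep)
  tt <- (seq_len(n_samples) - 1L) / sample_rate
  withr::with_seed(as.integer(seed), {
    grid$rating <- vapply(grid$class, draw_rating, numeric(1))
    grid$signal <- purrr::map(grid$class, function(cls) {
      src <- if (cls == 0L) {
        sin(2 * pi * stats::runif(1, 8, 12) * tt + stats::runif(1, 0, 2 * pi))
      } else {
        pink_noise(n_samples, sd = 1)
      }
      gains <- stats::runif(n_channels, 0.6, 1.4)
      mat <- gains %o% src +
        noise_sd * matrix(stats::rnorm(n_channels * n_samples), n_channels)
      multichannel_signal(mat, sample_rate = sample_rate)
    })
  })
  grid[c("subject_id", "trial_id", "class", "rating", "signal")]
}

# truncated-normal rating strictly on one side of the 4.5 threshold
draw_rating <- function(cls) {
  if (cls == 0L) { mu <- 3; lo <- 1; hi <- 4.4 } else { mu <- 7; lo <- 4.6; hi <- 9 }
  repeat {
    r <- stats::rnorm(1, mu, 0.8)
    if (r >= lo && r <= hi) return(r)
  }
}
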