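#' Assemble a multichannel signal
#'
#' Stacks one or more equal-length real-valued series into a channels x
#' samples matrix, the container every entropy function in this package
#' operates on. Row order (channel order) is preserved.
#'
#' @param x A numeric matrix (channels x samples), a single numeric vector
#'   (one channel), or a list of equal-length numeric vectors.
#' @param sample_rate Sampling rate in Hz. Metadata only: the entropy
#'   estimator is sampling-rate agnostic.
#' @param channel_names Optional character vector of channel identifiers,
#'   one per row.
#'
#' @return A `multichannel_signal`: a numeric matrix with class
#'   `"multichannel_signal"` and attributes `sample_rate` and row names set
#'   to the channel names.
#'
#' @examples
#' multichannel_signal(list(c(1, 2, 3), c(4, 5, 6)))
#' multichannel_signal(sin(seq(0, 2 * pi, length.out = 128)), sample_rate = 128)
#' @export
multichannel_signal <- function(x, sample_rate = NA_real_, channel_names = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) {
      stop("multichannel_signal: need at least one series", call. = FALSE)
    }
    lens <- vapply(x, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("multichannel_signal: all series must have the same length (got ",
           paste(lens, collapse = ", "), ")", call. = FALSE)
    }
    x <- do.call(rbind, lapply(x, as.numeric))
  } else if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1L)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("multichannel_signal: input must be a numeric matrix, vector, or list of vectors",
         call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 2L) {
    stop("multichannel_signal: need >= 1 channel and >= 2 samples", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("multichannel_signal: values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == nrow(x))
    rownames(x) <- channel_names
  }
  structure(x, sample_rate = sample_rate, class = c("multichannel_signal", "matrix", "array"))
}

#' @export
print.multichannel_signal <- function(x, ...) {
  sr <- attr(x, "sample_rate")
  cat(sprintf("<multichannel_signal> %d channel(s) x %d samples%s\n",
              nrow(x), ncol(x),
              if (is.na(sr)) "" else sprintf(" @ %g Hz", sr)))
  invisible(x)
}

#' @rdname multichannel_signal
#' @export
is_multichannel_signal <- function(x) inherits(x, "multichannel_signal")

n_channels <- function(x) nrow(x)
n_samples <- function(x) ncol(x)

#' Read / write a channel-matrix CSV
#'
#' The interchange format is one row per channel, one column per sample.
#' A header row of channel names is optional on read and written on request.
#'
#' @param path File path.
#' @param header Whether the first CSV row holds channel names.
#' @param sample_rate Sampling rate to attach (metadata only).
#'
#' @return `read_signal_csv()` returns a [multichannel_signal()];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path, header = FALSE, sample_rate = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- as.matrix(utils::read.csv(path, header = FALSE, colClasses = "character"))
  channel_names <- NULL
  first_row <- raw[1, ][!is.na(raw[1, ]) & raw[1, ] != ""]
  first_numeric <- !anyNA(suppressWarnings(as.numeric(first_row)))
  if (header || !first_numeric) {
    # header row holds one name per channel; data rows hold N samples
    channel_names <- as.character(first_row)
    raw <- raw[-1, , drop = FALSE]
    if (length(channel_names) != nrow(raw)) channel_names <- NULL
  }
  m <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw))
  if (any(!is.finite(m))) stop("non-numeric or missing values in ", path, call. = FALSE)
  multichannel_signal(m, sample_rate = sample_rate, channel_names = channel_names)
}

#' @rdname read_signal_csv
#' @param x A [multichannel_signal()].
#' @export
write_signal_csv <- function(x, path, header = !is.null(rownames(x))) {
  stopifnot(is_multichannel_signal(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    nm <- rownames(x)
    if (is.null(nm)) nm <- paste0("ch", seq_len(nrow(x)))
    writeLines(paste(nm, collapse = ","), con)
  }
  utils::write.table(unclass(x), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
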