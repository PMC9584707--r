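#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation report
#'
#' @param x A `"cv_report"` from [cross_validate()].
#' @param ... Unused.
#' @return The per-fold tibble: fold, confusion counts, metrics.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' One-row summary of a cross-validation report
#'
#' @inheritParams tidy.cv_report
#' @return A one-row tibble with `<metric>_mean` / `<metric>_sd` for
#'   precision, recall, f1 and accuracy, plus `k`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  wide <- stats::setNames(
    as.list(c(s$mean, s$sd)),
    c(paste0(s$metric, "_mean"), paste0(s$metric, "_sd")))
  dplyr::bind_cols(tibble::as_tibble(wide), tibble::tibble(k = x$k))
}

#' Tidy a fitted network's training trace
#'
#' @param x A `"mmdisten_mlp"` from [fit_mlp()].
#' @param ... Unused.
#' @return A tibble with `epoch` and training `loss` (binary
#'   cross-entropy).
#' @method tidy mmdisten_mlp
#' @export
tidy.mmdisten_mlp <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss), loss = x$loss)
}

#' @rdname tidy.mmdisten_mlp
#' @return `glance()`: a one-row tibble with `epochs_run`, `final_loss`,
#'   `n_features`.
#' @method glance mmdisten_mlp
#' @export
glance.mmdisten_mlp <- function(x, ...) {
  tibble::tibble(epochs_run = x$epochs_run,
                 final_loss = utils::tail(x$loss, 1),
                 n_features = length(x$feature_names))
}

#' Plot an entropy profile
#'
#' Entropy against coarse-graining scale, the standard way multiscale
#' entropy curves are read.
#'
#' @param object An [entropy_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot entropy_profile
#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "scale factor", y = "MM-mDistEn",
                  title = "Multiscale entropy profile") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `"cv_report"`.
#' @param ... Unused.
#' @return A ggplot of per-fold metric values with fold-mean bars.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[c("fold", "precision", "recall", "f1", "accuracy")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
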