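#' Binarize a continuous rating
#'
#' Dichotomizes a 1-9 self-report rating at a threshold: strictly above
#' gives `"high"`, strictly below gives `"low"`. A rating exactly at the
#' threshold is assigned `"low"` (ties broken downward).
#'
#' @param score Numeric rating(s), finite.
#' @param threshold Cut point (default 4.5).
#' @return Character vector of `"low"` / `"high"`.
#' @examples
#' binarize_rating(c(7, 3, 4.5))  # "high" "low" "low"
#' @export
binarize_rating <- function(score, threshold = 4.5) {
  if (any(!is.finite(score))) {
    stop("binarize_rating: ratings must be finite", call. = FALSE)
  }
  ifelse(score > threshold, "high", "low")
}

#' Extract entropy features from a set of trials
#'
#' Computes the entropy profile of every trial and assembles the feature
#' table used for classification: one row per trial, one column per scale
#' (`s_1 ... s_k`). With a channel `groups` mapping (e.g. frontal /
#' temporal / parietal / occipital), the profile is computed independently
#' on each channel subset and columns are group-major
#' (`<group>_s_<scale>`).
#'
#' @param trials A tibble with a `signal` list-column of
#'   [multichannel_signal()] (e.g. from [generate_labeled_dataset()]), or a
#'   bare list of signals. Columns `trial_id`, `rating`, `class`,
#'   `subject_id` are carried through when present; a `label` column
#'   (`"low"`/`"high"`) is derived from `rating` when available, else from
#'   `class` (1 = high).
#' @param config An [entropy_config()].
#' @param groups Optional named list mapping group name -> channel indices
#'   (or channel names).
#' @return A tibble: id/label columns followed by numeric feature columns.
#'   Any trial whose signal fails validation aborts the run with that
#'   trial named.
#' @examples
#' ds <- generate_labeled_dataset(n_subjects = 1, trials_per_class = 2,
#'                                n_channels = 2, n_samples = 128, seed = 1)
#' extract_features(ds, entropy_config(scales = 1:3))
#' @export
extract_features <- function(trials, config = entropy_config(), groups = NULL) {
  if (is.list(trials) && !is.data.frame(trials)) {
    trials <- tibble::tibble(
      trial_id = sprintf("trial_%03d", seq_along(trials)),
      signal = trials
    )
  }
  stopifnot(is.data.frame(trials), "signal" %in% names(trials))
  if (!"trial_id" %in% names(trials)) {
    trials$trial_id <- sprintf("trial_%03d", seq_len(nrow(trials)))
  }

  one_trial <- function(sig, id) {
    tryCatch({
      if (is.null(groups)) {
        prof <- entropy_profile(sig, config)
        stats::setNames(prof$entropy, paste0("s_", prof$scale))
      } else {
        unlist(lapply(names(groups), function(g) {
          sub <- subset_channels(sig, groups[[g]])
          prof <- entropy_profile(sub, config)
          stats::setNames(prof$entropy, paste0(g, "_s_", prof$scale))
        }))
      }
    }, error = function(e) {
      stop("extract_features: trial '", id, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  feats <- purrr::map2(trials$signal, trials$trial_id, one_trial)
  fmat <- do.call(rbind, feats)

  out <- tibble::tibble(trial_id = trials$trial_id)
  for (col in c("subject_id", "rating", "class")) {
    if (col %in% names(trials)) out[[col]] <- trials[[col]]
  }
  out$label <- if ("rating" %in% names(trials)) {
    binarize_rating(trials$rating)
  } else if ("class" %in% names(trials)) {
    ifelse(trials$class == 1, "high", "low")
  } else {
    NA_character_
  }
  dplyr::bind_cols(out, tibble::as_tibble(fmat))
}

subset_channels <- function(sig, chans) {
  m <- unclass(sig)
  sub <- m[chans, , drop = FALSE]
  multichannel_signal(sub, sample_rate = attr(sig, "sample_rate"))
}

#' Feature-column names of a feature table
#'
#' @param features A tibble from [extract_features()].
#' @return Character vector of the numeric entropy feature columns.
#' @export
feature_cols <- function(features) {
  grep("(^|_)s_[0-9]+$", names(features), value = TRUE)
}

#' Write / read a feature table CSV
#'
#' @param features Feature tibble from [extract_features()].
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
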