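#' Windowed mean (MEA)
#'
#' Arithmetic mean of the window values; reflects the relative hemoglobin
#' concentration change.
#'
#' @param x non-empty numeric window.
#' @return the mean.
#' @export
mea <- function(x) {
  assert_numeric_series(x)
  if (length(x) == 0) stopf("mea: empty window")
  mean(x)
}

#' Windowed standard deviation (STD)
#'
#' Population standard deviation (divisor \eqn{k}):
#' \deqn{STD = \sqrt{\tfrac{1}{k}\sum_i (x_i - MEA)^2}}
#' reflecting how stationary the hemoglobin concentration is over the window.
#'
#' @param x non-empty numeric window.
#' @return the standard deviation.
#' @export
std <- function(x) {
  assert_numeric_series(x)
  if (length(x) == 0) stopf("std: empty window")
  pop_sd(x)
}

#' Extract the sliding-window feature matrix
#'
#' One row per window position (windows fully inside the trial), with MEA and
#' STD per channel per component series: the standard configuration of 6
#' channels x 2 series yields 24 feature columns named
#' `<channel>_<series>_<MEA|STD>`; single-component signal types yield 12.
#' With `restrict_to_active = TRUE` only windows whose span lies inside an
#' active (rising or falling) segment on at least one channel are kept — the
#' union-over-channels rule — matching feature extraction from activation
#' segments.
#'
#' @param signals a `nirs_signals` object (see [improve_recording()]); a raw
#'   `nirs_recording` is accepted and treated as signal type `"RAW"`.
#' @param window,stride window length and stride in samples.
#' @param restrict_to_active keep only windows inside active segments.
#' @param segment_map segment data frame from [segment_recording()]; required
#'   when `restrict_to_active = TRUE`.
#' @return data frame with provenance columns `trial_id`, `subject_id`,
#'   `group`, `window_start`, `label`, then the feature columns.
#' @export
extract_features <- function(signals, window = 8, stride = 4,
                             restrict_to_active = FALSE, segment_map = NULL) {
  if (inherits(signals, "nirs_recording")) {
    signals <- improve_recording(signals, "RAW")
  }
  stopifnot(inherits(signals, "nirs_signals"))
  missing_ch <- setdiff(signals$channels, names(signals$series))
  if (length(missing_ch) > 0) {
    stopf("extract_features: missing channel(s): %s",
          paste(missing_ch, collapse = ", "))
  }
  n <- length(signals$series[[1]][[1]])
  window <- as.integer(window)
  if (n < window) stopf("extract_features: trial shorter than one window")
  starts <- seq.int(1L, n - window + 1L, by = as.integer(stride))

  if (restrict_to_active) {
    if (is.null(segment_map)) {
      stopf("extract_features: restrict_to_active requires a segment_map")
    }
    act <- segment_map[segment_map$kind %in% c("active_up", "active_down") &
                         segment_map$trial_id == signals$trial_id, ,
                       drop = FALSE]
    keep <- vapply(starts, function(s) {
      any(act$start <= s & act$end >= s + window - 1L)
    }, logical(1))
    starts <- starts[keep]
  }

  cols <- list()
  for (ch in signals$channels) {
    for (sn in signals$series_names) {
      x <- signals$series[[ch]][[sn]]
      mea_v <- vapply(starts, function(s) mea(x[s:(s + window - 1L)]), numeric(1))
      std_v <- vapply(starts, function(s) std(x[s:(s + window - 1L)]), numeric(1))
      cols[[paste(ch, sn, "MEA", sep = "_")]] <- mea_v
      cols[[paste(ch, sn, "STD", sep = "_")]] <- std_v
    }
  }
  out <- data.frame(trial_id = rep(signals$trial_id, length(starts)),
                    subject_id = rep(signals$subject_id, length(starts)),
                    group = rep(signals$group, length(starts)),
                    window_start = starts,
                    label = rep(signals$label, length(starts)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cols))
}

# provenance columns preceding the features in a feature matrix
FEATURE_META_COLS <- c("trial_id", "subject_id", "group", "window_start", "label")

#' Names of the feature columns of a feature matrix
#' @param features a feature matrix from [extract_features()].
#' @return character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), FEATURE_META_COLS)
}
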