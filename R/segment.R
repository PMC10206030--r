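#' Segmentation configuration
#'
#' @param window window length in samples (500 ms at 16 Hz).
#' @param stride window stride in samples (250 ms at 16 Hz).
#' @param tol_rel relative tolerance for "mean window slope approximately
#'   equal to the run slope".
#' @param tol_zero_mult multiple of the rest-period median absolute window
#'   slope used as the "approximately zero" threshold.
#' @param rest_seconds initial span of the trial assumed to be rest, from
#'   which the zero threshold is calibrated.
#' @param tol_zero_frac absolute floor for the zero threshold as a fraction of
#'   the trial's largest absolute window slope; keeps near-flat plateaus from
#'   registering as activity when the rest period is noise free.
#' @param min_run_windows minimum number of consecutive same-sign windows for
#'   a run to qualify as active. Hemoglobin concentration takes a few seconds
#'   to move between plateaus, so genuine activation ramps span several
#'   windows; isolated one- or two-window slope excursions are noise.
#' @return a `segment_config` list.
#' @export
segment_config <- function(window = 8, stride = 4, tol_rel = 0.5,
                           tol_zero_mult = 3, rest_seconds = 1,
                           tol_zero_frac = 0.05, min_run_windows = 3) {
  stopifnot(window >= 2, stride >= 1, tol_rel > 0, tol_zero_mult > 0,
            min_run_windows >= 1)
  structure(list(window = window, stride = stride, tol_rel = tol_rel,
                 tol_zero_mult = tol_zero_mult, rest_seconds = rest_seconds,
                 tol_zero_frac = tol_zero_frac,
                 min_run_windows = min_run_windows),
            class = "segment_config")
}

#' Linear fitting slope of one analysis window
#'
#' Ordinary least-squares slope of the signal against time over the window:
#' \deqn{LFS = \sum_i (t_i - \bar t)(x_i - \bar x) \; / \; \sum_i (t_i - \bar t)^2}
#' The slope (a.u./s) estimates the hemoglobin concentration change rate,
#' which tracks the degree of muscle activation: rising during activation,
#' falling during deactivation, near zero at rest or plateau.
#'
#' @param x window values.
#' @param t window times in seconds (defaults to a unit-rate grid).
#' @return the slope.
#' @export
lfs <- function(x, t = seq_along(x)) {
  assert_numeric_series(x)
  if (length(x) < 2) stopf("lfs: window must contain at least 2 samples")
  assert_equal_length(x, t, "x and t")
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom == 0) stopf("lfs: window times are constant")
  sum(tc * (x - mean(x))) / denom
}

#' Sliding-window linear fitting slopes
#'
#' One slope per window position; the number of windows is
#' `floor((N - window) / stride) + 1`.
#'
#' @param series numeric series, at least one window long.
#' @param sampling_rate sampling frequency in Hz.
#' @param window,stride window length and stride in samples.
#' @return data frame with `start` (1-based first sample), `end` (last
#'   sample) and `slope` per window.
#' @export
sliding_lfs <- function(series, sampling_rate, window = 8, stride = 4) {
  assert_numeric_series(series)
  n <- length(series)
  window <- as.integer(window)
  if (n < window) {
    stopf("sliding_lfs: series length %d shorter than one window (%d)", n, window)
  }
  starts <- seq.int(1L, n - window + 1L, by = as.integer(stride))
  t <- (seq_len(window) - 1) / sampling_rate
  slopes <- vapply(starts, function(s) lfs(series[s:(s + window - 1L)], t),
                   numeric(1))
  data.frame(start = starts, end = starts + window - 1L, slope = slopes)
}

#' Detect activation and deactivation segments
#'
#' Window slopes are computed with [sliding_lfs()] and classified by sign
#' against a zero threshold calibrated from the trial's initial rest period.
#' Consecutive windows sharing a non-zero sign form candidate runs; a run is
#' accepted as active when the mean of its window slopes is approximately
#' equal to the slope fitted over the whole run (within `tol_rel` relative)
#' and that run slope is not approximately zero. Rising runs are
#' `active_up` (activation), falling runs `active_down` (deactivation);
#' everything else is `inactive`. Segments partition the trial.
#'
#' @param series preprocessed numeric series.
#' @param sampling_rate sampling frequency in Hz.
#' @param config a [segment_config()].
#' @return data frame with `start`, `end` (sample indices), `kind` and `lfs`
#'   (slope over the segment, a.u./s).
#' @export
detect_segments <- function(series, sampling_rate, config = segment_config()) {
  win <- sliding_lfs(series, sampling_rate, config$window, config$stride)
  n <- length(series)

  rest_n <- max(config$window, round(config$rest_seconds * sampling_rate))
  rest_slopes <- abs(win$slope[win$end <= rest_n])
  if (length(rest_slopes) == 0) rest_slopes <- abs(win$slope[1])
  tol_zero <- max(config$tol_zero_mult * median(rest_slopes),
                  config$tol_zero_frac * max(abs(win$slope)))

  sgn <- ifelse(abs(win$slope) <= tol_zero, 0L, as.integer(sign(win$slope)))
  r <- rle(sgn)
  run_end_i <- cumsum(r$lengths)
  run_start_i <- run_end_i - r$lengths + 1L

  segs <- lapply(seq_along(r$values), function(i) {
    wi <- run_start_i[i]:run_end_i[i]
    s0 <- win$start[run_start_i[i]]
    s1 <- win$end[run_end_i[i]]
    kind <- "inactive"
    run_slope <- lfs(series[s0:s1], ((s0:s1) - 1) / sampling_rate)
    if (r$values[i] != 0L && r$lengths[i] >= config$min_run_windows) {
      mean_slope <- mean(win$slope[wi])
      ok_mean <- abs(mean_slope - run_slope) <= config$tol_rel * abs(run_slope)
      ok_zero <- abs(run_slope) > tol_zero
      if (ok_mean && ok_zero) {
        kind <- if (run_slope > 0) "active_up" else "active_down"
      }
    }
    data.frame(start = s0, end = s1, kind = kind, lfs = run_slope)
  })
  segs <- do.call(rbind, segs)

  # make the partition exact: extend the first/last segments to the trial
  # edges and merge adjacent inactive spans
  segs$start[1] <- 1L
  segs$end[nrow(segs)] <- as.integer(n)
  if (nrow(segs) > 1) {
    for (i in 2:nrow(segs)) segs$start[i] <- segs$end[i - 1] + 1L
    keep <- rep(TRUE, nrow(segs))
    for (i in 2:nrow(segs)) {
      if (segs$kind[i] == "inactive" && segs$kind[i - 1] == "inactive" && keep[i - 1]) {
        prev <- max(which(keep[1:(i - 1)]))
        segs$end[prev] <- segs$end[i]
        keep[i] <- FALSE
      }
    }
    segs <- segs[keep, , drop = FALSE]
  }
  segs <- segs[segs$end >= segs$start, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Segment every channel and component of an improved recording
#'
#' @param signals a `nirs_signals` object (see [improve_recording()]).
#' @param config a [segment_config()].
#' @return data frame with `trial_id`, `channel`, `series`, `start`, `end`,
#'   `kind`, `lfs`.
#' @export
segment_recording <- function(signals, config = segment_config()) {
  stopifnot(inherits(signals, "nirs_signals"))
  out <- list()
  for (ch in signals$channels) {
    for (sn in signals$series_names) {
      segs <- detect_segments(signals$series[[ch]][[sn]],
                              signals$sampling_rate, config)
      if (nrow(segs) > 0) {
        segs <- cbind(trial_id = signals$trial_id, channel = ch,
                      series = sn, segs)
        out[[length(out) + 1]] <- segs
      }
    }
  }
  do.call(rbind, out)
}
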