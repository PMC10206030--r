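#' Default trunk-muscle activation map
#'
#' Per class and channel, the plateau amplitudes (arbitrary
#' concentration-change units) of the clean common-mode (blood flow, `cms`)
#' and differential-mode (oxygen consumption, `dms`) components. The pattern
#' follows the known recruitment physiology of the three compensation types,
#' with the right side as the executing side:
#' \itemize{
#'   \item LF (lean forward): executing-side obliquus externus abdominis
#'     (ROEA) dominates, mild contralateral OEA/DT involvement;
#'   \item TR (trunk rotation): ROEA dominates with executing-side trapezius
#'     (RDT) and contralateral erector spinae (LES) assisting;
#'   \item SE (shoulder elevation): executing-side trapezius (RDT) and erector
#'     spinae (RES) dominate;
#'   \item NC (no compensation): mild executing-side engagement only.
#' }
#' `dms` is negative during activation (oxygen extraction lowers HbO2 relative
#' to Hb) and scaled to 30% of `cms`.
#'
#' @return data frame with columns `class`, `channel`, `cms`, `dms`, one row
#'   per (class, channel) pair.
#' @export
default_activation_map <- function() {
  amp <- rbind(
    #        LOEA ROEA LDT  RDT  LES  RES
    NC = c(  0.2, 0.5, 0.2, 0.5, 0.2, 0.5),
    LF = c(  0.7, 2.2, 0.6, 0.3, 0.3, 0.4),
    TR = c(  0.3, 2.0, 0.3, 1.0, 0.7, 0.4),
    SE = c(  0.2, 0.4, 0.4, 2.2, 0.6, 1.9)
  )
  colnames(amp) <- NIRS_CHANNELS
  out <- expand.grid(class = rownames(amp), channel = NIRS_CHANNELS,
                     stringsAsFactors = FALSE)
  out$cms <- amp[cbind(out$class, out$channel)]
  out$dms <- -0.3 * out$cms
  out[order(match(out$class, rownames(amp)), match(out$channel, NIRS_CHANNELS)), ]
}

#' Simulation configuration
#'
#' Study conditions for the synthetic trunk-muscle NIRS generator. Defaults
#' describe a single reaching trial: 10 s at 16 Hz, activation onset at 20%
#' and offset at 80% of the trial, a logistic ramp lasting `rise_time` seconds
#' (hemoglobin concentration takes a few seconds to reach a new plateau), slow
#' sinusoidal-plus-linear baseline drift, cardiac pulsation at 1.2 Hz,
#' broadband Gaussian noise, and occasional dropped samples from wireless
#' transmission.
#'
#' @param sampling_rate sampling frequency in Hz.
#' @param trial_duration trial length in seconds.
#' @param classes movement classes generated.
#' @param activation_map data frame `class, channel, cms, dms` covering every
#'   (class, channel) pair; see [default_activation_map()].
#' @param rise_time seconds for the ramp from rest to plateau.
#' @param onset_frac,offset_frac activation onset/offset as fractions of the
#'   trial.
#' @param drift_amplitude amplitude (a.u.) of the slow baseline drift.
#' @param drift_period period (s) of the sinusoidal drift component; kept
#'   well above the trial length so within-trial drift is smooth.
#' @param cardiac_freq,cardiac_amplitude cardiac interference frequency (Hz)
#'   and amplitude (a.u.); enters both chromophores with the same sign
#'   (pulsatile blood volume is common mode).
#' @param noise_sd standard deviation of white measurement noise (a.u.).
#' @param missing_rate per-sample probability that a channel's sample is
#'   dropped in transmission (never within the first `pad_lookback` samples).
#' @param subject_jitter_sd log-scale SD of the per-subject multiplicative
#'   amplitude factor making subjects non-identical.
#' @param seed default master seed used when none is passed explicitly.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(sampling_rate = 16,
                       trial_duration = 10,
                       classes = NIRS_CLASSES,
                       activation_map = default_activation_map(),
                       rise_time = 2,
                       onset_frac = 0.2,
                       offset_frac = 0.8,
                       drift_amplitude = 0.3,
                       drift_period = 120,
                       cardiac_freq = 1.2,
                       cardiac_amplitude = 0.1,
                       noise_sd = 0.05,
                       missing_rate = 0.02,
                       subject_jitter_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, trial_duration = trial_duration,
    classes = classes, activation_map = activation_map,
    rise_time = rise_time, onset_frac = onset_frac, offset_frac = offset_frac,
    drift_amplitude = drift_amplitude, drift_period = drift_period,
    cardiac_freq = cardiac_freq, cardiac_amplitude = cardiac_amplitude,
    noise_sd = noise_sd, missing_rate = missing_rate,
    subject_jitter_sd = subject_jitter_sd, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stopf("missing_rate must be in [0, 1)")
  }
  if (cfg$rise_time >= cfg$trial_duration) {
    stopf("rise_time must be shorter than trial_duration")
  }
  amps <- unlist(cfg$activation_map[, c("cms", "dms")])
  if (!all(is.finite(amps))) stopf("activation amplitudes must be finite")
  need <- expand.grid(class = cfg$classes, channel = NIRS_CHANNELS,
                      stringsAsFactors = FALSE)
  have <- paste(cfg$activation_map$class, cfg$activation_map$channel)
  miss <- setdiff(paste(need$class, need$channel), have)
  if (length(miss) > 0) {
    stopf("activation_map missing entries for: %s",
          paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

# smooth ramp-to-plateau activation profile: product of a logistic rise at t0
# and a logistic fall at t1, transition width set by rise_time
activation_profile <- function(t, t0, t1, rise_time) {
  scale <- rise_time / 8  # logistic covers ~2%..98% over 8 scale units
  stats::plogis((t - t0) / scale) * (1 - stats::plogis((t - t1) / scale))
}

#' Generate one synthetic NIRS trial with ground truth
#'
#' The clean signal is built per channel in (CMS, DMS) space — plateau
#' amplitudes from the activation map times the subject factor, shaped by a
#' logistic ramp — and mapped to (Hb, HbO2) via [dbsi_inverse()]. Artifacts
#' are then added on the chromophore series: slow drift (sinusoid of period
#' `drift_period` at a random phase, plus a linear term), a common-mode
#' cardiac sinusoid, white Gaussian noise, and dropped samples (set to `NA`
#' and flagged in `missing_mask`; the first four samples of a channel are
#' never dropped so that the padding rule always has a complete prefix).
#'
#' @param config a [sim_config()].
#' @param label movement class of the trial, one of the classes in `config`.
#' @param subject_id,trial_id identifiers stored in the recording.
#' @param seed integer seed; identical (config, label, seed) give
#'   bit-identical output.
#' @param group `"healthy"` or `"stroke"`.
#' @param amp_factor multiplicative amplitude factor (per-subject jitter,
#'   applied by [generate_dataset()]).
#' @return list with components `recording` (a `nirs_recording`) and `truth`
#'   (per-channel clean CMS/DMS series, activation interval and ramp
#'   intervals in sample indices).
#' @export
generate_trial <- function(config, label, subject_id = "S1",
                           trial_id = "T1", seed = config$seed,
                           group = c("healthy", "stroke"), amp_factor = 1) {
  group <- match.arg(group)
  if (!label %in% config$classes) {
    stopf("unknown label '%s'; configured classes: %s", label,
          paste(config$classes, collapse = ", "))
  }
  validate_sim_config(config)
  set.seed(derive_seed(seed, 1L))

  fs <- config$sampling_rate
  n <- round(config$trial_duration * fs)
  t <- (seq_len(n) - 1) / fs
  t0 <- config$onset_frac * config$trial_duration
  t1 <- config$offset_frac * config$trial_duration
  prof <- activation_profile(t, t0, t1, config$rise_time)

  map <- config$activation_map
  # ground-truth ramp intervals span the full transition: rise_time is the
  # time to move between plateaus, so the ramp occupies [t - rise_time/2,
  # t + rise_time/2] around each switch point
  half_ramp <- config$rise_time / 2
  idx_of <- function(x) pmin(pmax(round(x * fs) + 1L, 1L), n)

  series <- list(); mask <- list(); truth_ch <- list()
  for (ch in NIRS_CHANNELS) {
    row <- map[map$class == label & map$channel == ch, ]
    cms_clean <- amp_factor * row$cms * prof
    dms_clean <- amp_factor * row$dms * prof
    clean <- dbsi_inverse(cms_clean, dms_clean)

    cardiac <- config$cardiac_amplitude *
      sin(2 * pi * config$cardiac_freq * t + runif(1, 0, 2 * pi))
    add_artifacts <- function(x) {
      drift <- config$drift_amplitude *
        sin(2 * pi * t / config$drift_period + runif(1, 0, 2 * pi)) +
        runif(1, -1, 1) * config$drift_amplitude / config$trial_duration * t
      x + drift + cardiac + rnorm(n, 0, config$noise_sd)
    }
    hb <- add_artifacts(clean$hb)
    hbo2 <- add_artifacts(clean$hbo2)

    m <- runif(n) < config$missing_rate
    m[seq_len(min(4L, n))] <- FALSE
    hb[m] <- NA_real_
    hbo2[m] <- NA_real_

    series[[ch]] <- list(Hb = hb, HbO2 = hbo2)
    mask[[ch]] <- m
    truth_ch[[ch]] <- list(
      cms = cms_clean, dms = dms_clean,
      onset = idx_of(t0), offset = idx_of(t1),
      ramp_up = c(idx_of(t0 - half_ramp), idx_of(t0 + half_ramp)),
      ramp_down = c(idx_of(t1 - half_ramp), idx_of(t1 + half_ramp)),
      cms_amplitude = amp_factor * row$cms,
      dms_amplitude = amp_factor * row$dms
    )
  }

  recording <- structure(
    list(trial_id = trial_id, subject_id = subject_id, group = group,
         label = label, sampling_rate = fs, channels = NIRS_CHANNELS,
         series = series, missing_mask = mask),
    class = "nirs_recording"
  )
  list(recording = recording, truth = structure(truth_ch, class = "nirs_truth"))
}

#' Generate a balanced synthetic dataset
#'
#' Produces `trials_per_class` trials per class per subject, with per-subject
#' lognormal amplitude jitter so subjects are non-identical. `trials_per_class`
#' may be a single count or a named vector per class (the study protocol used
#' 20 repetitions per compensatory motion and 10 without compensation:
#' `c(NC = 10, LF = 20, TR = 20, SE = 20)`).
#'
#' @inheritParams generate_trial
#' @param n_subjects number of subjects.
#' @param trials_per_class integer count, or named integer vector by class.
#' @return list of `list(recording, truth)` elements, one per trial.
#' @export
generate_dataset <- function(config, n_subjects = 1, trials_per_class = 20,
                             seed = config$seed, group = "healthy") {
  stopifnot(n_subjects >= 1, all(trials_per_class >= 1))
  counts <- trials_per_class
  if (is.null(names(counts))) {
    counts <- stats::setNames(rep(counts[1], length(config$classes)),
                              config$classes)
  }
  if (!all(config$classes %in% names(counts))) {
    stopf("trials_per_class must name every class")
  }
  set.seed(derive_seed(seed, 2L))
  subj_factor <- rlnorm(n_subjects, 0, config$subject_jitter_sd)
  trial_seeds <- sample.int(2^31 - 1, n_subjects * sum(counts[config$classes]))

  out <- list(); k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", if (group == "healthy") "H" else "P", s)
    for (cl in config$classes) {
      for (r in seq_len(counts[[cl]])) {
        k <- k + 1L
        tid <- sprintf("%s_%s_%02d", sid, cl, r)
        out[[k]] <- generate_trial(config, cl, subject_id = sid,
                                   trial_id = tid, seed = trial_seeds[k],
                                   group = group,
                                   amp_factor = subj_factor[s])
      }
    }
  }
  out
}
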