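TRIAL_CSV_HEADER <- c("t", as.vector(t(outer(NIRS_CHANNELS, c("Hb", "HbO2"),
                                             paste, sep = "_"))))

fmt9 <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write one trial to CSV
#'
#' Thirteen columns: time in seconds, then Hb and HbO2 per channel in the
#' canonical channel order. Missing samples are written as empty fields, so a
#' write-read round trip preserves the missing mask exactly. Values are
#' formatted at 9 significant digits.
#'
#' @param recording a `nirs_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  n <- length(recording$series[[1]]$Hb)
  cols <- list(t = fmt9((seq_len(n) - 1) / recording$sampling_rate))
  for (ch in NIRS_CHANNELS) {
    cols[[paste0(ch, "_Hb")]] <- fmt9(recording$series[[ch]]$Hb)
    cols[[paste0(ch, "_HbO2")]] <- fmt9(recording$series[[ch]]$HbO2)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one trial from CSV
#'
#' Accepts any column order (channels are mapped by name) but requires the
#' complete 13-column schema. Empty fields become `NA` and set the missing
#' mask. Metadata not stored in the CSV (identifiers, group, label) is
#' supplied by the caller, normally from the manifest.
#'
#' @param path CSV file written by [write_trial_csv()].
#' @param trial_id,subject_id,group,label trial metadata.
#' @param sampling_rate sampling frequency in Hz; checked against the time
#'   column when it has at least two rows.
#' @return a `nirs_recording`.
#' @export
read_trial_csv <- function(path, trial_id = basename(path), subject_id = "S1",
                           group = "healthy", label = "NC",
                           sampling_rate = 16) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) stopf("read_trial_csv: %s: %s", path, conditionMessage(e)),
    warning = function(w) stopf("read_trial_csv: %s: %s", path, conditionMessage(w))
  )
  missing_cols <- setdiff(TRIAL_CSV_HEADER, names(df))
  if (length(missing_cols) > 0) {
    stopf("read_trial_csv: %s: missing column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) >= 2) {
    dt <- diff(df$t[1:2])
    if (dt > 0 && abs(1 / dt - sampling_rate) > 1e-6 * sampling_rate) {
      stopf("read_trial_csv: %s: time column implies %.6g Hz, expected %.6g Hz",
            path, 1 / dt, sampling_rate)
    }
  }
  series <- list(); mask <- list()
  for (ch in NIRS_CHANNELS) {
    hb <- df[[paste0(ch, "_Hb")]]
    hbo2 <- df[[paste0(ch, "_HbO2")]]
    series[[ch]] <- list(Hb = hb, HbO2 = hbo2)
    mask[[ch]] <- is.na(hb) | is.na(hbo2)
  }
  structure(
    list(trial_id = trial_id, subject_id = subject_id, group = group,
         label = label, sampling_rate = sampling_rate,
         channels = NIRS_CHANNELS, series = series, missing_mask = mask),
    class = "nirs_recording"
  )
}

#' Write a dataset to a directory of trial CSVs plus manifest
#'
#' @param dataset list of `list(recording, truth)` from [generate_dataset()].
#' @param dir output directory, created if needed.
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(el) {
    rec <- el$recording
    file <- paste0(rec$trial_id, ".csv")
    write_trial_csv(rec, file.path(dir, file))
    data.frame(trial_id = rec$trial_id, subject_id = rec$subject_id,
               group = rec$group, label = rec$label, file = file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a manifest file
#'
#' @param path manifest CSV with columns
#'   `trial_id,subject_id,group,label,file`.
#' @return the manifest data frame, validated for schema, label vocabulary
#'   and duplicate trial identifiers.
#' @export
read_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "subject_id", "group", "label", "file")
  missing_cols <- setdiff(need, names(mf))
  if (length(missing_cols) > 0) {
    stopf("read_manifest: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(mf$label), NIRS_CLASSES)
  if (length(bad) > 0) {
    stopf("read_manifest: unknown label(s) %s; allowed labels: %s",
          paste(bad, collapse = ", "), paste(NIRS_CLASSES, collapse = ", "))
  }
  dup <- mf$trial_id[duplicated(mf$trial_id)]
  if (length(dup) > 0) {
    stopf("read_manifest: duplicate trial_id(s): %s",
          paste(unique(dup), collapse = ", "))
  }
  mf
}

#' Validate a dataset directory
#'
#' Checks that the manifest parses, every referenced trial file exists and
#' reads back with the full channel schema.
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list with `n_trials`, `classes` (table) and `ok = TRUE`; errors
#'   otherwise.
#' @export
validate_dataset <- function(dir) {
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  for (i in seq_len(nrow(mf))) {
    fp <- file.path(dir, mf$file[i])
    if (!file.exists(fp)) {
      stopf("validate_dataset: trial '%s' references missing file %s",
            mf$trial_id[i], mf$file[i])
    }
    invisible(read_trial_csv(fp, trial_id = mf$trial_id[i],
                             subject_id = mf$subject_id[i],
                             group = mf$group[i], label = mf$label[i]))
  }
  list(n_trials = nrow(mf), classes = table(mf$label), ok = TRUE)
}

#' Read a dataset directory back into recordings
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @param sampling_rate sampling frequency in Hz.
#' @return list of `nirs_recording` objects.
#' @export
read_dataset <- function(dir, sampling_rate = 16) {
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(mf)), function(i) {
    read_trial_csv(file.path(dir, mf$file[i]), trial_id = mf$trial_id[i],
                   subject_id = mf$subject_id[i], group = mf$group[i],
                   label = mf$label[i], sampling_rate = sampling_rate)
  })
}
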