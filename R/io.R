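#' Read and write RR-interval CSV files
#'
#' The RRI file dialect is a CSV with a single `rr_ms` header line and one
#' interval (milliseconds) per line.
#'
#' @param rri An [rri_series()] or numeric vector (ms).
#' @param path File path.
#' @return `write_rri_csv()` returns `path` invisibly; `read_rri_csv()`
#'   returns an [rri_series()].
#' @export
write_rri_csv <- function(rri, path) {
  df <- data.frame(rr_ms = as.numeric(rri))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param subject_id,state,gender Labels attached to the series read.
#' @rdname write_rri_csv
#' @export
read_rri_csv <- function(path, subject_id = NA_character_,
                         state = NA_character_, gender = NA_character_) {
  df <- utils::read.csv(path)
  if (!"rr_ms" %in% names(df))
    stop_("data_error", "no 'rr_ms' column in %s", path)
  rri_series(df$rr_ms, subject_id = subject_id, state = state,
             gender = gender)
}

#' Read and write ECG records
#'
#' An ECG record is stored as a two-column CSV (`sample_index`, `mv`) plus a
#' JSON sidecar `<path>.meta.json` holding `sampling_rate_hz`, the labels and
#' any ground-truth peak indices.
#'
#' @param ecg An [ecg_record()].
#' @param path CSV file path (sidecar written next to it).
#' @return `write_ecg_record()` returns `path` invisibly;
#'   `read_ecg_record()` returns an [ecg_record()].
#' @export
write_ecg_record <- function(ecg, path) {
  utils::write.csv(data.frame(sample_index = seq_along(ecg$samples) - 1L,
                              mv = ecg$samples),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate_hz = ecg$sampling_rate,
               subject_id = ecg$subject_id, state = ecg$state,
               true_peaks = ecg$true_peaks)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ecg_record
#' @export
read_ecg_record <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop_("data_error", "missing sidecar %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ecg_record(df$mv, meta$sampling_rate_hz,
             subject_id = meta$subject_id %||% NA_character_,
             state = meta$state %||% NA_character_,
             true_peaks = if (length(meta$true_peaks)) as.integer(meta$true_peaks))
}

#' Write a cohort to a directory of RRI files
#'
#' One file per (subject, state), named `subjNN_<state>.csv`, plus a
#' `manifest.csv` table (`subject_id`, `gender`, `state`, `path`,
#' `n_intervals`, `seed`).
#'
#' @param cohort An `rri_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with the `path` column), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "rri_cohort"))
    stop_("invalid_parameter", "cohort must be an rri_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- as.data.frame(cohort$manifest)
  man$path <- file.path(dir, sprintf("%s_%s.csv", man$subject_id, man$state))
  for (i in seq_along(cohort$series))
    write_rri_csv(cohort$series[[i]], man$path[i])
  utils::write.csv(man[, c("subject_id", "gender", "state", "path",
                           "n_intervals", "seed")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(tibble::as_tibble(man))
}

#' Read a directory of RRI files as a series collection
#'
#' Uses `manifest.csv` when present; otherwise parses subject and state from
#' the `subjNN_<state>.csv` filename pattern.
#'
#' @param dir Directory containing RRI CSV files.
#' @return A list of [rri_series()].
#' @export
read_rri_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (file.exists(man_path)) {
    man <- utils::read.csv(man_path)
    return(lapply(seq_len(nrow(man)), function(i)
      read_rri_csv(file.path(dir, basename(man$path[i])),
                   subject_id = man$subject_id[i], state = man$state[i],
                   gender = if ("gender" %in% names(man)) man$gender[i]
                            else NA_character_)))
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  if (length(files) == 0) stop_("input_error", "no RRI files in %s", dir)
  lapply(files, function(f) {
    base <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(base, "_", fixed = TRUE)[[1]]
    read_rri_csv(f, subject_id = parts[1],
                 state = if (length(parts) > 1) parts[2] else NA_character_)
  })
}
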