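#' Write a trial to CSV
#'
#' Writes the eight sensor columns (`t,ax,ay,az,fsr1,fsr2,fsr3,fsr4`) as
#' RFC-4180 CSV with a header row. Accelerations are serialized with full
#' double precision so a round trip reproduces them to better than 1e-9 g.
#' Labels are not stored in the file; they live in the dataset manifest
#' (see [write_trial_dataset()]).
#'
#' @param trial An `insole_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  validate_trial(trial)
  readr::write_csv(tibble::as_tibble(trial)[trial_columns()], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a trial from CSV
#'
#' Expects exactly the header written by [write_trial_csv()]; rows violating
#' the sensor range invariants are rejected with the offending row index.
#'
#' @param path CSV file path.
#' @param subject_id,activity,fall_type Labels to attach (normally supplied
#'   from the dataset manifest).
#' @param fs Sampling frequency in Hz.
#' @return An `insole_trial`.
#' @export
read_trial_csv <- function(path, subject_id = NA_character_,
                           activity = NA_character_,
                           fall_type = NA_character_, fs = 20) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(dat), trial_columns())) {
    abort(sprintf("unexpected CSV columns: got [%s], expected [%s]",
                  paste(names(dat), collapse = ","),
                  paste(trial_columns(), collapse = ",")))
  }
  new_trial(dat, subject_id = subject_id, activity = activity,
            fall_type = fall_type, fs = fs)
}

#' Write a trial dataset to a directory of CSV files plus a manifest
#'
#' One CSV per trial named by `trial_id`, plus `manifest.tsv` with columns
#' `file, trial_id, subject_id, activity, fall_type, fs` so the labels
#' survive the round trip.
#'
#' @param dataset A nested trial dataset as returned by
#'   [generate_protocol_dataset()]: a tibble with columns `trial_id,
#'   subject_id, activity, fall_type, data`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_trial_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- paste0(dataset$trial_id, ".csv")
  purrr::walk2(dataset$data, files,
               function(tr, f) write_trial_csv(tr, file.path(dir, f)))
  manifest <- tibble::tibble(
    file = files,
    trial_id = dataset$trial_id,
    subject_id = dataset$subject_id,
    activity = dataset$activity,
    fall_type = dataset$fall_type,
    fs = purrr::map_dbl(dataset$data, trial_fs)
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Read a trial dataset written by [write_trial_dataset()]
#'
#' @param dir Directory containing `manifest.tsv` and the trial CSVs.
#' @return A nested trial dataset tibble.
#' @export
read_trial_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort(paste0("no manifest.tsv in ", dir))
  }
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  trials <- purrr::pmap(manifest, function(file, trial_id, subject_id,
                                           activity, fall_type, fs, ...) {
    read_trial_csv(file.path(dir, file), subject_id = subject_id,
                   activity = activity, fall_type = fall_type, fs = fs)
  })
  tibble::tibble(trial_id = manifest$trial_id,
                 subject_id = as.character(manifest$subject_id),
                 activity = manifest$activity,
                 fall_type = as.character(manifest$fall_type),
                 data = trials)
}
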