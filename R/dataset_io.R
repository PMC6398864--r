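# On-disk schema: patients.csv, prescriptions.csv, notes.jsonl,
# outcomes.csv, plus a ground-truth sidecar (ground_truth.csv + truth.yaml)
# kept separate from the analysis inputs.

#' Write a synthetic EHR dataset to a directory
#'
#' Emits `patients.csv`, `prescriptions.csv`, `notes.jsonl` (one JSON object
#' per line), `outcomes.csv`, and — when ground truth is supplied — a
#' `ground_truth.csv` / `truth.yaml` sidecar with the per-patient latent risk,
#' assigned class, true log hazard ratio and a config echo. Dates are
#' ISO-8601. The files round-trip losslessly through [read_dataset()].
#'
#' @param records an `ehr_dataset` (see [generate_cohort()])
#' @param ground_truth an `ehr_truth`, or NULL to omit the sidecar
#' @param directory output directory, created if needed
#' @return the directory, invisibly
#' @export
write_dataset <- function(records, ground_truth = NULL, directory) {
  assert_that(inherits(records, "ehr_dataset"), "records must be an ehr_dataset")
  assert_that(nrow(records$patients) > 0, "records must contain patients")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fwrite_iso <- function(dt, file) {
    data.table::fwrite(dt, file.path(directory, file), dateTimeAs = "ISO")
  }
  fwrite_iso(records$patients, "patients.csv")
  fwrite_iso(records$prescriptions, "prescriptions.csv")
  fwrite_iso(records$outcomes, "outcomes.csv")

  con <- file(file.path(directory, "notes.jsonl"), open = "w",
              encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(records$notes) > 0) {
    lines <- vapply(seq_len(nrow(records$notes)), function(i) {
      jsonlite::toJSON(list(patient_id = records$notes$patient_id[i],
                            date = as.character(records$notes$date[i]),
                            text = records$notes$text[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }

  if (!is.null(ground_truth)) {
    fwrite_iso(ground_truth$per_patient, "ground_truth.csv")
    yaml::write_yaml(
      list(true_log_hr = ground_truth$true_log_hr,
           config = lapply(ground_truth$config, as.vector)),
      file.path(directory, "truth.yaml"), precision = 15
    )
  }
  invisible(directory)
}

#' Read a synthetic EHR dataset from a directory
#'
#' Inverse of [write_dataset()]. The ground-truth sidecar is read only when
#' `with_truth = TRUE`; the analysis pipeline never sets it.
#'
#' @param directory directory holding the schema files
#' @param with_truth also read `ground_truth.csv` / `truth.yaml`?
#' @return an `ehr_dataset`, or a list `(records, truth)` when
#'   `with_truth = TRUE`
#' @export
read_dataset <- function(directory, with_truth = FALSE) {
  rd <- function(f, datecols) {
    dt <- data.table::fread(file.path(directory, f))
    for (cl in intersect(datecols, names(dt))) {
      dt[[cl]] <- as_date_safe(dt[[cl]])
    }
    dt
  }
  patients <- rd("patients.csv", c("enrollment_start", "enrollment_end"))
  prescriptions <- rd("prescriptions.csv", "date")
  outcomes <- rd("outcomes.csv", "event_date")
  if (nrow(outcomes) == 0) {
    outcomes <- data.table::data.table(patient_id = character(0),
                                       event_date = as.Date(character(0)))
  }

  lines <- readLines(file.path(directory, "notes.jsonl"), encoding = "UTF-8")
  if (length(lines)) {
    parsed <- lapply(lines, jsonlite::fromJSON)
    notes <- data.table::data.table(
      patient_id = vapply(parsed, `[[`, character(1), "patient_id"),
      date = as.Date(vapply(parsed, `[[`, character(1), "date")),
      text = vapply(parsed, `[[`, character(1), "text")
    )
  } else {
    notes <- data.table::data.table(patient_id = character(0),
                                    date = as.Date(character(0)),
                                    text = character(0))
  }

  records <- structure(
    list(patients = patients, prescriptions = prescriptions, notes = notes,
         outcomes = outcomes),
    class = "ehr_dataset"
  )
  if (!with_truth) return(records)

  per_patient <- rd("ground_truth.csv", character(0))
  meta <- yaml::read_yaml(file.path(directory, "truth.yaml"))
  truth <- structure(
    list(per_patient = per_patient, true_log_hr = meta$true_log_hr,
         config = meta$config),
    class = "ehr_truth"
  )
  list(records = records, truth = truth)
}
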