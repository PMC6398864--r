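# Shared fixtures built in code.

# Small simulated world reused across tests (channeled, protective true HR).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(n_patients = 600, seed = 4242))
    }
    cache
  }
})

# Hand-built ehr_dataset from per-patient pieces.
make_dataset <- function(patients, prescriptions = NULL, notes = NULL,
                         outcomes = NULL) {
  empty_rx <- data.table::data.table(
    patient_id = character(0), date = as.Date(character(0)),
    atc_code = character(0), quantity = numeric(0), daily_dose = numeric(0)
  )
  empty_notes <- data.table::data.table(
    patient_id = character(0), date = as.Date(character(0)),
    text = character(0)
  )
  empty_out <- data.table::data.table(
    patient_id = character(0), event_date = as.Date(character(0))
  )
  structure(
    list(
      patients = data.table::as.data.table(patients),
      prescriptions = if (is.null(prescriptions)) empty_rx
                      else data.table::as.data.table(prescriptions),
      notes = if (is.null(notes)) empty_notes
              else data.table::as.data.table(notes),
      outcomes = if (is.null(outcomes)) empty_out
                 else data.table::as.data.table(outcomes)
    ),
    class = "ehr_dataset"
  )
}

# One eligible patient whose first prescription lands on `day0`
# (2005-01-01 by default), enrolled long before and after.
base_patient <- function(pid = "P1", sex = "M", birth_year = 1960,
                         aspirin = 0L) {
  data.table::data.table(
    patient_id = pid, birth_year = birth_year, sex = sex,
    enrollment_start = as.Date("2000-01-01"),
    enrollment_end = as.Date("2012-12-31"),
    aspirin_exposed = aspirin
  )
}

day0 <- as.Date("2005-01-01")

rx_row <- function(pid, offset_days, atc = "M01AE01", quantity = 30,
                   daily_dose = 1) {
  data.table::data.table(patient_id = pid, date = day0 + offset_days,
                         atc_code = atc, quantity = quantity,
                         daily_dose = daily_dose)
}

# Random small patient for the cohort oracle tests: a handful of
# prescriptions with random gaps, classes, quantities, plus occasional
# mentions and outcome events.
random_patient_inputs <- function(pid) {
  n_rx <- sample(1:6, 1)
  offs <- sort(sample(0:400, n_rx))
  cls <- sample(c("M01AE01", "M01AH01"), n_rx, replace = TRUE)
  rx <- data.table::data.table(
    patient_id = pid, date = day0 + offs, atc_code = cls,
    quantity = sample(c(5, 10, 20, 30, 60, 200), n_rx, replace = TRUE),
    daily_dose = sample(1:3, n_rx, replace = TRUE)
  )
  notes <- NULL
  if (runif(1) < 0.4) {
    notes <- data.table::data.table(
      patient_id = pid,
      date = day0 + sample(-200:300, 1),
      text = sample(c("patient kreeg ibuprofen", "alles goed vandaag",
                      "Celecoxib gestart", "maagpijn en misselijk"), 1)
    )
  }
  outcomes <- NULL
  if (runif(1) < 0.5) {
    outcomes <- data.table::data.table(
      patient_id = pid, event_date = day0 + sample(0:250, 1)
    )
  }
  pat <- base_patient(pid,
                      birth_year = sample(c(1950, 1980, 1990), 1),
                      sex = sample(c("M", "F"), 1))
  # vary enrollment to exercise the eligibility rules
  pat$enrollment_start <- day0 - sample(c(100, 200, 400, 800, 2000), 1)
  pat$enrollment_end <- day0 + sample(c(50, 200, 500, 2000), 1)
  list(pat = pat, rx = rx, notes = notes, outcomes = outcomes)
}

# Oracle wrapper over a whole dataset built from random_patient_inputs.
oracle_build_episodes <- function(dataset, lexicon = default_lexicon()) {
  out <- list()
  for (i in seq_len(nrow(dataset$patients))) {
    p <- dataset$patients[i]
    rx <- dataset$prescriptions[patient_id == p$patient_id]
    rx <- data.frame(
      date = rx$date,
      class = ifelse(rx$atc_code %in% default_atc_map()$COX2,
                     "COX2", "NSNSAID"),
      quantity = rx$quantity, daily_dose = rx$daily_dose
    )
    notes <- dataset$notes[patient_id == p$patient_id]
    mentions <- if (nrow(notes)) {
      toks <- normalize_text(notes$text, character(0))
      hit <- vapply(toks, function(tt) any(tt %in% lexicon), logical(1))
      notes$date[hit]
    } else as.Date(character(0))
    ev <- dataset$outcomes[patient_id == p$patient_id]$event_date
    eps <- oracle_patient_episodes(rx, mentions, ev, p$birth_year,
                                   p$enrollment_start, p$enrollment_end)
    if (!is.null(eps)) {
      eps$patient_id <- p$patient_id
      out[[length(out) + 1L]] <- eps
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
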