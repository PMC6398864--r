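# Synthetic EHR generator.
#
# The generative model encodes channeling and confounding by indication:
# a latent gastrointestinal risk score drives (i) preferential COX-2
# prescribing, (ii) the occurrence rates of a set of proxy words in the
# free-text notes, and (iii) the outcome hazard. The pipeline never sees the
# latent risk; it can only recover it through the note text.

# ATC code pools per NSAID class used by the generator (subset of the
# M01A anti-inflammatory group).
.COX2_ATC <- c("M01AH01", "M01AH02", "M01AH03", "M01AH05")
.NSNSAID_ATC <- c("M01AE01", "M01AE02", "M01AE03", "M01AB01", "M01AB05",
                  "M01AC01")
.DRUG_NAMES <- c("ibuprofen", "naproxen", "ketoprofen", "indometacine",
                 "diclofenac", "piroxicam", "celecoxib", "rofecoxib",
                 "valdecoxib", "etoricoxib")
.DIRTY_TOKENS <- c("de", "het", "een", "en", "!!", "??", "#pijn",
                   "#ernstig", "...", "-", "*nb*", "3x", "500mg")

#' Generate a synthetic EHR cohort with known confounding structure
#'
#' Simulates patients with enrollment windows, ATC-coded NSAID prescriptions,
#' dated free-text notes, and outcome events. Each patient carries a latent
#' risk score (standard normal shifted by age and low-dose-aspirin exposure)
#' that channels treatment assignment, shifts proxy-word rates in the notes,
#' and raises the outcome hazard, so that the crude treatment-outcome
#' association is confounded while the note text contains proxies that a
#' propensity model can exploit.
#'
#' Outcome times are exponential (constant hazard) with log-hazard
#' `log(baseline_hazard) + true_log_hr * [COX-2] + confounder_log_hr * risk`,
#' observed only when they fall inside the patient's exposure episode. A
#' configurable fraction of patients receives a free-text drug-name mention
#' before first prescription, to exercise the free-text washout rule
#' downstream.
#'
#' @param config a [sim_config()] object
#' @return a list with components `records` (an `ehr_dataset`: data.tables
#'   `patients`, `prescriptions`, `notes`, `outcomes`) and `truth` (an
#'   `ehr_truth`: per-patient latent risk and assigned class, the true log
#'   hazard ratio, and a config echo). Ground truth is carried separately so
#'   the analysis pipeline cannot read it by accident.
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(n_patients = 50, seed = 7))
#' nrow(sim$records$patients)
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  ## --- patients -----------------------------------------------------------
  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.45, 0.55))
  enrollment_start <- as.Date("1996-01-01") +
    floor(stats::runif(n, 0, 365.25 * 13))
  span <- floor(stats::runif(n, 3 * 365, 16 * 365))
  enrollment_end <- pmin(enrollment_start + span, as.Date("2013-12-31"))
  span <- as.integer(enrollment_end - enrollment_start)

  # first NSAID prescription, placed so eligibility windows fit
  first_rx <- enrollment_start +
    floor(stats::runif(n, 560, pmax(561, span - 65)))
  age_at_rx <- pmin(pmax(round(stats::rnorm(n, 52, 17)), 18), 95)
  birth_year <- as.integer(format(first_rx, "%Y")) - age_at_rx
  aspirin <- stats::rbinom(n, 1, config$aspirin_prevalence)

  latent_risk <- 0.35 * (age_at_rx - 50) / 15 + 0.6 * aspirin +
    stats::rnorm(n)
  p_cox2 <- stats::plogis(config$cox2_base_logit +
                            config$channeling_strength * latent_risk)
  cox2 <- stats::rbinom(n, 1, p_cox2)
  assigned_class <- ifelse(cox2 == 1, "COX2", "NSNSAID")

  patients <- data.table::data.table(
    patient_id = patient_id, birth_year = birth_year, sex = sex,
    enrollment_start = enrollment_start, enrollment_end = enrollment_end,
    aspirin_exposed = as.integer(aspirin)
  )

  ## --- prescriptions ------------------------------------------------------
  n_rx <- 1L + stats::rpois(n, 1.0)
  rx <- data.table::data.table(
    patient_id = rep(patient_id, n_rx),
    k = sequence(n_rx),
    first_rx = rep(first_rx, n_rx),
    assigned = rep(assigned_class, n_rx),
    enroll_end = rep(enrollment_end, n_rx)
  )
  m <- nrow(rx)
  rx[, duration := pmax(5L, stats::rpois(m, config$rx_duration_days))]
  rx[, gap := ifelse(k == 1L, 0L, floor(stats::runif(m, 0, 50)))]
  rx[, sw_draw := k > 1L & stats::runif(m) < config$switch_prob]
  rx[, switched := cumsum(sw_draw) > 0, by = "patient_id"]
  rx[, class := ifelse(
    switched,
    ifelse(assigned == "COX2", "NSNSAID", "COX2"),
    assigned
  )]
  # sequential placement: each prescription starts `gap` days after the
  # previous one ends
  rx[, date := first_rx + cumsum(duration) - duration + cumsum(gap),
     by = "patient_id"]
  rx[, end := date + duration]
  rx[, daily_dose := sample(1:3, m, replace = TRUE)]
  rx[, quantity := duration * daily_dose]
  rx[, atc_code := ifelse(class == "COX2",
                          sample(.COX2_ATC, m, replace = TRUE),
                          sample(.NSNSAID_ATC, m, replace = TRUE))]

  ## --- true exposure episode end (for outcome observation) ----------------
  # chain rule: a prescription continues the first episode when it starts
  # within 30 days of the previous one's end; a class switch truncates.
  rx[, brk := k > 1L & gap > 30L]
  rx[, sw := k > 1L & !brk & class != class[1L], by = "patient_id"]
  rx[, stopidx := {
    i <- which(brk | sw)
    if (length(i)) i[1L] else NA_integer_
  }, by = "patient_id"]
  exposure <- rx[, {
    if (is.na(stopidx[1L])) {
      list(exp_end = max(end))
    } else {
      i <- stopidx[1L]
      if (sw[i]) list(exp_end = date[i]) else list(exp_end = max(end[seq_len(i - 1L)]))
    }
  }, by = "patient_id"]
  exposure[, exp_end := pmin(exp_end,
                             patients$enrollment_end[match(patient_id,
                                                           patients$patient_id)])]

  prescriptions <- rx[date <= enroll_end,
                      list(patient_id, date, atc_code, quantity, daily_dose)]
  data.table::setorder(prescriptions, patient_id, date, atc_code)

  ## --- outcome events -----------------------------------------------------
  rate <- config$baseline_hazard *
    exp(config$true_log_hr * cox2 + config$confounder_log_hr * latent_risk)
  t_event <- ceiling(stats::rexp(n, rate))
  event_date <- first_rx + t_event
  exp_end_by_patient <- exposure$exp_end[match(patient_id,
                                               exposure$patient_id)]
  observed <- event_date <= exp_end_by_patient & event_date <= enrollment_end
  outcomes <- data.table::data.table(
    patient_id = patient_id[observed],
    event_date = event_date[observed]
  )
  data.table::setorder(outcomes, patient_id)

  ## --- notes --------------------------------------------------------------
  n_notes <- stats::rpois(n, config$notes_per_patient_mean)
  notes <- data.table::data.table(
    patient_id = rep(patient_id, n_notes),
    risk = rep(latent_risk, n_notes),
    first_rx = rep(first_rx, n_notes),
    lo = rep(pmax(enrollment_start, first_rx - 360L), n_notes)
  )
  nn <- nrow(notes)
  notes[, date := lo + floor(stats::runif(nn) *
                               pmax(1, as.integer(first_rx - lo)))]
  notes[, note_id := seq_len(nn)]

  # token sampling: proxy-vs-noise block first (per-token Bernoulli with a
  # per-note probability), then a uniform index within the block
  n_tok <- stats::rpois(nn, config$words_per_note_mean)
  tok <- data.table::data.table(
    note_id = rep(notes$note_id, n_tok),
    risk = rep(notes$risk, n_tok)
  )
  nt <- nrow(tok)
  npx <- config$n_proxy_words
  nnoise <- config$vocab_size - npx
  if (nt > 0) {
    w_proxy <- npx * exp(config$proxy_strength * tok$risk)
    p_proxy <- if (npx == 0) rep(0, nt) else w_proxy / (w_proxy + nnoise)
    is_proxy <- stats::runif(nt) < p_proxy
    idx <- integer(nt)
    idx[is_proxy] <- sample.int(max(npx, 1L), sum(is_proxy), replace = TRUE)
    idx[!is_proxy] <- npx + sample.int(max(nnoise, 1L), sum(!is_proxy),
                                       replace = TRUE)
    tok[, token := sprintf("w%06d", idx)]
  } else {
    tok[, token := character(0)]
  }

  # dirty tokens exercising the normalizer (stop words, punctuation,
  # symbol-initial strings)
  n_dirty <- stats::rpois(nn, config$dirty_token_rate)
  nd <- sum(n_dirty)
  dirty <- data.table::data.table(
    note_id = rep(notes$note_id, n_dirty),
    token = if (nd > 0) sample(.DIRTY_TOKENS, nd, replace = TRUE)
            else character(0)
  )
  all_tok <- data.table::rbindlist(list(tok[, list(note_id, token)], dirty))
  data.table::setorder(all_tok, note_id)
  texts <- all_tok[, list(text = paste(token, collapse = " ")),
                   by = "note_id"]
  notes <- merge(notes, texts, by = "note_id", all.x = TRUE)
  notes[is.na(text), text := ""]

  note_tbl <- notes[, list(patient_id, date, text)]

  # free-text drug-name mentions before first prescription (washout probe)
  mentioned <- which(stats::runif(n) < config$mention_fraction)
  if (length(mentioned)) {
    mdate <- first_rx[mentioned] -
      (5L + floor(stats::runif(length(mentioned)) * 146))
    mdate <- pmax(mdate, enrollment_start[mentioned])
    mention_notes <- data.table::data.table(
      patient_id = patient_id[mentioned],
      date = mdate,
      text = paste("patient kreeg",
                   sample(.DRUG_NAMES, length(mentioned), replace = TRUE),
                   "voorgeschreven")
    )
    note_tbl <- data.table::rbindlist(list(note_tbl, mention_notes))
  }
  data.table::setorder(note_tbl, patient_id, date, text)

  records <- structure(
    list(patients = patients, prescriptions = prescriptions,
         notes = note_tbl, outcomes = outcomes),
    class = "ehr_dataset"
  )
  truth <- structure(
    list(
      per_patient = data.table::data.table(
        patient_id = patient_id, latent_risk = latent_risk,
        assigned_class = assigned_class
      ),
      true_log_hr = config$true_log_hr,
      config = unclass(config)
    ),
    class = "ehr_truth"
  )
  list(records = records, truth = truth)
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat(sprintf(
    "<ehr_dataset> %d patients, %d prescriptions, %d notes, %d outcome events\n",
    nrow(x$patients), nrow(x$prescriptions), nrow(x$notes), nrow(x$outcomes)
  ))
  invisible(x)
}

#' @export
print.ehr_truth <- function(x, ...) {
  cat(sprintf("<ehr_truth> %d patients, true log HR = %.4f (HR %.3f)\n",
              nrow(x$per_patient), x$true_log_hr, exp(x$true_log_hr)))
  invisible(x)
}

#' Default NSAID drug-name lexicon
#'
#' Lowercase drug names corresponding to the NSAID-related ATC codes used by
#' the generator; used for the free-text washout rule.
#'
#' @return character vector of lowercase drug names
#' @export
default_lexicon <- function() .DRUG_NAMES

#' Default ATC-to-class map
#'
#' Partition of NSAID ATC codes into the selective COX-2 inhibitor class and
#' the nonselective NSAID class, read from the packaged
#' `extdata/atc_classes.yaml` (the same YAML format accepted for custom
#' maps), with a hardcoded fallback matching the generator's code pools.
#'
#' @return named list with character vectors `COX2` and `NSNSAID`
#' @export
default_atc_map <- function() {
  f <- system.file("extdata", "atc_classes.yaml", package = "textps")
  if (nzchar(f)) {
    m <- yaml::read_yaml(f)
    return(list(COX2 = as.character(m$COX2),
                NSNSAID = as.character(m$NSNSAID)))
  }
  list(COX2 = .COX2_ATC, NSNSAID = .NSNSAID_ATC)
}
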