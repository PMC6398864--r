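# New-user NSAID episode construction.
#
# Episode rules: a candidate first prescription starts an episode only if the
# patient is an adult (>= 18), enrolled for >= 365 days, has >= 183 days of
# data before the start, and has neither an NSAID prescription (either class)
# nor a free-text drug-name mention in the 183 days before the start
# (half-open window [start - 183, start)). Consecutive same-class
# prescriptions chain when the next starts within 30 days of the previous
# one's end; a prescription of the opposite class truncates the episode at
# the switch date. The episode interval is closed [start, end] for outcome
# attachment.

#' Duration of one prescription in days
#'
#' Quantity divided by the daily-dose regimen, rounded half up to whole days;
#' durations under one day are clamped to one day.
#'
#' @param quantity prescribed quantity (units), > 0
#' @param daily_dose daily dose regimen (units/day), > 0
#' @return integer days (vectorized)
#' @export
#' @examples
#' prescription_duration(30, 1) # 30
#' prescription_duration(20, 3) # 7
prescription_duration <- function(quantity, daily_dose) {
  assert_that(all(quantity > 0), "quantity must be > 0")
  assert_that(all(daily_dose > 0), "daily_dose must be > 0")
  round_days(quantity / daily_dose)
}

#' Detect free-text drug-name mentions inside a time window
#'
#' TRUE iff any note dated in `[window_start, window_end)` contains, after
#' text normalization, a token equal to a lexicon entry. Used for the
#' free-text washout rule: new-user episodes require no NSAID drug-name
#' mention in the six months before the start.
#'
#' @param notes data.frame/data.table with columns `date`, `text`
#' @param lexicon nonempty character vector of lowercase drug names
#' @param window_start,window_end window dates; half-open `[start, end)`
#' @return logical flag
#' @export
detect_drug_mentions <- function(notes, lexicon, window_start, window_end) {
  assert_that(length(lexicon) > 0, "lexicon must be nonempty")
  if (is.null(notes) || nrow(notes) == 0) return(FALSE)
  window_start <- as_date_safe(window_start)
  window_end <- as_date_safe(window_end)
  dates <- as_date_safe(notes$date)
  inwin <- dates >= window_start & dates < window_end
  if (!any(inwin)) return(FALSE)
  toks <- normalize_text(notes$text[inwin], stop_words = character(0))
  any(vapply(toks, function(tt) any(tt %in% lexicon), logical(1)))
}

# Per-note mention flags for a whole notes table, using the same normalizer
# as detect_drug_mentions. Returns the notes rows that mention the lexicon.
mention_dates <- function(notes, lexicon) {
  if (is.null(notes) || nrow(notes) == 0 || length(lexicon) == 0) {
    return(data.table::data.table(patient_id = character(0),
                                  date = as.Date(character(0))))
  }
  # fast pre-filter: only normalize notes whose raw text contains a lexicon
  # word as a substring
  raw <- tolower(notes$text)
  cand <- which(Reduce(`|`, lapply(lexicon, function(w) {
    grepl(w, raw, fixed = TRUE)
  })))
  if (!length(cand)) {
    return(data.table::data.table(patient_id = character(0),
                                  date = as.Date(character(0))))
  }
  toks <- normalize_text(notes$text[cand], stop_words = character(0))
  hit <- vapply(toks, function(tt) any(tt %in% lexicon), logical(1))
  data.table::data.table(patient_id = notes$patient_id[cand][hit],
                         date = as_date_safe(notes$date[cand][hit]))
}

#' Build new-user NSAID treatment episodes
#'
#' Applies the new-user episode rules (adult age, one-year enrollment,
#' six-month data availability, six-month prescription and free-text washout,
#' 30-day chaining grace period, switch truncation) to an EHR dataset and
#' returns one row per episode. The episode class is that of its first
#' prescription. The first outcome event falling inside the closed episode
#' interval is attached; follow-up ends at the event or the episode end,
#' whichever is first.
#'
#' Prescriptions whose ATC code is in neither class of `atc_class_map` are
#' skipped with a warning. Same-day prescriptions of both classes at a
#' candidate start are ambiguous and produce no episode.
#'
#' @param records an `ehr_dataset`
#' @param atc_class_map list with character vectors `COX2` and `NSNSAID`
#' @param lexicon lowercase drug-name lexicon for the free-text washout;
#'   empty vector disables the rule
#' @param washout_days,enrollment_days,grace_days rule windows in days
#' @return data.table of episodes (`episode_id`, `patient_id`, `class_label`,
#'   `start_date`, `end_date`, `age_at_start`, `sex`, `aspirin_exposed`,
#'   `outcome_date`, `event`, `follow_up_days`)
#' @export
build_episodes <- function(records, atc_class_map = default_atc_map(),
                           lexicon = default_lexicon(),
                           washout_days = 183L, enrollment_days = 365L,
                           grace_days = 30L) {
  assert_that(inherits(records, "ehr_dataset"), "records must be an ehr_dataset")
  rx <- data.table::as.data.table(records$prescriptions)
  if (nrow(rx) == 0) return(empty_episode_table())
  rx[, date := as_date_safe(date)]

  cls <- rep(NA_character_, nrow(rx))
  cls[rx$atc_code %in% atc_class_map$COX2] <- "COX2"
  cls[rx$atc_code %in% atc_class_map$NSNSAID] <- "NSNSAID"
  if (anyNA(cls)) {
    warning(sprintf("skipping %d prescription(s) with unknown ATC code",
                    sum(is.na(cls))))
    rx <- rx[!is.na(cls)]
    cls <- cls[!is.na(cls)]
  }
  if (nrow(rx) == 0) return(empty_episode_table())
  rx[, class := cls]
  rx[, dur := prescription_duration(quantity, daily_dose)]
  rx[, end := date + dur]
  data.table::setorder(rx, patient_id, date, class)

  mentions <- mention_dates(records$notes, lexicon)
  outc <- data.table::as.data.table(records$outcomes)
  if (nrow(outc)) outc[, event_date := as_date_safe(event_date)]

  pat <- data.table::as.data.table(records$patients)
  pat[, enrollment_start := as_date_safe(enrollment_start)]
  pat[, enrollment_end := as_date_safe(enrollment_end)]

  # group prescriptions by patient via index ranges on the sorted table
  grp <- rx[, list(i0 = .I[1L], i1 = .I[.N]), by = "patient_id"]
  men_by_pat <- split(mentions$date, mentions$patient_id)
  out_by_pat <- if (nrow(outc)) split(outc$event_date, outc$patient_id)
                else list()
  pat_idx <- match(grp$patient_id, pat$patient_id)
  rx_date <- rx$date
  rx_class <- rx$class
  rx_end <- rx$end
  start_year <- data.table::year(rx_date)

  res <- vector("list", nrow(grp))
  for (i in seq_len(nrow(grp))) {
    if (is.na(pat_idx[i])) next
    idx <- grp$i0[i]:grp$i1[i]
    pid <- grp$patient_id[i]
    k <- pat_idx[i]
    res[[i]] <- patient_episodes(
      rx_date[idx], rx_class[idx], rx_end[idx], start_year[idx],
      birth_year = pat$birth_year[k], sex = pat$sex[k],
      aspirin = pat$aspirin_exposed[k],
      enroll_start = pat$enrollment_start[k],
      enroll_end = pat$enrollment_end[k],
      patient_id = pid,
      mention_dt = men_by_pat[[pid]], outcome_dt = sort(out_by_pat[[pid]]),
      washout_days = washout_days, enrollment_days = enrollment_days,
      grace_days = grace_days
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_episode_table())
  eps <- data.table::rbindlist(res)
  eps[, start_date := as.Date(start_date, origin = "1970-01-01")]
  eps[, end_date := as.Date(end_date, origin = "1970-01-01")]
  eps[, outcome_date := as.Date(outcome_date, origin = "1970-01-01")]
  if (nrow(eps) == 0) return(empty_episode_table())
  data.table::setorder(eps, patient_id, start_date)
  eps[, episode_id := sprintf("E%06d", seq_len(.N))]
  data.table::setcolorder(eps, c("episode_id", "patient_id", "class_label",
                                 "start_date", "end_date", "age_at_start",
                                 "sex", "aspirin_exposed", "outcome_date",
                                 "event", "follow_up_days"))
  eps[]
}

empty_episode_table <- function() {
  data.table::data.table(
    episode_id = character(0), patient_id = character(0),
    class_label = character(0), start_date = as.Date(character(0)),
    end_date = as.Date(character(0)), age_at_start = integer(0),
    sex = character(0), aspirin_exposed = integer(0),
    outcome_date = as.Date(character(0)), event = logical(0),
    follow_up_days = integer(0)
  )
}

# Episode state machine for one patient's (sorted) prescriptions. Dates are
# handled as numeric day counts for speed; the caller converts back.
patient_episodes <- function(rx_date, rx_class, rx_end, start_year,
                             birth_year, sex, aspirin, enroll_start,
                             enroll_end, patient_id, mention_dt, outcome_dt,
                             washout_days, enrollment_days, grace_days) {
  n <- length(rx_date)
  rx_date <- as.numeric(rx_date)
  rx_end <- as.numeric(rx_end)
  enroll_start <- as.numeric(enroll_start)
  enroll_end <- as.numeric(enroll_end)
  mention_dt <- as.numeric(mention_dt)
  outcome_dt <- as.numeric(outcome_dt)
  starts <- ends <- fup <- odates <- numeric(0)
  classes <- character(0)
  ages <- integer(0)
  events <- logical(0)
  i <- 1L
  while (i <= n) {
    s <- rx_date[i]
    sameday <- which(rx_date == s)
    if (length(unique(rx_class[sameday])) > 1L) {
      # ambiguous first class: no episode from this day
      i <- max(sameday) + 1L
      next
    }
    age <- start_year[i] - birth_year
    ok <- age >= 18L &&
      s >= enroll_start + enrollment_days &&
      s >= enroll_start + washout_days &&
      s <= enroll_end &&
      !any(rx_date >= s - washout_days & rx_date < s) &&
      (length(mention_dt) == 0 ||
         !any(mention_dt >= s - washout_days & mention_dt < s))
    if (!ok) {
      i <- i + 1L
      next
    }
    # chain same-class prescriptions; opposite class truncates
    cls <- rx_class[i]
    cur_end <- rx_end[i]
    j <- i + 1L
    while (j <= n && rx_date[j] <= cur_end + grace_days) {
      if (rx_class[j] == cls) {
        cur_end <- max(cur_end, rx_end[j])
        j <- j + 1L
      } else {
        cur_end <- rx_date[j]
        break
      }
    }
    e <- min(cur_end, enroll_end)
    if (e >= s) {
      ev <- outcome_dt[outcome_dt >= s & outcome_dt <= e]
      has_ev <- length(ev) > 0
      od <- if (has_ev) ev[1L] else NA_real_
      starts <- c(starts, s)
      ends <- c(ends, e)
      classes <- c(classes, cls)
      ages <- c(ages, as.integer(age))
      odates <- c(odates, od)
      events <- c(events, has_ev)
      fup <- c(fup, (if (has_ev) od else e) - s)
    }
    i <- j
  }
  if (!length(starts)) return(NULL)
  list(patient_id = rep(patient_id, length(starts)), class_label = classes,
       start_date = starts, end_date = ends, age_at_start = ages,
       sex = rep(sex, length(starts)),
       aspirin_exposed = rep(aspirin, length(starts)),
       outcome_date = odates, event = events,
       follow_up_days = as.integer(fup))
}
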