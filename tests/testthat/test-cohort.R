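test_that("prescription_duration divides, rounds half up, clamps to 1 day", {
  expect_equal(prescription_duration(30, 1), 30L)
  expect_equal(prescription_duration(60, 2), 30L)
  # 20/3 = 6.67 -> 7 under round-half-up
  expect_equal(prescription_duration(20, 3), 7L)
  expect_equal(prescription_duration(c(1, 15), c(4, 2)), c(1L, 8L))
  expect_error(prescription_duration(0, 1), "quantity")
  expect_error(prescription_duration(10, 0), "daily_dose")
})

test_that("detect_drug_mentions is case-insensitive and window-aware", {
  notes <- data.frame(patient_id = "P1", date = day0 - 100,
                      text = "patient kreeg Ibuprofen")
  expect_true(detect_drug_mentions(notes, c("ibuprofen"),
                                   day0 - 183, day0))
  # one day before the window opens
  notes$date <- day0 - 184
  expect_false(detect_drug_mentions(notes, c("ibuprofen"),
                                    day0 - 183, day0))
  # wrong drug
  notes$date <- day0 - 100
  expect_false(detect_drug_mentions(notes, c("naproxen"),
                                    day0 - 183, day0))
  expect_false(detect_drug_mentions(notes[0, ], c("ibuprofen"),
                                    day0 - 183, day0))
})

test_that("continuation rule chains prescriptions into one episode", {
  ds <- make_dataset(base_patient(),
                     rbind(rx_row("P1", 0), rx_row("P1", 25)))
  eps <- build_episodes(ds)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$start_date, day0)
  expect_equal(eps$end_date, day0 + 55)
  expect_equal(eps$class_label, "NSNSAID")
})

test_that("a gap beyond 30 days ends the episode and washout blocks a new one", {
  ds <- make_dataset(base_patient(),
                     rbind(rx_row("P1", 0), rx_row("P1", 70)))
  eps <- build_episodes(ds)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$end_date, day0 + 30)
})

test_that("a class switch truncates the episode at the switch date", {
  ds <- make_dataset(base_patient(),
                     rbind(rx_row("P1", 0),
                           rx_row("P1", 10, atc = "M01AH01")))
  eps <- build_episodes(ds)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$class_label, "NSNSAID")
  expect_equal(eps$end_date, day0 + 10)
})

test_that("eligibility rules: age, enrollment, free-text mention", {
  # under 18 at start
  ds <- make_dataset(base_patient(birth_year = 1990), rx_row("P1", 0))
  expect_equal(nrow(build_episodes(ds)), 0)
  # enrolled < 1 year before start
  pat <- base_patient()
  pat$enrollment_start <- day0 - 200
  ds <- make_dataset(pat, rx_row("P1", 0))
  expect_equal(nrow(build_episodes(ds)), 0)
  # drug-name mention in the washout window
  ds <- make_dataset(
    base_patient(), rx_row("P1", 0),
    notes = data.frame(patient_id = "P1", date = day0 - 30,
                       text = "gebruikt Naproxen dagelijks")
  )
  expect_equal(nrow(build_episodes(ds)), 0)
  # same mention, outside the window
  ds$notes$date <- day0 - 184
  expect_equal(nrow(build_episodes(ds)), 1)
  # removing the lexicon never decreases the episode count
  ds$notes$date <- day0 - 30
  expect_equal(nrow(build_episodes(ds, lexicon = character(0))), 1)
})

test_that("same-day prescriptions of both classes produce no episode", {
  ds <- make_dataset(base_patient(),
                     rbind(rx_row("P1", 0), rx_row("P1", 0, atc = "M01AH01")))
  expect_equal(nrow(build_episodes(ds)), 0)
})

test_that("unknown ATC codes are skipped with a warning", {
  ds <- make_dataset(base_patient(),
                     rbind(rx_row("P1", 0), rx_row("P1", 5, atc = "X99XX99")))
  expect_warning(eps <- build_episodes(ds), "unknown ATC")
  expect_equal(nrow(eps), 1)
})

test_that("outcome attachment respects the closed episode interval", {
  out_in <- data.frame(patient_id = "P1", event_date = day0 + 30)
  ds <- make_dataset(base_patient(), rx_row("P1", 0), outcomes = out_in)
  eps <- build_episodes(ds)
  expect_true(eps$event)
  expect_equal(eps$follow_up_days, 30L)
  # event one day after the episode end is censored
  ds$outcomes$event_date <- day0 + 31
  eps <- build_episodes(ds)
  expect_false(eps$event)
  expect_equal(eps$follow_up_days, 30L)
})

test_that("episodes match the day-by-day oracle on randomized patients", {
  set.seed(2024)
  n_checked <- 0L
  for (rep in 1:60) {
    parts <- lapply(sprintf("Q%03d", 1:5), random_patient_inputs)
    ds <- make_dataset(
      data.table::rbindlist(lapply(parts, `[[`, "pat")),
      data.table::rbindlist(lapply(parts, `[[`, "rx")),
      {
        nt <- data.table::rbindlist(Filter(Negate(is.null),
                                           lapply(parts, `[[`, "notes")))
        if (nrow(nt)) nt else NULL
      },
      {
        ot <- data.table::rbindlist(Filter(Negate(is.null),
                                           lapply(parts, `[[`, "outcomes")))
        if (nrow(ot)) ot else NULL
      }
    )
    got <- build_episodes(ds)
    want <- oracle_build_episodes(ds)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$patient_id, want$start_date), ]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$patient_id, want$patient_id)
      expect_equal(got$class_label, want$class_label)
      expect_equal(as.integer(got$start_date),
                   as.integer(want$start_date))
      expect_equal(as.integer(got$end_date), as.integer(want$end_date))
      expect_equal(got$event, want$event)
      expect_equal(got$follow_up_days, want$follow_up_days)
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 50)
})

test_that("episode invariants hold on simulated data", {
  sim <- small_sim()
  eps <- build_episodes(sim$records)
  expect_gt(nrow(eps), 0)
  expect_true(all(eps$start_date <= eps$end_date))
  expect_true(all(eps$age_at_start >= 18))
  expect_true(all(eps$follow_up_days >= 0))
  expect_true(all(eps$event ==
                    (!is.na(eps$outcome_date) &
                       eps$outcome_date >= eps$start_date &
                       eps$outcome_date <= eps$end_date)))
  # per-patient episodes never overlap
  by_pat <- split(eps, eps$patient_id)
  overlaps <- vapply(by_pat, function(e) {
    if (nrow(e) < 2) return(FALSE)
    e <- e[order(e$start_date), ]
    any(e$start_date[-1] <= e$end_date[-nrow(e)])
  }, logical(1))
  expect_false(any(overlaps))
  # washout: no prescription in the 183 days before any start
  rx <- sim$records$prescriptions
  clean <- vapply(seq_len(nrow(eps)), function(i) {
    p <- rx[rx$patient_id == eps$patient_id[i], ]
    !any(p$date >= eps$start_date[i] - 183 & p$date < eps$start_date[i])
  }, logical(1))
  expect_true(all(clean))
})
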