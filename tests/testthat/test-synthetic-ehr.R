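test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(n_patients = 10, seed = 1), "sim_config")
  expect_error(sim_config(vocab_size = 10, n_proxy_words = 20),
               "vocab_size")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
  expect_error(sim_config(baseline_hazard = NaN), "finite")
  expect_error(sim_config(aspirin_prevalence = 1.2), "aspirin_prevalence")
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_patients = 120, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$per_patient, b$truth$per_patient)
  c <- generate_cohort(sim_config(n_patients = 120, seed = 78))
  expect_false(identical(a$records$notes, c$records$notes))
})

test_that("record invariants hold: dates inside enrollment, positive doses", {
  sim <- small_sim()
  rec <- sim$records
  pat <- rec$patients
  rng <- function(tbl, col) {
    i <- match(tbl$patient_id, pat$patient_id)
    list(lo = pat$enrollment_start[i], hi = pat$enrollment_end[i])
  }
  r <- rng(rec$prescriptions)
  expect_true(all(rec$prescriptions$date >= r$lo &
                    rec$prescriptions$date <= r$hi))
  r <- rng(rec$notes)
  expect_true(all(rec$notes$date >= r$lo & rec$notes$date <= r$hi))
  r <- rng(rec$outcomes)
  expect_true(all(rec$outcomes$event_date >= r$lo &
                    rec$outcomes$event_date <= r$hi))
  expect_true(all(rec$prescriptions$quantity > 0))
  expect_true(all(rec$prescriptions$daily_dose > 0))
})

test_that("channeling raises latent risk among COX-2 initiators", {
  sim <- generate_cohort(sim_config(n_patients = 2000, seed = 9,
                                    channeling_strength = 1.5))
  tr <- sim$truth$per_patient
  expect_gt(mean(tr$latent_risk[tr$assigned_class == "COX2"]),
            mean(tr$latent_risk[tr$assigned_class == "NSNSAID"]))
})

test_that("null channeling and null effect give balanced classes and rates", {
  sim <- generate_cohort(sim_config(n_patients = 4000, seed = 10,
                                    channeling_strength = 0,
                                    true_log_hr = 0))
  tr <- sim$truth$per_patient
  risk_diff <- mean(tr$latent_risk[tr$assigned_class == "COX2"]) -
    mean(tr$latent_risk[tr$assigned_class == "NSNSAID"])
  expect_lt(abs(risk_diff), 0.1)
  # empirical outcome rates equal between classes within Monte-Carlo error
  has_event <- tr$patient_id %in% sim$records$outcomes$patient_id
  p <- prop.test(
    c(sum(has_event[tr$assigned_class == "COX2"]),
      sum(has_event[tr$assigned_class == "NSNSAID"])),
    c(sum(tr$assigned_class == "COX2"), sum(tr$assigned_class == "NSNSAID"))
  )$p.value
  expect_gt(p, 0.001)
})

test_that("proxy_strength = 0 decouples words from treatment class", {
  sim <- generate_cohort(sim_config(n_patients = 1500, seed = 12,
                                    proxy_strength = 0,
                                    vocab_size = 200, n_proxy_words = 40))
  tr <- sim$truth$per_patient
  eps <- build_episodes(sim$records)
  fm <- build_bow(eps, sim$records$notes)
  proxies <- intersect(sprintf("w%06d", 1:40), covariate_labels(fm))
  y <- eps$class_label == "COX2"
  pvals <- vapply(proxies, function(w) {
    pres <- as.numeric(fm$m[, w] > 0)
    suppressWarnings(stats::chisq.test(table(pres, y), correct = FALSE)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01, na.rm = TRUE), 0.9)
})

test_that("proxy-word document frequency tracks latent risk", {
  sim <- generate_cohort(sim_config(n_patients = 5000, seed = 13))
  eps <- build_episodes(sim$records)
  fm <- build_bow(eps, sim$records$notes)
  tr <- sim$truth$per_patient
  risk <- tr$latent_risk[match(eps$patient_id, tr$patient_id)]
  proxies <- intersect(sprintf("w%06d", 1:100), covariate_labels(fm))
  n_proxy_present <- Matrix::rowSums(fm$m[, proxies, drop = FALSE] > 0)
  ct <- suppressWarnings(
    stats::cor.test(n_proxy_present, risk, method = "spearman")
  )
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("a fraction of patients get pre-exposure drug-name mentions", {
  sim <- generate_cohort(sim_config(n_patients = 800, seed = 14,
                                    mention_fraction = 0.2))
  men <- textps:::mention_dates(sim$records$notes, default_lexicon())
  expect_gt(length(unique(men$patient_id)), 0.1 * 800)
  sim0 <- generate_cohort(sim_config(n_patients = 300, seed = 15,
                                     mention_fraction = 0))
  men0 <- textps:::mention_dates(sim0$records$notes, default_lexicon())
  expect_equal(nrow(men0), 0)
})

test_that("write_dataset round-trips through read_dataset", {
  sim <- generate_cohort(sim_config(n_patients = 60, seed = 16))
  dir <- withr::local_tempdir()
  write_dataset(sim$records, sim$truth, dir)
  back <- read_dataset(dir, with_truth = TRUE)
  expect_equal(as.data.frame(back$records$patients),
               as.data.frame(sim$records$patients))
  expect_equal(as.data.frame(back$records$prescriptions),
               as.data.frame(sim$records$prescriptions))
  expect_equal(as.data.frame(back$records$notes),
               as.data.frame(sim$records$notes))
  expect_equal(as.data.frame(back$records$outcomes),
               as.data.frame(sim$records$outcomes))
  expect_equal(back$truth$true_log_hr, sim$truth$true_log_hr)
  expect_equal(back$truth$per_patient$latent_risk,
               sim$truth$per_patient$latent_risk)
})

test_that("write_dataset handles hand-built and note-free datasets", {
  dir <- withr::local_tempdir()
  ds <- make_dataset(rbind(base_patient("P1"), base_patient("P2"),
                           base_patient("P3")),
                     prescriptions = rx_row("P1", 0))
  write_dataset(ds, NULL, dir)
  back <- read_dataset(dir)
  expect_equal(nrow(back$patients), 3)
  expect_equal(nrow(back$notes), 0)
  expect_equal(nrow(back$prescriptions), 1)
})
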