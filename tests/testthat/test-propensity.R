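toy_fm <- function(x) {
  rownames(x) <- sprintf("E%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("v%d", seq_len(ncol(x)))
  feature_matrix(x)
}

test_that("fit_ps shrinks monotonically with the penalty", {
  set.seed(41)
  n <- 200
  z <- rbinom(n, 1, 0.5)
  x <- cbind(z, rbinom(n, 1, 0.4))
  fm <- toy_fm(x)
  y <- as.logical(z)
  lams <- c(0.01, 1, 5, 20, 60)
  l1 <- vapply(lams, function(l) {
    sum(abs(fit_ps(fm, y, penalty = l, penalty_scale = "l1")$coefficients))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
  expect_gt(l1[1], l1[5])
})

test_that("fit_ps on independent data gives small coefficients and calibrated scores", {
  set.seed(42)
  n <- 2000
  x <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
  fm <- toy_fm(x)
  y <- rbinom(n, 1, 0.3) == 1
  mod <- fit_ps(fm, y, penalty = 5, penalty_scale = "l1")
  expect_true(all(abs(mod$coefficients) < 0.5))
  expect_equal(mean(score(mod, fm)), mean(y), tolerance = 0.02)
  # zero columns stay at zero
  x2 <- cbind(x, 0)
  fm2 <- toy_fm(x2)
  mod2 <- fit_ps(fm2, y)
  expect_equal(mod2$coefficients[6], 0)
})

test_that("fit_ps attains the grid-search optimum on 2-covariate toys", {
  set.seed(43)
  for (rep in 1:3) {
    n <- 120
    x <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.3))
    y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x[, 1] - 0.6 * x[, 2]))
    fm <- toy_fm(x)
    pen <- c(0.5, 2, 6)[rep]
    mod <- fit_ps(fm, y == 1, penalty = pen, penalty_scale = "l1")
    got <- textps:::ps_objective(mod$coefficients, mod$intercept, x, y, pen)
    grid <- oracle_grid_objective(x, y, pen)
    expect_gte(got, grid$objective - 1e-6)
  }
})

test_that("score applies the logistic formula and the zero-fill rule", {
  m <- structure(list(covariate_labels = c("a", "b", "c"),
                      coefficients = c(0.5, -0.9, 0.1), intercept = 0.2,
                      penalty = 0.01, converged = TRUE),
                 class = "ps_model")
  x <- cbind(a = c(1, 0, 1), b = c(0, 1, 1), c = c(1, 1, 0))
  rownames(x) <- sprintf("E%d", 1:3)
  fm <- feature_matrix(x)
  expect_equal(unname(score(m, fm)),
               plogis(c(0.2 + 0.5 + 0.1, 0.2 - 0.9 + 0.1, 0.2 + 0.5 - 0.9)),
               tolerance = 1e-12)
  # zero coefficients, zero intercept -> 0.5 everywhere
  m0 <- m
  m0$coefficients <- c(0, 0, 0)
  m0$intercept <- 0
  expect_true(all(score(m0, fm) == 0.5))
  # huge intercept -> scores approach 1
  m1 <- m0
  m1$intercept <- 40
  expect_true(all(score(m1, fm) > 1 - 1e-10))
  # model covariates absent from the matrix are zero-filled
  fm_sub <- feature_matrix(x[, "a", drop = FALSE])
  expect_equal(unname(score(m, fm_sub)), plogis(0.2 + 0.5 * x[, "a"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # complete mismatch errors
  fm_bad <- feature_matrix(matrix(1, 3, 1,
                                  dimnames = list(sprintf("E%d", 1:3), "zzz")))
  expect_error(score(m, fm_bad), "no model covariate")
})

test_that("auc equals the all-pairs enumeration oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.9, 0.2, 0.4, 0.6), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_equal(auc(rep(0.7, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(4:200, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- sample(round(runif(n), 2)) # coarse scores force ties
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-13)
  }
})

test_that("cross_validate is seeded, reproducible, and near 0.5 under the null", {
  set.seed(45)
  n <- 2000
  x <- matrix(rbinom(n * 20, 1, 0.2), n, 20)
  fm <- toy_fm(x)
  y <- rbinom(n, 1, 0.4) == 1
  cv1 <- cross_validate(fm, y, k = 3, seed = 7)
  cv2 <- cross_validate(fm, y, k = 3, seed = 7)
  expect_identical(cv1, cv2)
  expect_equal(cv1$mean_auc, mean(cv1$fold_aucs))
  expect_true(all(cv1$fold_aucs >= 0 & cv1$fold_aucs <= 1))
  expect_gt(cv1$mean_auc, 0.45)
  expect_lt(cv1$mean_auc, 0.55)
  expect_error(cross_validate(fm, y, k = 3), "seed")
})

test_that("top_covariates ranks by |beta| with deterministic ties", {
  m <- structure(list(covariate_labels = c("a", "b", "c", "d"),
                      coefficients = c(0.5, -0.9, 0.1, 0), intercept = 0,
                      penalty = 0.01, converged = TRUE),
                 class = "ps_model")
  top <- top_covariates(m, 2)
  expect_equal(top$label, c("b", "a"))
  # n larger than the covariate count returns all nonzero
  expect_equal(nrow(top_covariates(m, 100)), 3)
  # all-zero model -> empty
  m$coefficients <- rep(0, 4)
  expect_equal(nrow(top_covariates(m)), 0)
  # tie break by label
  m$coefficients <- c(0.3, -0.3, 0.3, 0)
  expect_equal(top_covariates(m, 3)$label, c("a", "b", "c"))
})

test_that("proxy words are enriched among top covariates in channeled data", {
  sim <- generate_cohort(sim_config(n_patients = 2500, seed = 46))
  eps <- build_episodes(sim$records)
  fm <- build_bow(eps, sim$records$notes)
  mod <- fit_ps(fm, eps$class_label == "COX2")
  top <- top_covariates(mod, 25)
  n_proxy_hits <- sum(top$label %in% sprintf("w%06d", 1:100))
  # chance rate: 100 proxies out of ~2000 words -> ~1.25 of 25
  expect_gt(n_proxy_hits, 5)
})

test_that("ps models round-trip through JSON", {
  sim <- small_sim()
  eps <- build_episodes(sim$records)
  fm <- build_bow(eps, sim$records$notes)
  mod <- fit_ps(fm, eps$class_label == "COX2")
  path <- file.path(withr::local_tempdir(), "m.json")
  write_ps_model(mod, path)
  back <- read_ps_model(path)
  expect_equal(back$coefficients, mod$coefficients)
  expect_equal(back$intercept, mod$intercept)
  expect_equal(score(back, fm), score(mod, fm))
})
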