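# L1-penalized logistic propensity model (Laplace prior), cross-validated
# AUC, and covariate ranking by weight.
#
# The penalized objective is the full binomial log-likelihood minus
# lambda * sum(|beta|), with an unpenalized intercept and unstandardized
# (binary 0/1) features. glmnet minimizes the per-observation deviance, so
# its lambda is this lambda divided by n.

#' Fit the L1-penalized logistic propensity model
#'
#' Maximizes `loglik(beta) - penalty * sum(|beta_j|)` for treatment-class
#' membership, with an unpenalized intercept. Features are not standardized
#' (they are 0/1 indicators). Covariates never seen in the data (all-zero
#' columns) keep a zero coefficient.
#'
#' The Laplace-prior hyper-parameter can be read on two scales. The default,
#' `penalty_scale = "prior_variance"`, follows the Bayesian-regression
#' parameterization in which the hyper-parameter is the prior variance
#' \eqn{\sigma^2} of each coefficient, giving a per-coefficient L1 weight
#' \eqn{\lambda = \sqrt{2/\sigma^2}} (so the default 0.01 yields
#' \eqn{\lambda \approx 14.1}); this is numerically well behaved at any
#' cohort size. `penalty_scale = "l1"` uses the value directly as the
#' per-coefficient L1 weight \eqn{\lambda}, which is the natural scale for
#' penalization-path experiments.
#'
#' @param fm a `feature_matrix`
#' @param treatment logical/0-1 vector (TRUE = COX-2) aligned to the rows
#' @param penalty Laplace-prior hyper-parameter; default 0.01
#' @param penalty_scale `"prior_variance"` (default) or `"l1"`; see Details
#' @return a `ps_model` with `covariate_labels`, `coefficients`, `intercept`,
#'   `penalty`, `lambda` (the per-coefficient L1 weight actually applied),
#'   and a `converged` flag
#' @export
fit_ps <- function(fm, treatment, penalty = 0.01,
                   penalty_scale = c("prior_variance", "l1")) {
  penalty_scale <- match.arg(penalty_scale)
  y <- as.integer(as.logical(treatment))
  n <- length(y)
  assert_that(n == nrow(fm$m), "treatment must align with matrix rows")
  assert_that(sum(y) >= 2 && sum(1 - y) >= 2,
              "need at least 2 episodes of each treatment class")
  assert_that(penalty > 0, "penalty must be > 0")
  lambda_coef <- if (penalty_scale == "prior_variance") sqrt(2 / penalty)
                 else penalty

  x <- fm$m
  pad <- ncol(x) < 2
  if (pad) {
    x <- cbind(x, Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0), dims = c(n, 1),
      dimnames = list(rownames(x), ".pad")
    ))
  }
  lam <- lambda_coef / n
  # short warm-start path down to the target lambda
  path <- lam * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-10, maxit = 1e6)
  beta <- as.numeric(fit$beta[, length(path)])
  intercept <- as.numeric(fit$a0[length(path)])
  labels <- colnames(x)
  if (pad) {
    keep <- labels != ".pad"
    beta <- beta[keep]
    labels <- labels[keep]
  }
  converged <- all(is.finite(beta)) && is.finite(intercept) &&
    max(abs(c(beta, intercept))) < 50
  if (!converged) {
    warning("fit_ps: possible non-convergence or separation ",
            "(extreme coefficients)")
  }
  structure(
    list(covariate_labels = labels, coefficients = beta,
         intercept = intercept, penalty = penalty,
         penalty_scale = penalty_scale, lambda = lambda_coef,
         converged = converged),
    class = "ps_model"
  )
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf(
    "<ps_model> %d covariates (%d nonzero), intercept %.4f, penalty %g\n",
    length(x$coefficients), sum(x$coefficients != 0), x$intercept, x$penalty
  ))
  invisible(x)
}

# Penalized objective of a ps_model configuration on given data; used by
# tests and diagnostics.
ps_objective <- function(beta, intercept, x, y, penalty) {
  eta <- as.numeric(x %*% beta) + intercept
  # numerically safe log(1 + exp(eta))
  lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  sum(y * eta - lse) - penalty * sum(abs(beta))
}

#' Propensity scores for a feature matrix
#'
#' `logistic(intercept + x . beta)`, in (0, 1). Model covariates missing from
#' the matrix are treated as zero (the zero-fill rule); matrix columns not in
#' the model are ignored. If no model covariate is present in the matrix at
#' all, the label sets are considered incompatible and an error is raised
#' (unless the model is intercept-only).
#'
#' @param model a `ps_model`
#' @param fm a `feature_matrix`
#' @return named numeric vector of scores, one per episode
#' @export
score <- function(model, fm) {
  labels <- model$covariate_labels
  common <- intersect(labels, colnames(fm$m))
  if (length(labels) > 0 && length(common) == 0 && ncol(fm$m) > 0) {
    stop("score: no model covariate found in the feature matrix", call. = FALSE)
  }
  eta <- rep(model$intercept, nrow(fm$m))
  if (length(common)) {
    b <- model$coefficients[match(common, labels)]
    eta <- eta + as.numeric(fm$m[, common, drop = FALSE] %*% b)
  }
  stats::setNames(stats::plogis(eta), rownames(fm$m))
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from ranks so that ties
#' are handled exactly.
#'
#' @param scores numeric scores
#' @param labels logical/0-1 class labels (TRUE = positive)
#' @return AUC in `[0, 1]`
#' @export
auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of the propensity model
#'
#' Randomly partitions episodes into `k` near-equal folds (seeded, not
#' stratified), fits the model on the other folds and evaluates AUC on each
#' held-out fold. If a partition leaves any fold without both classes it is
#' redrawn (up to 25 attempts), then an error is raised.
#'
#' @param fm a `feature_matrix`
#' @param treatment logical/0-1 treatment vector
#' @param k number of folds
#' @param seed RNG seed for the fold draw (mandatory for reproducibility)
#' @param penalty passed to [fit_ps()]
#' @return a `cv_report`: `fold_aucs`, `mean_auc`, `seed`
#' @export
cross_validate <- function(fm, treatment, k = 3, seed, penalty = 0.01,
                           penalty_scale = c("prior_variance", "l1")) {
  penalty_scale <- match.arg(penalty_scale)
  assert_that(!missing(seed), "seed is required")
  y <- as.logical(treatment)
  n <- length(y)
  assert_that(n >= k, "need n >= k")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- NULL
  for (try in 1:25) {
    f <- sample(rep(seq_len(k), length.out = n))
    ok <- all(vapply(seq_len(k), function(i) {
      sum(y[f != i]) >= 2 && sum(!y[f != i]) >= 2 &&
        any(y[f == i]) && any(!y[f == i])
    }, logical(1)))
    if (ok) {
      folds <- f
      break
    }
  }
  assert_that(!is.null(folds), "could not draw folds with both classes")

  fold_aucs <- vapply(seq_len(k), function(i) {
    tr <- folds != i
    sub <- feature_matrix(fm$m[tr, , drop = FALSE],
                          lookback_days = fm$lookback_days,
                          binary = fm$binary)
    mod <- fit_ps(sub, y[tr], penalty = penalty,
                  penalty_scale = penalty_scale)
    te <- feature_matrix(fm$m[!tr, , drop = FALSE],
                         lookback_days = fm$lookback_days,
                         binary = fm$binary)
    auc(score(mod, te), y[!tr])
  }, numeric(1))

  structure(list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> mean AUC %.4f (folds: %s), seed %d\n",
              x$mean_auc, paste(sprintf("%.4f", x$fold_aucs), collapse = ", "),
              x$seed))
  invisible(x)
}

# Save/restore global RNG state so seeded subroutines do not perturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Top covariates of a propensity model by weight
#'
#' Nonzero coefficients sorted by absolute value, descending; ties broken by
#' label. Mirrors the usual reporting of the strongest proxies a text-based
#' propensity model picked up.
#'
#' @param model a `ps_model`
#' @param n how many to return (fewer if the model has fewer nonzero weights)
#' @return data.frame with `label` and `beta`
#' @export
top_covariates <- function(model, n = 25) {
  nz <- which(model$coefficients != 0)
  if (!length(nz)) {
    return(data.frame(label = character(0), beta = numeric(0)))
  }
  lab <- model$covariate_labels[nz]
  b <- model$coefficients[nz]
  o <- order(-abs(b), lab)
  o <- o[seq_len(min(n, length(o)))]
  data.frame(label = lab[o], beta = b[o], row.names = NULL)
}

#' Serialize a propensity model to JSON
#' @param model a `ps_model`
#' @param path output file
#' @return path, invisibly
#' @export
write_ps_model <- function(model, path) {
  jsonlite::write_json(
    list(covariate_labels = model$covariate_labels,
         coefficients = model$coefficients, intercept = model$intercept,
         penalty = model$penalty,
         penalty_scale = model$penalty_scale %||% "prior_variance",
         lambda = model$lambda, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a propensity model written by [write_ps_model()]
#' @param path JSON file
#' @return a `ps_model`
#' @export
read_ps_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(
    list(covariate_labels = as.character(obj$covariate_labels),
         coefficients = as.numeric(obj$coefficients),
         intercept = obj$intercept, penalty = obj$penalty,
         penalty_scale = obj$penalty_scale, lambda = obj$lambda,
         converged = isTRUE(obj$converged)),
    class = "ps_model"
  )
}
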