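# Covariate selection: frequency threshold, chi-square association with the
# outcome, or the established-confounder set (age, sex, low-dose aspirin).

new_selection_result <- function(method, threshold_or_alpha, selected) {
  structure(
    list(method = method, threshold_or_alpha = threshold_or_alpha,
         selected_labels = selected, n_selected = length(selected)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s parameter=%s selected=%d\n",
              x$method, format(x$threshold_or_alpha), x$n_selected))
  invisible(x)
}

#' Select covariates by document frequency
#'
#' Keeps covariates present in at least `threshold` episodes (inclusive).
#' Raising the threshold never adds covariates.
#'
#' @param fm a `feature_matrix`
#' @param threshold minimum document frequency, >= 1
#' @return a `selection_result`
#' @export
filter_by_frequency <- function(fm, threshold) {
  assert_that(length(threshold) == 1 && threshold >= 1,
              "threshold must be a single value >= 1")
  df <- doc_freq(fm)
  new_selection_result("FREQUENCY", threshold, names(df)[df >= threshold])
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Plain Pearson chi-square with one degree of freedom and no continuity
#' correction; the p-value is the upper tail of the chi-square distribution.
#' When a row or column margin is zero the statistic is undefined and NA is
#' returned (callers skip such covariates).
#'
#' @param table 2x2 matrix of nonnegative counts
#' @return list with `statistic` and `p`
#' @export
#' @examples
#' chisq_statistic(matrix(c(10, 30, 90, 70), 2)) # statistic 12.5
chisq_statistic <- function(table) {
  assert_that(all(dim(table) == c(2, 2)), "table must be 2x2")
  assert_that(all(table >= 0) && sum(table) > 0,
              "counts must be nonnegative with positive total")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(statistic = NA_real_, p = NA_real_))
  }
  expected <- outer(rs, cs) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Select covariates associated with the outcome (chi-square test)
#'
#' For each covariate, forms the 2x2 presence-by-outcome table and keeps the
#' covariate when the Pearson chi-square p-value is below `alpha`. Covariates
#' with a zero margin (constant columns, or when the outcome is constant) are
#' skipped. No multiple-testing adjustment is applied.
#'
#' @param fm a `feature_matrix` (binary presence)
#' @param outcome_flags logical/0-1 vector aligned to the matrix rows
#' @param alpha significance level
#' @return a `selection_result`
#' @export
filter_by_association <- function(fm, outcome_flags, alpha = 0.05) {
  assert_that(length(outcome_flags) == nrow(fm$m),
              "outcome_flags must align with matrix rows")
  y <- as.logical(outcome_flags)
  n <- length(y)
  n1 <- sum(y)
  pres <- fm$m > 0
  # 2x2 cells per covariate from two sparse column sums
  a <- Matrix::colSums(pres[y, , drop = FALSE])        # present & outcome
  pc <- Matrix::colSums(pres)                          # present total
  b <- pc - a                                          # present & no outcome
  c_ <- n1 - a
  d <- (n - n1) - b
  tot <- n
  e_a <- pc * n1 / tot
  e_b <- pc * (n - n1) / tot
  e_c <- (tot - pc) * n1 / tot
  e_d <- (tot - pc) * (n - n1) / tot
  valid <- pc > 0 & pc < tot & n1 > 0 & n1 < tot
  stat <- rep(NA_real_, length(pc))
  stat[valid] <- (a[valid] - e_a[valid])^2 / e_a[valid] +
    (b[valid] - e_b[valid])^2 / e_b[valid] +
    (c_[valid] - e_c[valid])^2 / e_c[valid] +
    (d[valid] - e_d[valid])^2 / e_d[valid]
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  keep <- !is.na(p) & p < alpha
  new_selection_result("CHISQ", alpha, colnames(fm$m)[keep])
}

#' Established-confounder covariates (age, sex, aspirin)
#'
#' Builds the method-3 covariate set: one indicator per observed integer age
#' in years, one sex indicator (`sex_F`), and one low-dose-aspirin indicator.
#' Zero-variance columns (e.g. a single-sex cohort) are dropped.
#'
#' @param episodes episode table from [build_episodes()]
#' @return a `feature_matrix` of 0/1 indicators
#' @export
established_confounders <- function(episodes) {
  assert_that(nrow(episodes) > 0, "episodes must be nonempty")
  ep <- data.table::as.data.table(episodes)
  n <- nrow(ep)
  ages <- sort(unique(ep$age_at_start))
  cols <- list()
  for (a in ages) cols[[sprintf("age_%d", a)]] <- as.numeric(ep$age_at_start == a)
  cols[["sex_F"]] <- as.numeric(ep$sex == "F")
  cols[["aspirin"]] <- as.numeric(ep$aspirin_exposed == 1)
  m <- do.call(cbind, cols)
  rownames(m) <- ep$episode_id
  keep <- apply(m, 2, function(v) stats::var(v) > 0)
  # a lone age level is informationless only if it is constant
  m <- m[, keep, drop = FALSE]
  feature_matrix(m, lookback_days = NA_integer_, binary = TRUE)
}

#' Serialize a selection result to YAML
#' @param sel a `selection_result`
#' @param path output file
#' @return path, invisibly
#' @export
write_selection <- function(sel, path) {
  yaml::write_yaml(
    list(method = sel$method,
         threshold_or_alpha = sel$threshold_or_alpha,
         n_selected = sel$n_selected,
         selected_labels = as.list(sel$selected_labels)),
    path
  )
  invisible(path)
}
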