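# Hazard-ratio estimation for COX-2 vs nsNSAID episodes under the four
# analysis designs: crude, age-matched, and the two PS-matched designs, each
# with optional covariate adjustment. Matched analyses refit an unstratified
# Cox model on the matched sample (episodes, not patients, are the
# independent unit).

#' Greedy one-to-many matching on age
#'
#' Same pass machinery as [greedy_match()] with `|age difference| <=
#' tolerance_years` as the admissibility rule and the absolute age
#' difference as the ordering key, so exact-age controls are consumed first.
#'
#' @param treated data.frame with columns `id` and `age`
#' @param controls data.frame with columns `id` and `age`
#' @param tolerance_years maximum admissible age difference (inclusive)
#' @return a `matched_cohort` (the difference column is named
#'   `age_difference`)
#' @export
match_on_age <- function(treated, controls, tolerance_years = 2) {
  assert_that(tolerance_years > 0, "tolerance_years must be > 0")
  tr <- data.frame(id = treated$id, score = as.numeric(treated$age))
  co <- data.frame(id = controls$id, score = as.numeric(controls$age))
  match_impl(tr, co, tolerance_years, score_name = "age_difference")
}

#' Cox proportional-hazards estimate of the treatment hazard ratio
#'
#' Time axis is days since episode start; the event is the outcome within
#' the episode; censoring is at episode end. The model contains the COX-2
#' indicator plus the requested adjustment covariates (age in years as a
#' continuous term, indicator sex, indicator aspirin). Ties use the Efron
#' approximation; the confidence interval is the Wald 95% interval.
#'
#' @param episodes episode table (from [build_episodes()] or a matched
#'   subset); needs `class_label`, `follow_up_days`, `event`, and any
#'   adjustment columns
#' @param adjustment_set subset of `c("age", "sex", "aspirin")`
#' @param design label recorded on the estimate (e.g. "CRUDE")
#' @return a `hazard_estimate`: `design`, `adjustment_set`, `hr`, `ci_low`,
#'   `ci_high`, `n_treated`, `n_control`, `n_events`, `converged`
#' @export
fit_cox <- function(episodes, adjustment_set = character(0),
                    design = "CRUDE") {
  ep <- data.table::as.data.table(episodes)
  assert_that(nrow(ep) > 0, "episodes must be nonempty")
  assert_that(all(ep$follow_up_days > 0),
              "all follow_up_days must be > 0 (zero-length follow-up)")
  assert_that(sum(ep$event) >= 1, "need at least one outcome event")
  bad <- setdiff(adjustment_set, c("age", "sex", "aspirin"))
  assert_that(length(bad) == 0,
              paste("unknown adjustment covariates:", paste(bad, collapse = ",")))

  d <- data.frame(
    time = as.numeric(ep$follow_up_days),
    event = as.integer(ep$event),
    cox2 = as.integer(ep$class_label == "COX2")
  )
  terms <- "cox2"
  if ("age" %in% adjustment_set) {
    d$age <- as.numeric(ep$age_at_start)
    terms <- c(terms, "age")
  }
  if ("sex" %in% adjustment_set) {
    d$sexF <- as.integer(ep$sex == "F")
    terms <- c(terms, "sexF")
  }
  if ("aspirin" %in% adjustment_set) {
    d$aspirin <- as.integer(ep$aspirin_exposed == 1)
    terms <- c(terms, "aspirin")
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = "efron")
  b <- stats::coef(fit)[["cox2"]]
  se <- sqrt(stats::vcov(fit)["cox2", "cox2"])
  converged <- is.finite(b) && is.finite(se) && se < 100
  if (!converged) warning("fit_cox: unstable estimate (flagged)")
  structure(
    list(design = design, adjustment_set = adjustment_set,
         hr = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
         n_treated = sum(d$cox2 == 1), n_control = sum(d$cox2 == 0),
         n_events = sum(d$event), converged = converged),
    class = "hazard_estimate"
  )
}

#' @export
print.hazard_estimate <- function(x, ...) {
  adj <- if (length(x$adjustment_set)) paste(x$adjustment_set, collapse = "+")
         else "none"
  cat(sprintf(
    "<hazard_estimate> %s [adj: %s] HR %.3f (95%% CI %.3f-%.3f), %d/%d treated/control, %d events\n",
    x$design, adj, x$hr, x$ci_low, x$ci_high, x$n_treated, x$n_control,
    x$n_events
  ))
  invisible(x)
}

# Subset the episode table to a matched sample: matched treated plus their
# controls (each control appears once by construction).
matched_episode_set <- function(episodes, mc) {
  ids <- unique(c(mc$pairs$treated_id, mc$pairs$control_id))
  ep <- data.table::as.data.table(episodes)
  ep[episode_id %in% ids]
}

#' Run the full matching-by-adjustment analysis grid
#'
#' Produces the analysis-grid table: a crude comparison; an age-matched
#' analysis (tolerance +/- 2 years) with adjustment subsets; and one
#' PS-matched analysis per supplied propensity-score vector, each with
#' adjustment subsets. Any cell that fails (for example no events in a
#' matched sample) is recorded with NA estimates and the suite continues.
#'
#' @param episodes full episode table
#' @param ps_scores named list of per-episode propensity-score vectors
#'   (names become designs, e.g. `PS_FREQ`, `PS_CHISQ`); scores must be
#'   named by episode id
#' @param caliper PS matching caliper
#' @param age_tolerance years for age matching
#' @param adjustment_sets list of adjustment subsets applied to each matched
#'   design
#' @return data.table with one row per grid cell (design, adjustment, hr,
#'   ci_low, ci_high, n_treated, n_control, n_events, error)
#' @export
run_analysis_suite <- function(episodes, ps_scores = list(),
                               caliper = 0.01, age_tolerance = 2,
                               adjustment_sets = list(
                                 character(0), "age", "sex",
                                 c("age", "sex"), c("sex", "aspirin"),
                                 c("age", "sex", "aspirin")
                               )) {
  ep <- data.table::as.data.table(episodes)
  ep <- ep[follow_up_days > 0]
  rows <- list()
  add <- function(design, adj, est, err = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      design = design,
      adjustment = if (length(adj)) paste(adj, collapse = "+") else "none",
      hr = est$hr %||% NA_real_, ci_low = est$ci_low %||% NA_real_,
      ci_high = est$ci_high %||% NA_real_,
      n_treated = est$n_treated %||% NA_integer_,
      n_control = est$n_control %||% NA_integer_,
      n_events = est$n_events %||% NA_integer_,
      error = err
    )
  }
  cell <- function(design, data, adj) {
    tryCatch(add(design, adj, fit_cox(data, adj, design = design)),
             error = function(e) add(design, adj, list(),
                                     err = conditionMessage(e)))
  }

  cell("CRUDE", ep, character(0))

  tre <- ep[class_label == "COX2"]
  con <- ep[class_label == "NSNSAID"]
  if (nrow(tre) && nrow(con)) {
    amc <- match_on_age(data.frame(id = tre$episode_id, age = tre$age_at_start),
                        data.frame(id = con$episode_id, age = con$age_at_start),
                        tolerance_years = age_tolerance)
    aset <- matched_episode_set(ep, amc)
    for (adj in adjustment_sets) {
      if ("age" %in% adj) next # age is the matching variable here
      cell("AGE_MATCHED", aset, adj)
    }
  }

  for (nm in names(ps_scores)) {
    s <- ps_scores[[nm]]
    tre_s <- s[tre$episode_id]
    con_s <- s[con$episode_id]
    keep_t <- !is.na(tre_s)
    keep_c <- !is.na(con_s)
    if (!any(keep_t) || !any(keep_c)) next
    mc <- greedy_match(
      data.frame(id = tre$episode_id[keep_t], score = tre_s[keep_t]),
      data.frame(id = con$episode_id[keep_c], score = con_s[keep_c]),
      caliper = caliper
    )
    mset <- matched_episode_set(ep, mc)
    for (adj in adjustment_sets) cell(nm, mset, adj)
  }

  data.table::rbindlist(rows)
}
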