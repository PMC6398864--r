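# Greedy iterative one-to-many matching with a caliper.
#
# Pass algorithm: within a pass, candidate (treated, available-control)
# pairs with |difference| <= caliper are consumed in ascending difference
# order; accepting a pair removes the control permanently and the treated
# member for the remainder of the pass. Passes repeat until no admissible
# pair remains, so every treated member collects a variable number of
# controls (at least one when any admissible control exists).

#' Greedy one-to-many caliper matching on the propensity score
#'
#' Matches each treated episode to one control per pass, starting from the
#' smallest propensity-score difference; a matched control is precluded from
#' further matching, and the process repeats until all controls are matched
#' or no match within the caliper is possible. Ties in the difference are
#' broken by (treated id, control id) lexicographic order, which makes the
#' result deterministic.
#'
#' @param treated data.frame with columns `id` and `score` for treated
#'   (COX-2) episodes
#' @param controls data.frame with columns `id` and `score` for control
#'   (nsNSAID) episodes
#' @param caliper maximum admissible score difference (inclusive)
#' @return a `matched_cohort`: `pairs` (data.table `treated_id`,
#'   `control_id`, `pass_index`, `ps_difference`), `unmatched_treated` (ids
#'   never matched in any pass), and `caliper`
#' @export
#' @examples
#' greedy_match(data.frame(id = "T1", score = 0.50),
#'              data.frame(id = c("C1", "C2", "C3"),
#'                         score = c(0.505, 0.508, 0.53)),
#'              caliper = 0.01)
greedy_match <- function(treated, controls, caliper = 0.01) {
  assert_that(caliper > 0, "caliper must be > 0")
  assert_that(all(treated$score > 0 & treated$score < 1) &&
                all(controls$score > 0 & controls$score < 1),
              "scores must lie in (0, 1)")
  match_impl(treated, controls, caliper, score_name = "ps_difference")
}

# Shared pass machinery; also used for age matching where the admissibility
# rule is |age difference| <= tolerance.
match_impl <- function(treated, controls, caliper,
                       score_name = "ps_difference") {
  empty <- function() {
    p <- data.table::data.table(treated_id = character(0),
                                control_id = character(0),
                                pass_index = integer(0),
                                diff = numeric(0))
    data.table::setnames(p, "diff", score_name)
    structure(list(pairs = p,
                   unmatched_treated = as.character(treated$id),
                   caliper = caliper),
              class = "matched_cohort")
  }
  if (is.null(treated) || nrow(treated) == 0 ||
      is.null(controls) || nrow(controls) == 0) {
    return(empty())
  }
  tr <- data.table::data.table(tid = as.character(treated$id),
                               ts = as.numeric(treated$score))
  co <- data.table::data.table(cid = as.character(controls$id),
                               cs = as.numeric(controls$score))
  data.table::setorder(co, cs, cid)

  # enumerate only within-caliper pairs via a sorted-window sweep; the
  # window is widened by an ulp-scale margin and the exact |diff| <= caliper
  # rule applied afterwards
  eps <- caliper * 1e-9
  lo <- findInterval(tr$ts - caliper - eps, co$cs,
                     rightmost.closed = FALSE, left.open = TRUE) + 1L
  hi <- findInterval(tr$ts + caliper + eps, co$cs)
  nper <- pmax(0L, hi - lo + 1L)
  if (sum(nper) == 0) return(empty())
  ti <- rep(seq_len(nrow(tr)), nper)
  ci <- unlist(lapply(which(nper > 0L),
                      function(i) seq.int(lo[i], hi[i])), use.names = FALSE)
  pairs <- data.table::data.table(
    ti = ti, ci = ci,
    tid = tr$tid[ti], cid = co$cid[ci],
    d = abs(tr$ts[ti] - co$cs[ci])
  )
  pairs <- pairs[d <= caliper]
  if (nrow(pairs) == 0) return(empty())
  data.table::setorder(pairs, d, tid, cid)

  n_controls <- nrow(co)
  control_used <- rep(FALSE, n_controls)
  accepted <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    avail <- pairs[!control_used[ci]]
    if (nrow(avail) == 0) break
    got_any <- FALSE
    # sequential greedy over the sorted list, vectorized in rounds: a row
    # that is the first remaining occurrence of both its treated member and
    # its control is always accepted by the sequential scan
    while (nrow(avail) > 0) {
      first_t <- !duplicated(avail$ti)
      first_c <- !duplicated(avail$ci)
      take <- first_t & first_c
      if (!any(take)) break # cannot happen: row 1 is always first of both
      acc <- avail[take]
      got_any <- TRUE
      accepted[[length(accepted) + 1L]] <- data.table::data.table(
        treated_id = acc$tid, control_id = acc$cid,
        pass_index = pass, diff = acc$d
      )
      control_used[acc$ci] <- TRUE
      used_t <- unique(acc$ti)
      avail <- avail[!control_used[ci] & !(ti %in% used_t)]
    }
    if (!got_any) break
  }

  pairs_out <- if (length(accepted)) {
    data.table::rbindlist(accepted)[order(pass_index, diff, treated_id,
                                          control_id)]
  } else {
    data.table::data.table(treated_id = character(0),
                           control_id = character(0),
                           pass_index = integer(0), diff = numeric(0))
  }
  data.table::setnames(pairs_out, "diff", score_name)
  structure(
    list(pairs = pairs_out,
         unmatched_treated = setdiff(tr$tid, pairs_out$treated_id),
         caliper = caliper),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  np <- if (nrow(x$pairs)) max(x$pairs$pass_index) else 0L
  cat(sprintf(
    "<matched_cohort> %d pairs over %d pass(es), %d unmatched treated, caliper %g\n",
    nrow(x$pairs), np, length(x$unmatched_treated), x$caliper
  ))
  invisible(x)
}

#' Matching summary by pass
#' @param x a `matched_cohort`
#' @return data.table with pairs per pass and distinct members
#' @export
match_summary <- function(x) {
  if (nrow(x$pairs) == 0) {
    return(data.table::data.table(pass_index = integer(0), n_pairs = integer(0),
                                  n_treated = integer(0)))
  }
  x$pairs[, list(n_pairs = .N,
                 n_treated = data.table::uniqueN(treated_id)),
          by = "pass_index"]
}

#' Write matched pairs to CSV plus a per-pass YAML summary
#' @param x a `matched_cohort`
#' @param csv_path pairs file
#' @param yaml_path optional summary file
#' @return csv_path, invisibly
#' @export
write_matches <- function(x, csv_path, yaml_path = NULL) {
  data.table::fwrite(x$pairs, csv_path)
  if (!is.null(yaml_path)) {
    s <- match_summary(x)
    yaml::write_yaml(
      list(caliper = x$caliper, n_pairs = nrow(x$pairs),
           n_unmatched_treated = length(x$unmatched_treated),
           per_pass = lapply(seq_len(nrow(s)), function(i) as.list(s[i]))),
      yaml_path
    )
  }
  invisible(csv_path)
}
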