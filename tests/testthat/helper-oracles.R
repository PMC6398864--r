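# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (re-sorting, nested loops, day-by-day simulation, dense
# grids) and share no code with the implementation paths they check.

# --- matching: brute-force greedy that re-sorts the whole candidate list
# after every acceptance -----------------------------------------------------
oracle_greedy_match <- function(treated, controls, caliper) {
  cand <- expand.grid(t = seq_len(nrow(treated)), c = seq_len(nrow(controls)))
  cand$tid <- as.character(treated$id[cand$t])
  cand$cid <- as.character(controls$id[cand$c])
  cand$d <- abs(treated$score[cand$t] - controls$score[cand$c])
  cand <- cand[cand$d <= caliper, , drop = FALSE]
  control_avail <- rep(TRUE, nrow(controls))
  names(control_avail) <- as.character(controls$id)
  out <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    used_t <- character(0)
    accepted_any <- FALSE
    repeat {
      live <- cand[control_avail[cand$cid] & !(cand$tid %in% used_t), ,
                   drop = FALSE]
      if (nrow(live) == 0) break
      live <- live[order(live$d, live$tid, live$cid), , drop = FALSE]
      row <- live[1, ]
      out[[length(out) + 1L]] <- data.frame(
        treated_id = row$tid, control_id = row$cid, pass_index = pass,
        ps_difference = row$d, stringsAsFactors = FALSE
      )
      control_avail[row$cid] <- FALSE
      used_t <- c(used_t, row$tid)
      accepted_any <- TRUE
    }
    if (!accepted_any) break
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(treated_id = character(0), control_id = character(0),
                  pass_index = integer(0), ps_difference = numeric(0))
}

# --- AUC: all-pairs concordance enumeration ---------------------------------
oracle_auc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]
  neg <- scores[!y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- penalized logistic: two-stage dense grid over (intercept, b1, b2) ------
oracle_grid_objective <- function(x, y, penalty) {
  obj_many <- function(B) {
    # B: G x 3 (intercept, b1, b2); returns penalized loglik per row
    eta <- cbind(1, x) %*% t(B) # n x G
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    colSums(y * eta - lse) - penalty * (abs(B[, 2]) + abs(B[, 3]))
  }
  coarse <- as.matrix(expand.grid(i = seq(-3, 3, 0.1),
                                  b1 = seq(-3, 3, 0.1),
                                  b2 = seq(-3, 3, 0.1)))
  v <- obj_many(coarse)
  best <- coarse[which.max(v), ]
  fine <- as.matrix(expand.grid(
    i = seq(best[1] - 0.15, best[1] + 0.15, 0.005),
    b1 = seq(best[2] - 0.15, best[2] + 0.15, 0.005),
    b2 = seq(best[3] - 0.15, best[3] + 0.15, 0.005)
  ))
  vf <- obj_many(fine)
  list(best = fine[which.max(vf), ], objective = max(vf))
}

# --- Cox: one-parameter partial-likelihood grid (no ties in the fixture) ----
oracle_cox_grid <- function(time, event, x, grid = seq(-4, 4, 1e-4)) {
  pl <- vapply(grid, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      at_risk <- which(time >= time[i])
      s <- s + x[i] * b - log(sum(exp(x[at_risk] * b)))
    }
    s
  }, numeric(1))
  grid[which.max(pl)]
}

# --- bag of words: nested-loop tokenize-and-tally ---------------------------
oracle_bow <- function(episodes, notes, stop_words, lookback_days,
                       binary = TRUE) {
  tallies <- list()
  for (i in seq_len(nrow(episodes))) {
    counts <- list()
    for (j in seq_len(nrow(notes))) {
      if (notes$patient_id[j] != episodes$patient_id[i]) next
      d <- as.Date(notes$date[j])
      if (d < episodes$start_date[i] - lookback_days ||
          d >= episodes$start_date[i]) next
      for (tok in normalize_text(notes$text[j], stop_words)[[1]]) {
        counts[[tok]] <- (counts[[tok]] %||% 0) + 1
      }
    }
    tallies[[episodes$episode_id[i]]] <- counts
  }
  vocab <- sort(unique(unlist(lapply(tallies, names))))
  m <- matrix(0, nrow(episodes), length(vocab),
              dimnames = list(episodes$episode_id, vocab))
  for (eid in names(tallies)) {
    for (tok in names(tallies[[eid]])) {
      m[eid, tok] <- if (binary) 1 else tallies[[eid]][[tok]]
    }
  }
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- episodes: day-by-day state-machine oracle ------------------------------
# rx: data.frame(date, class, quantity, daily_dose); mentions/outcomes: Date
# vectors. Returns a data.frame of episodes for one patient.
oracle_patient_episodes <- function(rx, mentions, outcomes, birth_year,
                                    enroll_start, enroll_end,
                                    washout = 183, enroll_min = 365,
                                    grace = 30) {
  if (nrow(rx) == 0) return(NULL)
  rx <- rx[order(rx$date, rx$class), , drop = FALSE]
  dur <- pmax(1, floor(rx$quantity / rx$daily_dose + 0.5))
  rx$end <- rx$date + dur
  consumed <- rep(FALSE, nrow(rx))
  out <- list()
  repeat {
    open_idx <- which(!consumed)
    if (!length(open_idx)) break
    s <- min(rx$date[open_idx])
    at_s <- open_idx[rx$date[open_idx] == s]
    all_at_s <- which(rx$date == s)
    if (length(unique(rx$class[all_at_s])) > 1) {
      consumed[at_s] <- TRUE
      next
    }
    age <- as.integer(format(s, "%Y")) - birth_year
    washout_rx <- any(rx$date >= s - washout & rx$date < s)
    washout_mention <- length(mentions) > 0 &&
      any(mentions >= s - washout & mentions < s)
    eligible <- age >= 18 && s >= enroll_start + enroll_min &&
      s >= enroll_start + washout && s <= enroll_end &&
      !washout_rx && !washout_mention
    if (!eligible) {
      consumed[at_s] <- TRUE
      next
    }
    cls <- rx$class[at_s[1]]
    consumed[at_s] <- TRUE
    cur_end <- max(rx$end[at_s])
    # walk forward one day at a time
    d <- s
    repeat {
      d <- d + 1
      if (d > cur_end + grace) break
      starting <- which(!consumed & rx$date == d)
      if (!length(starting)) next
      if (any(rx$class[starting] != cls)) {
        cur_end <- d
        # a lone opposite-class prescription stays a future candidate; a
        # mixed-class day can never start an episode, so consume it whole
        if (length(unique(rx$class[rx$date == d])) > 1) {
          consumed[rx$date == d] <- TRUE
        }
        break
      }
      consumed[starting] <- TRUE
      cur_end <- max(cur_end, rx$end[starting])
    }
    e <- min(cur_end, enroll_end)
    if (e >= s) {
      ev <- sort(outcomes[outcomes >= s & outcomes <= e])
      has <- length(ev) > 0
      out[[length(out) + 1L]] <- data.frame(
        class_label = cls, start_date = s, end_date = e,
        age_at_start = age, event = has,
        outcome_date = if (has) ev[1] else as.Date(NA),
        follow_up_days = as.integer((if (has) ev[1] else e) - s)
      )
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
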