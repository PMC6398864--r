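#' Simulation configuration for the synthetic EHR generator
#'
#' Bundles and validates every knob of the generative model: cohort size,
#' vocabulary structure, the strength of channeling (preferential COX-2
#' prescribing to high-risk patients), the strength with which proxy words
#' track latent gastrointestinal risk, and the true treatment effect on the
#' outcome hazard.
#'
#' Defaults describe a world with marked channeling and confounding by
#' indication: a protective true hazard ratio of 0.5 for COX-2 exposure,
#' confounding that biases the crude hazard ratio upward, and note text whose
#' proxy-word frequencies carry a recoverable risk signal. Event and exposure
#' rates are chosen for statistical test power at cohort sizes of a few
#' thousand patients rather than to mimic national prescribing rates; the
#' methods vignette discusses this choice.
#'
#' @param n_patients number of patients to simulate
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output
#' @param vocab_size number of distinct synthetic vocabulary words
#' @param n_proxy_words how many words have occurrence rates tied to latent
#'   risk (must not exceed `vocab_size`)
#' @param proxy_strength log-rate shift of each proxy word per unit latent
#'   risk
#' @param channeling_strength log-odds of COX-2 (vs nsNSAID) assignment per
#'   unit latent risk
#' @param true_log_hr true log hazard ratio of COX-2 vs nsNSAID on the
#'   outcome
#' @param confounder_log_hr log hazard of the outcome per unit latent risk
#' @param baseline_hazard outcome hazard per day for a zero-risk nsNSAID user
#' @param notes_per_patient_mean Poisson mean of free-text notes per patient
#' @param words_per_note_mean Poisson mean of tokens per note
#' @param rx_duration_days typical prescription duration in days
#' @param aspirin_prevalence probability of low-dose aspirin exposure
#' @param cox2_base_logit intercept of the treatment-assignment logit; at the
#'   default roughly a quarter of episodes are COX-2 when channeling is off
#' @param mention_fraction fraction of patients given a free-text NSAID
#'   drug-name mention shortly before their first prescription, to exercise
#'   the free-text washout rule
#' @param switch_prob probability that a follow-on prescription switches to
#'   the opposite NSAID class, truncating the episode
#' @param dirty_token_rate expected number of "dirty" tokens (stop words,
#'   punctuation, symbol-initial strings) injected per note, to exercise the
#'   text normalizer
#' @return a validated `sim_config` object (a named list)
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 200, seed = 1)
#' cfg$true_log_hr
sim_config <- function(n_patients = 2000,
                       seed = 42L,
                       vocab_size = 2000L,
                       n_proxy_words = 100L,
                       proxy_strength = 1.0,
                       channeling_strength = 1.5,
                       true_log_hr = log(0.5),
                       confounder_log_hr = 0.8,
                       baseline_hazard = 0.0015,
                       notes_per_patient_mean = 6,
                       words_per_note_mean = 25,
                       rx_duration_days = 30L,
                       aspirin_prevalence = 0.1,
                       cox2_base_logit = -1.1,
                       mention_fraction = 0.05,
                       switch_prob = 0.04,
                       dirty_token_rate = 1.5) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    vocab_size = as.integer(vocab_size),
    n_proxy_words = as.integer(n_proxy_words),
    proxy_strength = proxy_strength,
    channeling_strength = channeling_strength,
    true_log_hr = true_log_hr, confounder_log_hr = confounder_log_hr,
    baseline_hazard = baseline_hazard,
    notes_per_patient_mean = notes_per_patient_mean,
    words_per_note_mean = words_per_note_mean,
    rx_duration_days = as.integer(rx_duration_days),
    aspirin_prevalence = aspirin_prevalence,
    cox2_base_logit = cox2_base_logit,
    mention_fraction = mention_fraction,
    switch_prob = switch_prob,
    dirty_token_rate = dirty_token_rate
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- vapply(cfg, is.numeric, logical(1))
  assert_that(all(num), "all sim_config fields must be numeric")
  assert_that(all(vapply(cfg, function(x) length(x) == 1 && is.finite(x),
                         logical(1))),
              "all sim_config fields must be finite scalars")
  assert_that(cfg$n_patients >= 1, "n_patients must be >= 1")
  assert_that(cfg$vocab_size >= cfg$n_proxy_words,
              "vocab_size must be >= n_proxy_words")
  assert_that(cfg$n_proxy_words >= 0, "n_proxy_words must be >= 0")
  assert_that(cfg$baseline_hazard > 0, "baseline_hazard must be > 0")
  for (p in c("aspirin_prevalence", "mention_fraction", "switch_prob")) {
    assert_that(cfg[[p]] >= 0 && cfg[[p]] <= 1,
                paste(p, "must be in [0, 1]"))
  }
  assert_that(cfg$rx_duration_days >= 1, "rx_duration_days must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
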