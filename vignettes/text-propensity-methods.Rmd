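---
title: "Propensity scores from clinical free text: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propensity scores from clinical free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Comparative-safety studies in routine-care databases are haunted by
confounding by indication. The canonical example implemented here: selective
COX-2 inhibitors were designed to spare the gastric mucosa, so physicians
preferentially prescribe them to patients already at high risk of upper
gastrointestinal bleeding (UGIB). A crude comparison of UGIB hazards between
new users of COX-2 inhibitors and of nonselective NSAIDs is therefore biased
against the COX-2 class. Much of what makes a patient "high risk" in primary
care never appears as a diagnostic code — it lives in the free-text notes.
This package treats those notes as a source of confounder *proxies*: every
unigram becomes a candidate covariate of a propensity score (PS) model, and
matching on that score is compared against conventional adjustment.

## The pipeline

1. **Cohort construction** (`build_episodes`). New-user treatment episodes
   are built from ATC-coded prescriptions: adults (≥ 18), enrolled ≥ 365
   days, with ≥ 183 days of data, no NSAID prescription of either class and
   no free-text NSAID drug-name mention in the 183 days before the first
   prescription. Prescription duration is quantity / daily dose. An episode
   chains prescriptions that start within 30 days of the previous one's end,
   ends at the last chained prescription's end, and is truncated at a switch
   to the opposite class. The class of the first prescription labels the
   episode. The first outcome event inside the closed episode interval is
   the event; otherwise follow-up is censored at episode end.
2. **Featurization** (`normalize_text`, `build_bow`). Text is lowercased,
   special characters are stripped, tokens not starting with a letter or
   digit and stop words are dropped. Each episode's covariates are the
   unigrams present in its patient's notes over the half-open 183-day
   lookback window before the episode start (binary presence by default).
3. **Covariate selection** (`filter_by_frequency`, `filter_by_association`,
   `established_confounders`). Either a document-frequency threshold, a
   per-covariate Pearson chi-square screen against the outcome at p < 0.05
   (no continuity correction, no multiplicity adjustment — deliberately, as
   a screen rather than a test), or the conventional set: one indicator per
   observed age-in-years, sex, low-dose aspirin.
4. **Propensity model** (`fit_ps`, `cross_validate`). L1-penalized logistic
   regression of treatment class on the selected covariates, unpenalized
   intercept, unstandardized 0/1 features. Performance is the mean AUC over
   three seeded, unstratified cross-validation folds.
5. **Matching** (`greedy_match`, `match_on_age`). Greedy one-to-many caliper
   matching: all within-caliper (treated, control) pairs are consumed in
   ascending score-difference order; a matched control is removed
   permanently, a treated member only for the rest of the pass; passes
   repeat until no admissible pair remains. The caliper is 0.01 on the
   probability scale (inclusive). Age matching reuses the same machinery
   with |Δage| ≤ 2 years.
6. **Outcome analysis** (`fit_cox`, `run_analysis_suite`). Cox proportional
   hazards on days since episode start, Efron ties, Wald 95% CIs, fit
   unstratified on the matched sample, with adjustment subsets of
   {age, sex, aspirin}. The suite produces the full design × adjustment
   grid: crude, age-matched, and one PS-matched block per selection method.

## Penalty parameterization (a deliberate choice)

The Laplace ("double exponential") prior hyper-parameter is 0.01 by
default. Two readings of such a hyper-parameter exist in the literature on
large-scale Bayesian logistic regression: the per-coefficient L1 weight
λ itself, or the prior *variance* σ², with λ = √(2/σ²). The package default
uses the prior-variance reading (0.01 → λ ≈ 14.1 per coefficient on the
full-likelihood scale) for two reasons. First, it is the parameterization
of the software tradition this method descends from. Second, the direct
reading degenerates at desk scale: with λ = 0.01 and a few thousand
episodes against a comparable number of unigram covariates the objective is
effectively unpenalized, the classes are linearly separable, and coordinate
descent stalls (we observed single fold fits exceeding 100 s that complete
in 0.3 s under the prior-variance reading). Studies at database scale
(hundreds of thousands of episodes, n ≫ p) do not hit this regime, which is
presumably why the ambiguity is harmless there. `penalty_scale = "l1"`
exposes the direct reading; the package's penalization-path tests use it so
that λ keeps its textbook monotonicity semantics.

## What the synthetic world emulates

`generate_cohort` draws, per patient, a latent gastrointestinal risk score
(standard normal shifted by age and aspirin exposure) that does three things
at once:

* **channeling** — the log-odds of receiving COX-2 at first exposure rise
  by `channeling_strength` (default 1.5) per unit risk;
* **confounding** — the outcome log-hazard rises by `confounder_log_hr`
  (default 0.8) per unit risk, on top of a true treatment effect
  `true_log_hr` (default log 0.5) and an exponential baseline
  (`baseline_hazard`, default 0.0015/day);
* **proxy text** — `n_proxy_words` (default 100) of the `vocab_size`
  (default 2000) vocabulary words have their occurrence log-rates shifted by
  `proxy_strength` (default 1.0) per unit risk; the rest are noise. Notes
  also contain literal stop words, punctuation and symbol-initial tokens to
  exercise the normalizer, and a `mention_fraction` of patients receive a
  drug-name mention before first prescription to exercise the free-text
  washout rule.

Event and exposure rates are deliberately set for statistical power at
cohorts of a few thousand patients rather than for epidemiological realism:
roughly 25–30% of episodes are COX-2 (the source study had 5%) and roughly
8% of episodes carry an event (the source study had ~0.2%). The channeling
and proxy strengths were fixed once, before the acceptance tests were
written, by checking the Bayes-optimal AUC of the generative model (the AUC
achievable by a model that sees the latent risk itself): at the defaults it
is ≈ 0.83, leaving a comfortable margin for a text-based model to clear the
0.65 detection bar while a no-channeling world sits at 0.5. A green test
therefore establishes that the pipeline recovers a *strong, stationary,
single-factor* confounding signal from token presence; it does not
establish performance on natural clinical language, multi-factor
confounding, time-varying risk, or rare-event regimes.

## Numerical and procedural choices

* "Six months" = 183 days, "one year" = 365 days. Washout windows are
  half-open `[start − 183 d, start)`; the episode interval is closed for
  event attachment.
* Durations round half up to whole days and clamp to ≥ 1 day.
* Same-day first prescriptions of both classes are ambiguous: no episode.
* Matching ties in |Δscore| break by (treated id, control id) order — the
  result is fully deterministic. Treated members unmatched in one pass are
  retried while any admissible control remains.
* Cross-validation folds are a seeded simple random partition, not
  stratified; partitions leaving a fold without both classes are redrawn
  (bounded retries).
* glmnet convergence: warm-start path down to the target λ, threshold
  1e−10; unseen (all-zero) covariates keep coefficient 0; extreme
  coefficients flag probable separation rather than failing.
* Matched analyses refit an unstratified Cox model on the matched sample;
  episodes (not patients) are the independent unit, and no robust
  clustering by patient is applied — a known limitation shared with the
  design this package reproduces.
* Every random draw in the pipeline derives from the single run seed; the
  manifest echoes the config, so a manifest suffices to reproduce a run.

## Known limitations

Synthetic notes are token streams, not language (no negation, no n-grams,
no spelling variation); the chi-square screen inherits the instability of
screening on rare events; one-to-many matching without replacement can
consume the entire control pool when scores are concentrated, making
late-pass matches uninformative; and the frequency-threshold default in
`default_run_config` (5) is a desk-scale stand-in for the database-scale
threshold of 1000.
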