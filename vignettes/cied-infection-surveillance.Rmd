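---
title: "Methods: flagging CIED infections from structured and free-text EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flagging CIED infections from structured and free-text EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciedtriage)
```

## The surveillance problem

Infections after cardiovascular implantable electronic device (CIED)
procedures — device pocket infections, lead infections, endocarditis —
occur in roughly 1% of procedures within 90 days, usually weeks after the
patient has left the procedural area. Neither ingredient of conventional
surveillance works well here: diagnosis codes are incomplete and
unspecific, and the reference standard (manual chart review against a
structured infection definition) cannot be applied to tens of thousands of
procedures. `ciedtriage` implements the middle path: compute cheap,
deterministic *flags* for every procedure from routine EMR extracts, score
each procedure with a logistic model, and spend reviewer time only on cases
whose predicted probability of infection clears a threshold.

This vignette documents the model, its assumptions, the tunable parameters,
the synthetic data generator, and the numerical and design choices a
maintainer would want to know about.

## The reference infection definition

`adjudicate()` encodes the criterion standard applied to chart
abstractions: a case is a 90-day CIED infection iff physician documentation
of infection is present *or* at least two of {documented symptoms, positive
laboratory tests, antibiotic treatment initiated}, and no exclusion applies
(infection already present at the procedure, superficial cellulitis at
another body site, stitch abscess only), and onset — when recorded — is
within 90 days. The definition lists inclusions and exclusions separately
without stating precedence; we make exclusion precedence explicit:
**exclusions always win**. Cellulitis *at the device site* is a recordable
infection type (`cellulitis_only`), distinct from the excluded
"superficial cellulitis in other locations"; the two are separate
abstraction fields so the distinction cannot be lost.

## Flags and their windows

All windows are day-granular offsets from the procedure day (day 0), and
all are inclusive of both endpoints except mortality. Endpoint inclusivity
is not something phrases like "up to 30 d" or "6-90 d" pin down, so we
choose inclusive and document it:

| flag | window | definition |
|---|---|---|
| `died_90d` | \[0, 90) | death date strictly before day 90 |
| `icd_*` | \[0, 90\] | ICD-10-CM prefix match (dots stripped both sides) |
| `fever_30d` | \[0, 30\] | any temperature ≥ 38.0 °C |
| `antibiotic_class` | fills in \[6, 90\] | ≥ 3 consecutive covered days |
| `micro_*` | \[0, 90\] | orders/cultures, see below |
| `note_infection_post` | \[+3, +90\] | post-infection keyword rules |
| `note_infection_pre` | \[−90, −3\] | history keyword rules |

Decisions worth spelling out:

* **Fever threshold.** Source materials print both "100.3 °F" and
  "38 °C"; these differ (100.3 °F = 37.9 °C). We use 38.0 °C, the value
  printed with the flag definition, and expose it as
  `fever_threshold_c` in the config.
* **Antibiotic duration** is computed from dispensing data
  (`fill_date` + `days_supplied` as a covered-day interval; overlapping
  fills of the same drug merge), because EMR warehouses expose fills, not
  administrations. The fill window starts at day 6 so routine
  periprocedural prophylaxis cannot qualify. Whether the original window
  keys on order or fill dates is unknowable from the published material;
  fill date is the defensible warehouse-level choice.
* **Micro windows** start at day 0 (a day-3 start is equally defensible;
  day 0 keeps all structured windows aligned).
* **Code and antibiotic lists** ship as editable YAML
  (`inst/extdata/config.yaml`) because the exact deployed lists are
  site-specific: CIED-infection prefixes (T82.6\*, T82.7\*), SSI plus
  wound dehiscence (T81.4\*, T81.3\* — in CIED data, dehiscence codes are
  often the only SSI-family coding observed), nonspecific infection
  (A49.9, R78.81, B99), and a *Staphylococcus*-directed agent list
  (cefazolin, cephalexin, dicloxacillin, vancomycin, daptomycin, ...).
  Unknown drug names are treated as non-antibiotics and logged, never
  guessed.
* `micro_order_no_staph` is defined as *an order exists in window and no
  staphylococcal organism was found*; with no orders at all it is FALSE —
  it is an "order, but..." flag, not a negation of the organism flags.

## Keyword matching semantics

Free-text matching is deliberately primitive and fully declarative
(`keyword_rule()` / `compile_ruleset()`): an ordered sequence of word
groups, each group a curated set of spelling variants, matched over
lowercased punctuation-stripped tokens with at most `max_gap_tokens`
intervening tokens between consecutive matched words. The default gap is 1:
"one or two spaces" between words in prose corresponds to adjacency or a
single intervening word. Tight gaps with preserved word order outperform
liberal windows (e.g. five words between *CIED* and *infection*), which is
why the matcher has no proximity scoring — just the bound.

Implementation: matching is a right-to-left feasibility table over
(word-group, token-position) pairs, then one span is reconstructed per
feasible start. This is equivalent to brute-force enumeration of ordered
token subsequences under the gap constraint — the test suite checks exact
agreement with such an enumerator on 10 000 random token streams — but
linear in note length for fixed rule size. Greedy left-to-right matching
would be wrong: the earliest continuation can dead-end while a later one
succeeds.

Known, deliberate limitations: no stemming or edit distance (variant lists
are explicit), no sentence boundaries (the gap bound limits long-range
matches), and **no negation detection** — "no evidence of infection"
matches. The design compensates structurally rather than linguistically:
the preprocedure-history flag enters the model as a negative predictor and
absorbs the dominant false-positive mechanism, serial copy-forward of
historical infection text. Note-title filters are case-insensitive
substring patterns ("cardiology") because exact note titles are
site-specific; patient-instruction notes (which discuss infection without
evidence of infection) are excluded by simply not matching the filter.

The shipped rule file (`inst/extdata/keyword_rules.yaml`) is a working
default — pocket/device/CIED/pacemaker + infection, endocarditis, the same
phrases as preprocedure history rules, and organism rules for
*Staphylococcus aureus* and coagulase-negative staphylococci. It is
configuration, expected to be replaced with a site-curated list.

## The triage model

`triage_fit()` is a plain fixed-effects binomial-logit GLM via iteratively
reweighted least squares (convergence: log-likelihood change < 1e-8, max
100 iterations). We deliberately fit *no facility random effects*: the
model is applied out-of-sample as a fixed coefficient vector, which is how
a single published coefficient set is used in practice; a mixed-effects
extension is out of scope. The covariate set (`triage_covariates()`) is
the final surveillance model: mortality, two comorbidities, two code
flags, the antibiotic class as two indicators against "no qualifying
course", the cardiac-specimen flag, and the two note flags.

Several flags are sparse at realistic prevalence, so near-separation is a
live concern (the symptom: enormous odds ratios with unbounded Wald CIs).
The fitter warns and names suspect covariates; `firth = TRUE` switches to
Firth-penalized scoring (hat-diagonal score correction, written in-package)
which keeps estimates finite under complete separation. ML remains the
default because it is the conventional estimator and is well-behaved at
the cohort sizes the pipeline targets.

The default review threshold is a predicted probability of **0.10**,
compared with `>=` so that the threshold coincides with a band edge of the
probability-band table (0–1%, 1–3%, 3–10%, 10–50%, 50–100%). At realistic
prevalence this threshold captures the large majority of true infections
while flagging only ~1–3% of procedures for review. Queue sampling
(`triage_queue()`) is seeded stratified simple random sampling: by default
80% of above-threshold cases and 1% of below-threshold cases (the latter a
leakage check), with sample sizes `round(fraction × stratum)`.

## Evaluation

`confusion_metrics()` computes PPV, sensitivity and specificity **over
reviewed cases only**, with exact Clopper–Pearson 95% CIs. This reproduces
the arithmetic of partial-verification review designs and carries their
caveat: because unreviewed cases contribute nothing, sensitivity and
specificity are conditional on the review sample, and no verification-bias
correction is attempted (bias-corrected two-phase estimators are an
explicit non-goal). Zero denominators yield `NA`, never 0. The CI method is
a choice — the original analyses do not name theirs — so externally printed
CIs should be compared loosely.

`roc_auc()` is the midrank Mann–Whitney concordance (identical to the
model C-statistic when applied to fitted probabilities), with curve points
at every distinct threshold; it is checked against all-pairs enumeration
(n ≤ 50) and against an established ROC implementation. `cohen_kappa()`
uses the standard (p₀ − pₑ)/(1 − pₑ); two identical constant raters give
κ = 1 by documented convention. `infection_summary()` reports type shares
and mean (SD) onset; SD of a single observation is `NA`. Displayed
percentages round half-up to one decimal.

`review_counts_to_cases()` inverts a published band summary into
case-level data (band-midpoint probabilities, sequential ids) so that
published review counts can be pushed through the same evaluation code
paths instead of re-deriving ratios by hand; `scripts/acceptance.R` uses
exactly this route.

## The synthetic EMR generator

`simulate_cohort()` exists because CIED EMR extracts cannot be public. It
emulates the *statistical structure the algorithm assumes*, not clinical
reality:

* 0.8% of procedures get a planted 90-day infection (83/15/2% pocket /
  endocarditis-or-lead / cellulitis), with onset ~ Normal(35, 21²) days
  truncated to \[3, 90\];
* a further 0.7% are "present-at-procedure" cases: revision procedures on
  an existing infection, excluded from the outcome but heavy emitters of
  historical documentation and residual treatment signals — the main
  false-positive source;
* conditional on status, each documentation signal (ICD code, qualifying
  antibiotic course, positive culture with organism text, fever, death,
  keyword note) is emitted independently with configured probabilities.
  Emission probabilities given infection are anchored to observed flag
  rates among confirmed infections; background rates to observed cohort
  marginal flag rates. The background negative-culture order rate is set
  so the overall order rate, not the standalone negative rate, matches its
  observed marginal.
* noise planted on purpose: periprocedural prophylaxis fills (before day
  6), sub-3-day courses, non-antibiotic medications, normal temperatures,
  filler notes, and keyword-bearing patient-instruction notes that only
  the title filter keeps out.

Two structural correlations are planted rather than left to independence:

1. **Copy-forward.** Preprocedure historical-infection documentation is
   copied into postprocedure notes with probability 0.9. Background
   postprocedure keyword mentions therefore arise mostly from copied
   history; among non-infected cases pre- and post-flags are strongly
   correlated, while among true infections the post flag is nearly
   universal regardless of history. This makes the history flag a
   *conditionally negative* predictor (fitted OR well below 1) even though
   its marginal rate is higher among infections than in the cohort —
   reproducing the mechanism that motivates the flag, not just its
   marginal rate.
2. **Generator–adjudicator consistency.** Every procedure also gets a
   chart abstraction drawn to be consistent with its planted truth:
   `adjudicate()` applied to the generated abstractions returns exactly
   the planted infection labels (a tested invariant).

Note text is filler vocabulary with keyword phrases inserted at random
positions, 40% of the time with one intervening token, so the gap
semantics are exercised; the filler vocabulary is disjoint from all rule
variants, so accidental matches cannot occur. No attempt is made at
clinically realistic prose.

What passing tests on this generator do **not** show: robustness to
misspellings outside the variant lists, to negated mentions, to note-title
taxonomies unlike the simulated ones, or to flag correlations beyond the
two planted above. Real-data performance claims require real-data
validation.

## Reproducibility and problem sizes

Every stochastic component (generator, queue sampling) takes an explicit
seed and restores the caller's RNG state; identical seeds give
byte-identical cohort files and reports. The test suite and the acceptance
script use cohorts of 10 000 procedures per arm for the end-to-end
property (enough for ~80 planted infections and a stable fit — at a few
thousand procedures the ~0.8% prevalence leaves so few events that ML
fits can separate; use `firth = TRUE` there), 5 000 for flag-prevalence
recovery, and 20 000 for prevalence calibration. The end-to-end sanity
envelope at these settings: out-of-sample sensitivity above 0.8 at the
10% threshold and PPV at least tenfold above prevalence.

## Degenerate inputs, tie-breaks, conventions

* Probability exactly at a band edge belongs to the upper band (`[lo, hi)`;
  the top band is closed), consistent with the `>=` threshold.
* `triage_queue` with fraction 1/0 returns exactly the stratum / nothing.
* A threshold of 1.0 yields an empty above-threshold stratum and an
  undefined (NA) PPV, not an error; a single-class validation cohort
  leaves the AUC `NA`.
* Vitals outside 30–45 °C are rejected at read time with line-numbered
  diagnostics; a death date before the procedure is a data-quality
  warning and a FALSE mortality flag.
* Ties in scores are handled by midranks in the AUC and by distinct-value
  thresholds in the ROC curve.
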