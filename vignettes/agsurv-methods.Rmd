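---
title: "Methods: keyword-screened Naive Bayes surveillance of agricultural injuries in EMS narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keyword-screened Naive Bayes surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agsurv)
```

## The surveillance problem

Pre-hospital care reports (PCRs) pair a handful of categorical fields with a
free-text narrative. Agricultural work-relatedness is almost never coded
explicitly, so case ascertainment must lean on the narrative. A raw keyword
search has high recall but poor precision; reviewing every keyword hit at
state scale is a multi-FTE effort. `agsurv` interposes a probabilistic
classifier between the keyword screen and the human coders: records are
first reduced to the *keyword-positive stratum* (at least one unsuppressed
lexicon stem in the narrative), a Bernoulli Naive Bayes model scores that
stratum, and only records above a calibrated posterior threshold go to
review. The threshold is chosen not for accuracy but for a *sensitivity
floor*: the system is designed to capture a target share (90% by default) of
true cases, accepting that the remainder is missed.

## Cleaning

Two deterministic steps, in fixed order:

1. **Deduplication.** Records agreeing exactly on gender, admit date, ZIP
   code and date of birth are one encounter filed twice; one is retained
   uniformly at random. The retention draw is seeded from the sorted member
   record ids, so results are invariant to row order. A missing value in any
   of the four fields exempts a record from grouping — we never merge on
   missingness. "Admit date" is our reading of the admission field in the
   four-variable match; the alternative readings are not distinguishable
   from the published rule set.
2. **No-interest removal.** Dispatch reason transfer/lifting/intercept or
   destination nursing home, matched case-insensitively after trimming;
   missing never matches. Cleaning runs *before* dialect harmonization
   (mirroring the original SAS-then-Python order), so these labels are kept
   canonical up to letter case in every dialect vocabulary.

Idempotence (a second pass removes nothing) and conservation (input = kept +
removed, per step) are enforced by tests.

## Narrative scanning

Normalization lower-cases, replaces every non-alphanumeric character by a
space, and splits on whitespace; stemming is the English Snowball (Porter2)
algorithm, implemented inside the package from the published algorithm
definition (regions R1/R2, y/Y marking, steps 0–5 with longest-suffix-wins
semantics). The keyword lexicon entries are themselves Snowball stems, which
gives an external oracle: the test suite asserts that domain surface words
(horses, hooves, silage, irrigation, fertilizer, ...) stem to exactly the
published lexicon values.

Matching is position-based on the stemmed token sequence:

- a stem fires when a stemmed token equals it **or begins with it** (prefix
  semantics: "irrig" is meant to catch "irrigation"); multi-word stems match
  consecutive token n-grams joined by `_`;
- a match is suppressed when it lies inside an occurrence of an *exclusion
  phrase* (proper nouns and businesses: "farmington", "state farm") or when
  the next token is an *address suffix* ("barn rd");
- *collision words* are removed before stemming: "animate" stems to the same
  value as "animal" and would otherwise fire the animal keyword. We store
  whatever the stemmer actually produces rather than hard-coding the common
  stem.

The published exclusion list (1,557 entries, grown iteratively during
coding) is not public; the lexicon ships with the rule classes and a small
starter set, and is extensible via a YAML file. Lexicon stems are stemmer
*outputs* and are never re-stemmed: two of them ("hors", "coveral") are not
fixed points of a second application, which is expected Snowball behavior.

## Features

Transformation maps `(variable, dialect, raw) -> canonical` harmonize
incident location, mechanism of injury, dispatch reason, primary impression
and destination type across state/year dialects; unmapped labels pass
through with a warning, an unknown dialect is an error. The design matrix
concatenates keyword flags (lexicon order) with one-hot dummies for incident
location, mechanism, dispatch reason, primary impression and gender, each
with an explicit `missing` level so every variable's block partitions each
row. Identifier fields (DOB, admit date, ZIP, state) are deliberately
excluded from the features: as dummies they would explode cardinality and
effectively memorize identities. Level sets are discovered on training data
and frozen in a JSON schema; unseen levels at apply time collapse to
`missing`, which protects cross-state runs from silent column drift (a
schema mismatch at scoring time is an error, never ignored).

The binary outcome is case class 1–3 versus 0; classes 2 and 3 (suspected
agricultural or suspected traumatic) count as positives.

## The classifier

Bernoulli Naive Bayes with Laplace-style smoothing:

$$\hat\theta_{j,y} = \frac{n_{j,y} + \alpha}{N_y + 2\alpha}, \qquad
\hat\pi_y = N_y / N,$$

with `alpha = 1` by default (the customary default of the toolchain this
kind of pipeline uses; the original smoothing constant is not published, so
exact reproduction of printed importance values is not attempted).
Everything is computed in log space; the posterior is the logistic of the
class log-joint difference, so it is strictly inside (0,1) and safe with
hundreds of features. Correctness is pinned by two independent routes:
exhaustive joint-probability enumeration on small models (tolerance 1e-10)
and agreement with `e1071::naiveBayes` to 1e-8.

Variable importance is $\log\hat\theta_{j,1} - \log\hat\theta_{j,0}$,
reported with the 2×2 contingency counts (a, b, c, d). Using smoothed
estimates keeps the statistic finite for features absent from one class —
precisely the rare, highly specific keywords that dominate the ranking.

## Threshold calibration

`select_threshold()` returns the `ceiling(target * P)`-th largest positive
score: the smallest cutoff whose inclusive tagging (`score >= t`) captures
at least the target share of the P positives. This makes the sensitivity
guarantee hold *by construction* on the selection set, and a brute-force
scan in the tests confirms minimality (any higher distinct cutoff breaks the
guarantee).

`calibrate()` repeats, one hundred times by default: draw a random
(unstratified) 80/20 split, fit on the training share, score the validation
share, select the threshold there, and record threshold, tagged fraction,
precision and AUC. Where the sensitivity floor is enforced was a genuine
design choice — the protocol description is compatible with selecting on
the validation split or on the whole file; we select on the validation
split, the standard practice for a held-out operating point. Degenerate
splits (a single-class training set, or no validation positives) are redrawn
rather than skipped so exactly `n_iterations` records are aggregated; means
and SDs use the n−1 denominator. The threshold transferred to new, untagged
data is the *mean* of the per-iteration thresholds, and tagging is inclusive
(`posterior >= threshold`).

ROC curves sweep all distinct score values with tied scores collapsed into a
single step; AUC by the trapezoidal rule, which equals the tie-corrected
Mann–Whitney statistic exactly (asserted against a pairwise oracle and
against `pROC`). `cross_scenario_eval()` fits on one corpus and reports, on
another sharing the frozen schema, the AUC and the false-positive rate
incurred at the threshold achieving the target true-positive rate on the
test scores (test-side enforcement; the train-side reading of that operating
point is possible but less informative about transfer).

## The synthetic generator

Restricted source data cannot ship, so `generate_corpus()` provides the
study conditions for all tests:

- **Narratives** are 5–40 tokens of EMS-style filler (a vocabulary verified
  to contain no keyword collisions) with keyword surface forms and
  confounder phrases inserted at distinct gaps, so planted units never
  interleave. This template model is a stand-in: no distributional detail
  about real narratives is published, and none is claimed.
- **Class structure.** A record is a case (class 1–3, default mix 40/30/30 —
  the published data only constrain the post-hoc confirmed split) with the
  configured prevalence. Non-case narratives contain a keyword with
  per-slot probability 0.05; case narratives get three slots whose odds are
  multiplied by `keyword_enrichment` (default 8). Categorical fields are
  drawn from class-conditional distributions in which a farm location and
  animal/machinery mechanisms are strongly case-associated, mirroring the
  qualitative structure of the published importance ranking.
- **Confounders.** A configurable share of non-case narratives receive a
  keyword *only* inside an excluded context ("barn rd", "farmington"); the
  truth sidecar records these separately from genuine plantings.
- **Duplicates and no-interest records** are planted at configurable rates;
  no-interest labels go to non-case records only (a transfer or lift-assist
  dispatch is by construction not an acute trauma, and planting them on
  cases would silently delete true cases before the model).
- **Dialects.** Two state vocabularies (ME canonical, NH synonyms) exercise
  the transformation maps.
- **Determinism.** Every record draws from a counter-derived RNG substream
  of the master seed, so corpora are byte-identical across runs and
  insertion order cannot change results.

What passing tests on this generator do *not* show: robustness to real EMS
spelling noise, negations, abbreviation conventions, or the true rarity
structure of agricultural keywords. The generator validates the *machinery*
(recovery of planted structure, exact bookkeeping, calibration behavior),
not clinical NLP performance.

## Numerical choices and problem sizes

- Smoothing `alpha = 1`; configurable, must be > 0 (zero would produce
  log-zero likelihoods).
- Posterior computed as `plogis(logjoint1 - logjoint0)`; no raw products.
- Threshold ties: inclusive `>=` everywhere.
- Report percentages round half-up to one decimal, matching conventional
  presentation; raw values are kept alongside.
- Burden: FTE = n × minutes / 60 / hours-per-FTE with 1,000 hours per FTE by
  default — the value consistent with both published FTE figures (solving
  each printed figure for the constant gives ≈995–998 hours).
- Test problem sizes: parameter recovery uses 50,000 draws from a known
  generative model (binomial SE comfortably below the 0.01 tolerance);
  protocol tests use a 10,000-record corpus at 3% prevalence and enrichment
  8; oracle equivalence enumerates up to 2^12 feature vectors.

## Known limitations

- The stemmer implements the standard English Snowball algorithm; it is
  validated against the published stem table and classic examples, not
  against the full reference vocabulary list.
- Exclusion semantics are two formal rules (phrase containment,
  following-token address suffix) plus pre-stemming collision removal; the
  original system's exclusion list was larger and partly manual.
- Posterior probabilities are used raw; no probability calibration beyond
  thresholding is attempted, and no k-fold or bootstrap variants of the
  protocol are provided.
- Printed performance figures from the restricted corpora (threshold mean
  0.016, 15% tagged, AUC 0.95, cross-scenario AUCs 0.83–0.95) are not
  reproducible without those data; the package reproduces the *procedures*
  and the printed report arithmetic exactly, and demonstrates the protocol's
  behavior on synthetic ground truth.
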