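# agsurv

Occupational agricultural injuries are chronically under-counted: farm
operations are largely exempt from regulatory injury reporting, and the
structured fields of administrative health records rarely identify work-
relatedness. Free-text pre-hospital care reports (PCRs) — the record an EMS
crew files for every encounter — do contain the telltale vocabulary
("pinned under tractor", "kicked by cow in pasture"), but at state scale a
plain keyword search over millions of narratives still leaves far too many
records for human review.

`agsurv` implements a complete surveillance pipeline that addresses this for
injury epidemiologists and state EMS data stewards:

1. **Cleaning** — exact-match deduplication on (gender, admit date, ZIP,
   date of birth), one duplicate retained at random, then removal of records
   of no interest (dispatch reason transfer / lifting / intercept,
   destination nursing home).
2. **Narrative scanning** — lower-casing, punctuation stripping, English
   Snowball (Porter2) stemming (implemented in the package), and detection
   of a 119-stem agricultural keyword lexicon with exclusion rules:
   exclusion phrases (street and business names), stem-collision words
   removed before stemming (e.g. "animate", which stems identically to
   "animal"), and address-suffix suppression ("Barn Rd" is not a barn).
3. **Features** — transformation maps harmonize categorical vocabularies
   across state/year "dialects"; keyword flags plus one-hot dummies (with an
   explicit missing level) form a frozen binary design matrix.
4. **Classifier** — a from-scratch Bernoulli Naive Bayes over binary
   features x_j with class y ∈ {0,1}:

   θ̂_{j,y} = (n_{j,y} + α) / (N_y + 2α),  α = 1 (Laplace) by default,

   scored in log space, P(y=1|x) via the logistic of the class log-joint
   difference. Variable importance is the smoothed log-probability
   difference log θ̂_{j,1} − log θ̂_{j,0} with its 2×2 contingency counts.
5. **Calibration** — the decision threshold is chosen so that a target share
   (default 90%) of true cases is captured: over 100 random 80/20
   train/validation splits, each iteration selects the smallest validation
   score cutoff capturing ⌈0.9·P⌉ positives; means and SDs of threshold,
   tagged fraction, precision and ROC AUC are reported. Cross-scenario
   (year/state) transfer is evaluated by the AUC and the false-positive rate
   needed to reach the target true-positive rate.
6. **Surveillance** — applying a trained model and the mean calibrated
   threshold to untagged corpora emits a review sheet for human coders, the
   funnel statistics (imported → cleaned → keyword-positive → tagged →
   confirmed), and review-burden estimates in full-time equivalents.

Because real state PCR data are restricted, the package includes a
first-class synthetic corpus generator (`generate_corpus()`) that emulates
the statistical structure the pipeline assumes — class-conditional keyword
enrichment, excluded-context confounders, dialect vocabularies, exact-field
duplicates, no-interest records — with a ground-truth sidecar, so every
stage is testable offline.

## Worked example

```r
library(agsurv)
lex    <- fixture_lexicon()
cfg    <- synth_config(n_records = 3000, prevalence = 0.05,
                       keyword_enrichment = 8, seed = 7)
corpus <- generate_corpus(cfg, lex)

report <- clean(corpus$records, seed = 11)
kept   <- harmonize(report$kept, default_maps())
hits   <- keyword_matrix(kept, lex)
stratum <- kept[kept$record_id %in% hits$keyword_positive, ]
schema <- build_schema(kept)
dm     <- build_design_matrix(stratum, hits, schema)

cal    <- calibrate(dm, calibration_config(seed = 5))
model  <- nb_fit(dm)
app    <- apply_model(corpus$records, model, cal$threshold_mean,
                      lex, schema, default_maps(), seed = 11)
```

which prints (`print(report)`, `print(hits)`, `print(cal)`,
`head(nb_importance(model), 5)`, `print(app$funnel)`):

```
<clean_report>
  input:              3060
  duplicates removed: 60
  no-interest removed: 138
  remaining:          2862 (6.5% eliminated)
<keyword_hits> 2862 records scanned, 236 keyword-positive, 135 suppressed matches
<calibration_result> 100 iterations (target sensitivity 0.90)
  threshold:       0.3864 (SD 0.2692)
  tagged fraction: 0.455 (SD 0.087)
  precision:       0.864 (SD 0.110)
  AUC:             0.966 (SD 0.023)
                               feature log_prob_difference  a b  c   d
1 mechanism_of_injury_Struck by animal            3.410396 21 0 78 137
2               incident_location_Farm            3.209725 53 2 46 135
3        mechanism_of_injury_Machinery            2.334256 29 3 70 134
4                         stem:sprayer            1.928791  4 0 95 137
5                            stem:barn            1.705648  3 0 96 137
<funnel_report>
  imported:         3060
  after cleaning:   2862
  keyword-positive: 236
  tagged:           102 (43.2% of keyword-positive, 56.8% reduction)
```

Reading the numbers: the generator planted 3,060 rows (3,000 plus exact-field
duplicates); cleaning removed the 60 duplicates and 138 no-interest records.
Of the cleaned records, 236 contain an unsuppressed agricultural keyword —
only this stratum is ever scored. Calibration finds that tagging records
with posterior ≥ 0.386 (on average) captures ≥ 90% of true cases in every
validation split while tagging under half the stratum, with mean precision
0.86 and AUC 0.97. The most discriminating features are the farm incident
location and animal/machinery mechanisms plus rare but specific keyword
stems — `a`/`b` count the records with the feature among cases/non-cases.
Applying the calibrated threshold tags 102 of 236 keyword-positive records,
a 56.8% reduction in human review volume relative to reviewing every
keyword hit. At published review speed (3.5 min/record, 1,000 h per FTE),
`review_burden(29099)$fte` gives `1.7` FTE versus `review_burden(95545)$fte`
= `5.6` FTE for an uncalibrated keyword search at state scale.

A command-line interface over the same functions ships in
`inst/exec/agsurv.R` (verbs: simulate, clean, scan, featurize, train,
calibrate, importance, apply, confirm, burden).

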