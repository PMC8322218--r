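## End-to-end application of a trained model and calibrated threshold to
## untagged corpora: review-sheet emission, funnel statistics, review-burden
## estimates.

#' Funnel statistics for a surveillance run
#'
#' Pure arithmetic on the record-count cascade imported -> cleaned ->
#' keyword-positive -> tagged (-> confirmed). Validates monotonicity: counts
#' never increase down the funnel.
#'
#' @param n_imported,n_after_cleaning,n_keyword_positive,n_tagged funnel
#'   counts.
#' @param n_confirmed,n_class1,n_class23 optional post-review counts.
#' @return object of class `funnel_report` carrying the counts plus
#'   `tagged_over_keyword_positive` and `reduction_vs_keyword_search`
#'   (percentages; their sum is exactly 100) and, when confirmed counts are
#'   present, `confirmed_over_tagged`.
#' @examples
#' # published application-era counts: 95,545 keyword-positive, 29,099 tagged
#' f <- funnel_report(1923107, 1923107, 95545, 29099)
#' round_half_up(f$reduction_vs_keyword_search, 1) # 69.5
#' @export
funnel_report <- function(n_imported, n_after_cleaning, n_keyword_positive,
                          n_tagged, n_confirmed = NA_integer_,
                          n_class1 = NA_integer_, n_class23 = NA_integer_) {
  counts <- c(n_imported, n_after_cleaning, n_keyword_positive, n_tagged)
  if (any(diff(counts) > 0)) {
    .stopf("funnel counts must be non-increasing (got %s)",
           paste(counts, collapse = " -> "))
  }
  if (!is.na(n_confirmed) && n_confirmed > n_tagged) {
    .stopf("confirmed count exceeds tagged count")
  }
  tagged_pct <- if (n_keyword_positive > 0) 100 * n_tagged / n_keyword_positive else 0
  structure(
    list(
      n_imported = n_imported,
      n_after_cleaning = n_after_cleaning,
      n_keyword_positive = n_keyword_positive,
      n_tagged = n_tagged,
      tagged_over_keyword_positive = tagged_pct,
      reduction_vs_keyword_search = 100 - tagged_pct,
      n_confirmed = n_confirmed,
      confirmed_over_tagged = if (!is.na(n_confirmed) && n_tagged > 0) {
        100 * n_confirmed / n_tagged
      } else {
        NA_real_
      },
      n_class1 = n_class1,
      n_class23 = n_class23
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<funnel_report>\n  imported:         %d\n  after cleaning:   %d\n",
      "  keyword-positive: %d\n  tagged:           %d (%.1f%% of keyword-positive,",
      " %.1f%% reduction)\n"
    ),
    x$n_imported, x$n_after_cleaning, x$n_keyword_positive, x$n_tagged,
    round_half_up(x$tagged_over_keyword_positive, 1),
    round_half_up(x$reduction_vs_keyword_search, 1)
  ))
  if (!is.na(x$n_confirmed)) {
    cat(sprintf("  confirmed:        %d (%.1f%% of tagged)\n",
                x$n_confirmed, round_half_up(x$confirmed_over_tagged, 1)))
  }
  invisible(x)
}

# review-sheet column order (the visual-determination variables, then the
# model output and the two columns coders fill in)
.sheet_columns <- c(
  "record_id", "state", "incident_id", "date_of_birth", "gender",
  "incident_location", "dispatch_reason", "primary_impression",
  "mechanism_of_injury", "admit_date", "stems", "narrative",
  "posterior", "case_class", "comments"
)

#' Apply a trained model to an untagged corpus
#'
#' Runs the full pipeline - clean, harmonize, keyword scan, featurize,
#' posterior scoring - and emits the review sheet of records with posterior at
#' or above the calibrated threshold, together with the funnel report.
#'
#' @param records raw PCR data frame.
#' @param model a fitted `nb_model`.
#' @param threshold calibrated posterior threshold (typically
#'   `threshold_mean` from [calibrate()]); tagging is inclusive
#'   (`posterior >= threshold`).
#' @param lexicon a [keyword_lexicon].
#' @param schema the frozen `feature_schema` the model was trained with.
#' @param maps optional [transformation_map()] applied before featurization.
#' @param seed seed for random duplicate retention during cleaning.
#' @return list with `sheet` (data frame in review-sheet column order:
#'   identifiers, categorical fields, matched stems, narrative, posterior and
#'   empty case-class/comment columns) and `funnel` (a [funnel_report()]).
#' @export
apply_model <- function(records, model, threshold, lexicon, schema,
                        maps = NULL, seed = 1L) {
  stopifnot(inherits(model, "nb_model"), inherits(schema, "feature_schema"))
  cr <- clean(records, seed = seed)
  kept <- cr$kept
  if (!is.null(maps)) kept <- harmonize(kept, maps)
  hits <- keyword_matrix(kept, lexicon)
  stratum <- kept[kept$record_id %in% hits$keyword_positive, , drop = FALSE]

  if (nrow(stratum)) {
    dm <- build_design_matrix(stratum, hits, schema)
    if (!identical(colnames(dm$X), model$feature_names)) {
      .stopf("design matrix does not match the model's feature schema")
    }
    posterior <- nb_posterior(model, dm)
  } else {
    posterior <- numeric(0)
  }
  tagged <- posterior >= threshold
  sheet <- stratum[tagged, , drop = FALSE]
  flag_rows <- hits$flags[sheet$record_id, , drop = FALSE]
  sheet$stems <- if (nrow(sheet)) {
    apply(flag_rows, 1, function(r) paste(colnames(flag_rows)[r == 1L], collapse = ";"))
  } else {
    character(0)
  }
  sheet$posterior <- posterior[tagged]
  sheet$case_class <- NA_integer_
  sheet$comments <- ""
  sheet <- sheet[, .sheet_columns]
  rownames(sheet) <- NULL

  funnel <- funnel_report(
    n_imported = nrow(records),
    n_after_cleaning = nrow(kept),
    n_keyword_positive = nrow(stratum),
    n_tagged = sum(tagged)
  )
  list(sheet = sheet, funnel = funnel)
}

#' Fold adjudicated review results back into the funnel
#'
#' @param sheet a review sheet whose `case_class` column has been filled in
#'   (every row adjudicated 0-3).
#' @param funnel the [funnel_report()] from the same run.
#' @return the updated `funnel_report` with `n_confirmed` (class 1-3),
#'   `n_class1`, `n_class23` and `confirmed_over_tagged`.
#' @export
confirm_counts <- function(sheet, funnel) {
  stopifnot(inherits(funnel, "funnel_report"))
  bad <- is.na(sheet$case_class) | !(sheet$case_class %in% 0:3)
  if (any(bad)) {
    .stopf("unadjudicated or invalid case classes for record(s): %s",
           paste(utils::head(sheet$record_id[bad], 10), collapse = ", "))
  }
  funnel_report(
    n_imported = funnel$n_imported,
    n_after_cleaning = funnel$n_after_cleaning,
    n_keyword_positive = funnel$n_keyword_positive,
    n_tagged = funnel$n_tagged,
    n_confirmed = sum(sheet$case_class %in% 1:3),
    n_class1 = sum(sheet$case_class == 1L),
    n_class23 = sum(sheet$case_class %in% 2:3)
  )
}

#' Per-record review time defaults (minutes)
#'
#' Initial first/second coding 3.5, discrepancy review 6, lead verification
#' 2.5, case-determination questions 5.
#'
#' @return named numeric vector of minutes per record by activity.
#' @export
burden_minutes <- function() {
  c(
    initial_coding = 3.5, discrepancy_review = 6,
    lead_verification = 2.5, question_review = 5
  )
}

#' Estimate the visual-review staffing burden
#'
#' `fte = n_records * minutes_per_record / 60 / hours_per_fte`, reported to
#' one decimal (half-up).
#'
#' @param n_records records to review.
#' @param minutes_per_record minutes per record (see [burden_minutes()];
#'   default: initial coding, 3.5).
#' @param hours_per_fte working hours that constitute one full-time
#'   equivalent (default 1000).
#' @return object of class `burden_estimate` with `fte` (1 decimal) and
#'   `fte_raw`.
#' @examples
#' review_burden(29099)$fte # 1.7
#' @export
review_burden <- function(n_records, minutes_per_record = burden_minutes()[["initial_coding"]],
                          hours_per_fte = 1000) {
  if (!.scalar(n_records, function(x) x >= 0)) .stopf("n_records must be >= 0")
  if (!.scalar(hours_per_fte, function(x) x > 0)) {
    .stopf("hours_per_fte must be positive")
  }
  fte_raw <- n_records * minutes_per_record / 60 / hours_per_fte
  structure(
    list(
      n_records = n_records, minutes_per_record = minutes_per_record,
      hours_per_fte = hours_per_fte, fte_raw = fte_raw,
      fte = round_half_up(fte_raw, 1)
    ),
    class = "burden_estimate"
  )
}

#' @export
print.burden_estimate <- function(x, ...) {
  cat(sprintf(
    "<burden_estimate> %d records x %.1f min / %g h per FTE = %.1f FTE\n",
    x$n_records, x$minutes_per_record, x$hours_per_fte, x$fte
  ))
  invisible(x)
}
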