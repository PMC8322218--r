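## Record cleaning: exact-match deduplication and removal of records of no
## interest. Runs before any narrative processing, mirroring the upstream
## order of operations (structured-field cleaning first, text second).

#' Column schema of a PCR corpus
#'
#' One row per EMS encounter: identifiers, categorical fields, a free-text
#' narrative and an optional four-level case class (0 = not a case;
#' 1 = confirmed agricultural + confirmed traumatic/acute; 2 = confirmed
#' traumatic/acute + suspected agricultural; 3 = suspected traumatic/acute +
#' confirmed agricultural).
#'
#' @return character vector of column names in canonical order.
#' @export
pcr_columns <- function() {
  c(
    "record_id", "state", "incident_id", "date_of_birth", "gender",
    "admit_date", "zip_code", "incident_location", "dispatch_reason",
    "primary_impression", "mechanism_of_injury", "destination_type",
    "narrative", "case_class"
  )
}

#' Read / write PCR corpora as CSV
#'
#' UTF-8, RFC 4180 quoting; empty cells are missing values. `case_class` may
#' be entirely blank (an untagged corpus).
#'
#' @param path file path.
#' @return `read_pcr_csv` returns a data frame with the [pcr_columns()]
#'   schema; `write_pcr_csv` invisibly returns `path`.
#' @export
read_pcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = "")
  missing <- setdiff(pcr_columns(), names(df))
  if (length(missing)) .stopf("PCR file lacks columns: %s", paste(missing, collapse = ", "))
  df <- df[, pcr_columns()]
  df$case_class <- suppressWarnings(as.integer(df$case_class))
  df$narrative[is.na(df$narrative)] <- ""
  validate_pcr(df)
}

#' @rdname read_pcr_csv
#' @param records PCR data frame.
#' @export
write_pcr_csv <- function(records, path) {
  utils::write.csv(records[, pcr_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a PCR data frame
#'
#' Checks the invariants: record ids unique, case class (when present) in
#' 0..3.
#'
#' @param records PCR data frame.
#' @return `records`, invisibly validated (returned unchanged).
#' @export
validate_pcr <- function(records) {
  if (anyDuplicated(records$record_id)) .stopf("record_id values must be unique")
  cc <- records$case_class[!is.na(records$case_class)]
  if (length(cc) && !all(cc %in% 0:3)) .stopf("case_class must be in {0,1,2,3}")
  records
}

# the four-variable duplicate key
.dedup_fields <- c("gender", "admit_date", "zip_code", "date_of_birth")

## Group key for duplicate detection; NA for any record with a missing
## identifier field (missing never equals missing).
.dedup_key <- function(records) {
  vals <- lapply(records[.dedup_fields], as.character)
  miss <- Reduce(`|`, lapply(vals, .is_missing))
  key <- do.call(paste, c(vals, sep = "\r"))
  key[miss] <- NA_character_
  key
}

#' Remove exact duplicates on the four identifier fields
#'
#' Records agreeing exactly on gender, admit date, ZIP code and date of birth
#' are considered duplicates; one per group is retained, chosen uniformly at
#' random. The retention draw is seeded per group from the sorted member ids,
#' so the result is invariant to input reordering. A missing value in any of
#' the four fields exempts a record from grouping entirely.
#'
#' @param records PCR data frame.
#' @param seed integer RNG seed for the random retention.
#' @return list with `kept` (data frame, input order preserved) and
#'   `removed_count`.
#' @export
deduplicate <- function(records, seed = 1L) {
  if (!nrow(records)) {
    return(list(kept = records, removed_count = 0L))
  }
  key <- .dedup_key(records)
  keep <- rep(TRUE, nrow(records))
  groups <- split(seq_len(nrow(records)), key)
  for (g in groups) {
    if (length(g) < 2L) next
    ids <- sort(records$record_id[g])
    gseed <- derive_seed(seed, sum(utf8ToInt(paste(ids, collapse = ""))))
    keep_id <- ids[withr_seed_sample(gseed, length(g))]
    keep[g[records$record_id[g] != keep_id]] <- FALSE
  }
  list(kept = records[keep, , drop = FALSE], removed_count = sum(!keep))
}

## draw one index in 1..n under a local seed without disturbing the caller's
## RNG state
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n, 1L)
}

# canonical no-interest labels
.no_interest_dispatch <- c("transfer", "lifting", "intercept")
.no_interest_destination <- "nursing home"

#' Remove records of no interest
#'
#' Drops records with a dispatch reason of transfer, lifting or intercept, or
#' a destination type of nursing home. Labels are compared case-insensitively
#' after trimming; missing values never match.
#'
#' @param records PCR data frame.
#' @return list with `kept` and `removed_count`.
#' @export
filter_no_interest <- function(records) {
  if (!nrow(records)) {
    return(list(kept = records, removed_count = 0L))
  }
  disp <- tolower(trimws(as.character(records$dispatch_reason)))
  dest <- tolower(trimws(as.character(records$destination_type)))
  drop <- (!.is_missing(records$dispatch_reason) & disp %in% .no_interest_dispatch) |
    (!.is_missing(records$destination_type) & dest %in% .no_interest_destination)
  list(kept = records[!drop, , drop = FALSE], removed_count = sum(drop))
}

#' Clean a PCR corpus
#'
#' Two deterministic steps in fixed order: [deduplicate()] then
#' [filter_no_interest()].
#'
#' @param records PCR data frame.
#' @param seed integer seed for random duplicate retention.
#' @return an object of class `clean_report`: list with `kept` (the cleaned
#'   data frame), `n_input`, `n_duplicates_removed`, `n_no_interest_removed`,
#'   `n_remaining` and `percent_eliminated`.
#' @examples
#' # report arithmetic on supplied counts:
#' # 1,072,745 in, 224,572 eliminated -> 20.9% eliminated
#' @export
clean <- function(records, seed = 1L) {
  dd <- deduplicate(records, seed)
  fi <- filter_no_interest(dd$kept)
  clean_report(
    n_input = nrow(records),
    n_duplicates_removed = dd$removed_count,
    n_no_interest_removed = fi$removed_count,
    kept = fi$kept
  )
}

#' Assemble a cleaning report from counts
#'
#' Pure arithmetic on the counts, usable directly on externally reported
#' figures as well as on [clean()] output.
#'
#' @param n_input records before cleaning.
#' @param n_duplicates_removed,n_no_interest_removed records removed by each
#'   step.
#' @param kept optional cleaned data frame.
#' @return a `clean_report` object.
#' @export
clean_report <- function(n_input, n_duplicates_removed, n_no_interest_removed,
                         kept = NULL) {
  removed <- n_duplicates_removed + n_no_interest_removed
  n_remaining <- n_input - removed
  if (!is.null(kept) && nrow(kept) != n_remaining) {
    .stopf("conservation violated: kept %d != input %d - removed %d",
           nrow(kept), n_input, removed)
  }
  structure(
    list(
      kept = kept,
      n_input = n_input,
      n_duplicates_removed = n_duplicates_removed,
      n_no_interest_removed = n_no_interest_removed,
      n_remaining = n_remaining,
      percent_eliminated = if (n_input > 0) 100 * removed / n_input else 0
    ),
    class = "clean_report"
  )
}

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<clean_report>\n  input:              %d\n  duplicates removed: %d\n",
      "  no-interest removed: %d\n  remaining:          %d (%.1f%% eliminated)\n"
    ),
    x$n_input, x$n_duplicates_removed, x$n_no_interest_removed,
    x$n_remaining, round_half_up(x$percent_eliminated, 1)
  ))
  invisible(x)
}
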