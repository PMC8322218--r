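## Categorical harmonization across state/year dialects and construction of
## the binary design matrix (keyword flags + one-hot category dummies).

# variables that receive transformation maps
.map_variables <- c("incident_location", "mechanism_of_injury",
                    "dispatch_reason", "primary_impression", "destination_type")

#' Default feature variables
#'
#' The categorical variables one-hot encoded into the design matrix.
#' Identifier fields (date of birth, admit date, ZIP, state) are used for
#' deduplication and reporting only; encoding them as dummies would explode
#' cardinality and leak identity.
#'
#' @return character vector of variable names.
#' @export
schema_default_variables <- function() {
  c("incident_location", "mechanism_of_injury", "dispatch_reason",
    "primary_impression", "gender")
}

#' Build a transformation map table
#'
#' A transformation map links a dialect's raw categorical labels to canonical
#' labels, one row per (variable, dialect, raw, canonical).
#'
#' @param variable,dialect,raw,canonical equal-length character vectors.
#' @return data frame of class `transformation_map`.
#' @export
transformation_map <- function(variable, dialect, raw, canonical) {
  df <- data.frame(variable = variable, dialect = dialect, raw = raw,
                   canonical = canonical, stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("variable", "dialect", "raw")])
  if (any(dup)) .stopf("duplicate (variable, dialect, raw) map entries")
  class(df) <- c("transformation_map", "data.frame")
  df
}

#' Default transformation maps for the shipped dialects
#'
#' Inverts the [default_dialects()] vocabularies into a map table.
#'
#' @param dialects dialect list (default [default_dialects()]).
#' @return a [transformation_map()] data frame.
#' @export
default_maps <- function(dialects = default_dialects()) {
  rows <- list()
  for (d in dialects) {
    for (v in intersect(names(d$vocab), .map_variables)) {
      voc <- d$vocab[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, dialect = d$state, raw = unname(voc),
        canonical = names(voc), stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  transformation_map(df$variable, df$dialect, df$raw, df$canonical)
}

#' Read / write transformation maps as CSV
#' @param path file path.
#' @return `read_maps_csv` returns a [transformation_map()].
#' @export
read_maps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  transformation_map(df$variable, df$dialect, df$raw, df$canonical)
}

#' @rdname read_maps_csv
#' @param maps a [transformation_map()].
#' @export
write_maps_csv <- function(maps, path) {
  utils::write.csv(as.data.frame(maps), path, row.names = FALSE)
  invisible(path)
}

#' Harmonize categorical labels to the canonical vocabulary
#'
#' Replaces mapped variables' raw labels by their canonical labels for each
#' record's dialect. Raw labels without a map entry pass through unchanged
#' with a warning; an entirely unknown dialect is a configuration error.
#'
#' @param records PCR data frame.
#' @param maps a [transformation_map()] (or `NULL` for identity).
#' @param dialect character vector of dialect keys, one per record; defaults
#'   to the record's state.
#' @return the records with mapped variables replaced by canonical labels.
#' @export
harmonize <- function(records, maps, dialect = records$state) {
  if (is.null(maps) || !nrow(maps)) {
    return(records)
  }
  unknown <- setdiff(unique(dialect), unique(maps$dialect))
  if (length(unknown)) {
    .stopf("dialect(s) not present in the transformation maps: %s",
           paste(unknown, collapse = ", "))
  }
  unmapped <- character(0)
  for (v in intersect(unique(maps$variable), names(records))) {
    sub <- maps[maps$variable == v, , drop = FALSE]
    key <- paste(dialect, records[[v]], sep = "\r")
    idx <- match(key, paste(sub$dialect, sub$raw, sep = "\r"))
    found <- !is.na(idx) & !is.na(records[[v]])
    miss <- is.na(idx) & !is.na(records[[v]])
    if (any(miss)) {
      unmapped <- c(unmapped, paste0(v, ": ", unique(records[[v]][miss])))
    }
    records[[v]][found] <- sub$canonical[idx[found]]
  }
  if (length(unmapped)) {
    warning(sprintf("unmapped raw labels passed through unchanged: %s",
                    paste(unique(unmapped), collapse = "; ")), call. = FALSE)
  }
  records
}

#' Freeze a one-hot schema from training data
#'
#' Records the observed levels of each feature variable so the same design
#' matrix columns can be rebuilt on new data (unseen levels collapse to the
#' explicit "missing" level).
#'
#' @param records harmonized PCR data frame.
#' @param variables variables to encode (default
#'   [schema_default_variables()]).
#' @return object of class `feature_schema`.
#' @export
build_schema <- function(records, variables = schema_default_variables()) {
  lv <- lapply(variables, function(v) {
    x <- records[[v]]
    sort(unique(x[!.is_missing(x)]))
  })
  names(lv) <- variables
  structure(list(variables = lv), class = "feature_schema")
}

#' Read / write a frozen schema as JSON
#' @param path file path.
#' @return `read_schema_json` returns a `feature_schema`.
#' @export
read_schema_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- lapply(raw$variables, as.character)
  structure(list(variables = lv), class = "feature_schema")
}

#' @rdname read_schema_json
#' @param schema a `feature_schema`.
#' @export
write_schema_json <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Build the binary design matrix
#'
#' Columns are the lexicon stems (provenance `stem:<s>`, in lexicon order)
#' followed by one (0,1) column per frozen level of each schema variable plus
#' an explicit missing level (`<variable>_<level>`). Per variable, exactly one
#' level column is set in every row. The binary outcome label is derived from
#' `case_class` (1 iff class 1-3) when the corpus is fully labeled.
#'
#' @param records harmonized PCR data frame (the rows to encode, typically
#'   the keyword-positive stratum).
#' @param hits a `keyword_hits` object from [keyword_matrix()] covering at
#'   least these records.
#' @param schema a frozen `feature_schema` from [build_schema()].
#' @return object of class `design_matrix`: list with `row_ids`, `X` (binary
#'   integer matrix), `label` (0/1 vector or `NULL`), `schema`.
#' @export
build_design_matrix <- function(records, hits, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  idx <- match(records$record_id, rownames(hits$flags))
  if (anyNA(idx)) {
    .stopf("records and keyword hits are misaligned: %d record(s) missing from hits",
           sum(is.na(idx)))
  }
  stem_block <- hits$flags[idx, , drop = FALSE]
  colnames(stem_block) <- paste0("stem:", colnames(stem_block))

  blocks <- list(stem_block)
  for (v in names(schema$variables)) {
    levels_v <- c(schema$variables[[v]], "missing")
    x <- as.character(records[[v]])
    x[.is_missing(x) | !(x %in% schema$variables[[v]])] <- "missing"
    m <- matrix(0L, nrow = nrow(records), ncol = length(levels_v),
                dimnames = list(NULL, paste0(v, "_", levels_v)))
    m[cbind(seq_len(nrow(records)), match(x, levels_v))] <- 1L
    blocks[[length(blocks) + 1L]] <- m
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- records$record_id

  label <- NULL
  if (!anyNA(records$case_class)) {
    label <- as.integer(records$case_class %in% 1:3)
  }
  structure(
    list(row_ids = records$record_id, X = X, label = label, schema = schema),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d records x %d binary features%s\n",
    nrow(x$X), ncol(x$X),
    if (is.null(x$label)) " (unlabeled)" else {
      sprintf(" (%d positive / %d negative)", sum(x$label == 1), sum(x$label == 0))
    }
  ))
  invisible(x)
}
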