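## Narrative normalization, stemming and keyword detection.
##
## Matching is position-based on stemmed tokens: a lexicon stem fires when a
## stemmed token (or, for multi-word stems, a run of consecutive stemmed
## tokens joined by "_") equals the stem or begins with it.  Prefix semantics
## are deliberate: table stems such as "irrig" or "fenc" are meant to catch
## "irrigation", "fencing", etc.

#' Normalize a narrative into tokens
#'
#' Lower-cases the text, replaces every non-alphanumeric character by a space
#' and splits on whitespace. Punctuation and case therefore never influence
#' keyword matching.
#'
#' @param narrative character scalar (free text; may be empty or `NA`).
#' @return character vector of tokens (possibly empty).
#' @examples
#' normalize_text("Pt FELL from hay-loft!!")
#' @export
normalize_text <- function(narrative) {
  if (length(narrative) != 1L) .stopf("normalize_text() expects a single narrative")
  if (is.na(narrative) || !nzchar(narrative)) {
    return(character(0))
  }
  x <- gsub("[^a-z0-9]+", " ", tolower(narrative))
  toks <- strsplit(trimws(x), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Stem normalized tokens
#'
#' Applies the English Snowball stemmer to each token. Collision words -
#' raw words that would stem to the same value as a keyword (the classic
#' example: "animate" collides with "animal") - are removed *before*
#' stemming.
#'
#' @param tokens character vector from [normalize_text()].
#' @param collision_words raw words to drop prior to stemming (usually
#'   `lexicon$collision_words`).
#' @return character vector of stems.
#' @export
stem_tokens <- function(tokens, collision_words = character(0)) {
  if (length(collision_words)) tokens <- tokens[!(tokens %in% collision_words)]
  snowball_stem(tokens)
}

## Pre-stem the pieces of a lexicon that matching needs repeatedly.
.compile_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "keyword_lexicon"))
  parts <- strsplit(lexicon$stems, "_", fixed = TRUE)
  list(
    stems = lexicon$stems,
    nparts = lengths(parts),
    collision_words = lexicon$collision_words,
    suffix_stems = unique(snowball_stem(lexicon$address_suffixes)),
    phrases = lexicon$exclusion_phrases,
    phrase_tokens = lapply(lexicon$exclusion_phrases, function(p) {
      stem_tokens(normalize_text(p))
    })
  )
}

## All [start, end] occurrences of the exclusion phrases in a stem sequence.
.phrase_spans <- function(toks, comp) {
  spans <- list()
  n <- length(toks)
  for (pi in seq_along(comp$phrase_tokens)) {
    p <- comp$phrase_tokens[[pi]]
    m <- length(p)
    if (!m || m > n) next
    for (i in which(toks == p[1])) {
      if (i + m - 1L <= n && all(toks[i:(i + m - 1L)] == p)) {
        spans[[length(spans) + 1L]] <- c(i, i + m - 1L, pi)
      }
    }
  }
  spans
}

.match_one <- function(toks, comp) {
  nstem <- length(comp$stems)
  flags <- integer(nstem)
  names(flags) <- comp$stems
  sup_stem <- character(0)
  sup_reason <- character(0)
  n <- length(toks)
  if (!n) {
    return(list(flags = flags, suppressed = data.frame(
      stem = character(0), reason = character(0), stringsAsFactors = FALSE
    )))
  }
  spans <- .phrase_spans(toks, comp)
  joined <- list(toks)
  maxk <- max(comp$nparts)
  if (maxk >= 2L) {
    for (k in 2:maxk) {
      joined[[k]] <- if (n >= k) {
        cols <- lapply(0:(k - 1L), function(o) toks[(1L + o):(n - k + 1L + o)])
        do.call(paste, c(cols, sep = "_"))
      } else {
        character(0)
      }
    }
  }
  for (s in seq_len(nstem)) {
    k <- comp$nparts[s]
    cand <- which(startsWith(joined[[k]], comp$stems[s]))
    if (!length(cand)) next
    for (i in cand) {
      j <- i + k - 1L
      reason <- NULL
      for (sp in spans) {
        if (sp[1] <= i && j <= sp[2]) {
          reason <- paste0("exclusion_phrase: ", comp$phrases[sp[3]])
          break
        }
      }
      if (is.null(reason) && j < n && toks[j + 1L] %in% comp$suffix_stems) {
        reason <- paste0("address_suffix: ", toks[j + 1L])
      }
      if (is.null(reason)) {
        flags[s] <- 1L
      } else {
        sup_stem <- c(sup_stem, comp$stems[s])
        sup_reason <- c(sup_reason, reason)
      }
    }
  }
  list(flags = flags, suppressed = data.frame(
    stem = sup_stem, reason = sup_reason, stringsAsFactors = FALSE
  ))
}

#' Scan one record's narrative for lexicon keywords
#'
#' Flags stem `j` when it occurs in the stemmed token sequence (multi-word
#' stems match consecutive token n-grams joined by `_`) and no exclusion
#' applies. A match is suppressed when (a) it lies inside an occurrence of an
#' exclusion phrase, or (b) the token immediately following it is an address
#' suffix. Suppressed matches are reported with their reason.
#'
#' @param record a one-row PCR data frame (or any list with `record_id` and
#'   `narrative`).
#' @param lexicon a [keyword_lexicon].
#' @return list with `record_id`, `flags` (named 0/1 integer vector aligned to
#'   `lexicon$stems`) and `suppressed` (data frame of stem, reason).
#' @examples
#' lex <- fixture_lexicon()
#' hit <- match_keywords(
#'   list(record_id = "r1", narrative = "pinned under tractor near the barn"),
#'   lex
#' )
#' names(which(hit$flags == 1))
#' @export
match_keywords <- function(record, lexicon) {
  comp <- .compile_lexicon(lexicon)
  narr <- if (is.data.frame(record)) record$narrative[1] else record$narrative
  id <- if (is.data.frame(record)) record$record_id[1] else record$record_id
  toks <- stem_tokens(normalize_text(narr), comp$collision_words)
  res <- .match_one(toks, comp)
  list(record_id = id, flags = res$flags, suppressed = res$suppressed)
}

#' Keyword flag matrix for a corpus
#'
#' Runs [match_keywords()] over every record and assembles the binary
#' records-by-stems matrix, together with the keyword-positive stratum (the
#' records with at least one non-suppressed keyword) - the only records the
#' classifier ever scores.
#'
#' @param records PCR data frame (see [read_pcr_csv()] for the schema).
#' @param lexicon a [keyword_lexicon].
#' @return an object of class `keyword_hits`: list with `flags` (integer
#'   matrix, rownames = record ids), `keyword_positive` (character vector of
#'   record ids) and `suppressed` (data frame record_id, stem, reason).
#' @export
keyword_matrix <- function(records, lexicon) {
  comp <- .compile_lexicon(lexicon)
  n <- nrow(records)
  flags <- matrix(0L, nrow = n, ncol = length(comp$stems),
                  dimnames = list(records$record_id, comp$stems))
  sup <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- stem_tokens(normalize_text(records$narrative[i]), comp$collision_words)
    res <- .match_one(toks, comp)
    flags[i, ] <- res$flags
    if (nrow(res$suppressed)) {
      sup[[i]] <- cbind(record_id = records$record_id[i], res$suppressed)
    }
  }
  sup <- if (any(!vapply(sup, is.null, logical(1)))) {
    do.call(rbind, sup[!vapply(sup, is.null, logical(1))])
  } else {
    data.frame(record_id = character(0), stem = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  structure(
    list(
      flags = flags,
      keyword_positive = records$record_id[rowSums(flags) > 0],
      suppressed = sup
    ),
    class = "keyword_hits"
  )
}

#' @export
print.keyword_hits <- function(x, ...) {
  cat(sprintf(
    "<keyword_hits> %d records scanned, %d keyword-positive, %d suppressed matches\n",
    nrow(x$flags), length(x$keyword_positive), nrow(x$suppressed)
  ))
  invisible(x)
}
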