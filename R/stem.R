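## English Snowball ("Porter2") stemmer.
##
## Implemented here in full because keyword matching operates on stems and the
## lexicon entries are themselves Snowball stems.  The implementation follows
## the published algorithm definition: regions R1/R2, y/Y marking, steps 0-5
## with longest-suffix-wins semantics (a matched suffix outside its required
## region blocks shorter alternatives; there is no backtracking).

.p2_vowels <- c("a", "e", "i", "o", "u", "y")

.p2_exceptions <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  # invariant forms
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.p2_exceptions2 <- c(
  "inning", "outing", "canning", "herring", "earring",
  "proceed", "exceed", "succeed"
)

## y at word start, or y following a vowel, acts as a consonant: mark it "Y"
## (uppercase is outside the vowel set) and restore at the end.
.p2_mark_y <- function(ch) {
  if (ch[1] == "y") ch[1] <- "Y"
  if (length(ch) > 1) {
    for (i in 2:length(ch)) {
      if (ch[i] == "y" && ch[i - 1] %in% .p2_vowels) ch[i] <- "Y"
    }
  }
  ch
}

## R1 = region after the first vowel followed by a non-vowel (special-cased
## for gener-/commun-/arsen- prefixes); R2 = same rule applied inside R1.
## Returned as start positions; n+1 means the region is empty.
.p2_regions <- function(ch) {
  n <- length(ch)
  w <- paste(ch, collapse = "")
  r1 <- n + 1L
  for (p in c("gener", "commun", "arsen")) {
    if (startsWith(w, p)) {
      r1 <- nchar(p) + 1L
      break
    }
  }
  v <- ch %in% .p2_vowels
  if (r1 == n + 1L && n > 1L) {
    for (i in 1:(n - 1)) {
      if (v[i] && !v[i + 1]) {
        r1 <- i + 2L
        break
      }
    }
  }
  r2 <- n + 1L
  if (r1 <= n - 1L) {
    for (i in r1:(n - 1)) {
      if (v[i] && !v[i + 1]) {
        r2 <- i + 2L
        break
      }
    }
  }
  c(r1 = r1, r2 = r2)
}

.p2_has_vowel <- function(s) {
  any(strsplit(s, "", fixed = TRUE)[[1]] %in% .p2_vowels)
}

## Does `w` end in a short syllable?  Either a two-letter word beginning
## vowel + non-vowel, or ... non-vowel, vowel, non-vowel (last not w/x/Y).
.p2_ends_short_syllable <- function(w) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(ch)
  v <- ch %in% .p2_vowels
  if (n == 2) {
    return(v[1] && !v[2])
  }
  if (n < 3) {
    return(FALSE)
  }
  !v[n - 2] && v[n - 1] && !v[n] && !(ch[n] %in% c("w", "x", "Y"))
}

.p2_stem_one <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2) {
    return(w)
  }
  if (startsWith(w, "'")) w <- substr(w, 2, nchar(w))
  hit <- .p2_exceptions[w]
  if (!is.na(hit)) {
    return(unname(hit))
  }
  if (nchar(w) <= 2) {
    return(w)
  }

  ch <- .p2_mark_y(strsplit(w, "", fixed = TRUE)[[1]])
  w <- paste(ch, collapse = "")
  reg <- .p2_regions(ch)
  r1 <- reg[["r1"]]
  r2 <- reg[["r2"]]

  n <- function() nchar(w)
  chop <- function(k) substr(w, 1, nchar(w) - k)
  in_r1 <- function(suf) nchar(w) - nchar(suf) + 1L >= r1
  in_r2 <- function(suf) nchar(w) - nchar(suf) + 1L >= r2

  ## --- step 0: strip apostrophe suffixes
  for (suf in c("'s'", "'s", "'")) {
    if (endsWith(w, suf)) {
      w <- chop(nchar(suf))
      break
    }
  }

  ## --- step 1a
  if (endsWith(w, "sses")) {
    w <- paste0(chop(4), "ss")
  } else if (endsWith(w, "ied") || endsWith(w, "ies")) {
    w <- if (n() - 3L > 1L) paste0(chop(3), "i") else paste0(chop(3), "ie")
  } else if (endsWith(w, "us") || endsWith(w, "ss")) {
    # leave alone
  } else if (endsWith(w, "s")) {
    # delete if the preceding part contains a vowel not immediately before s
    if (n() > 2L && .p2_has_vowel(substr(w, 1, n() - 2L))) w <- chop(1)
  }

  if (w %in% .p2_exceptions2) {
    return(chartr("Y", "y", w))
  }

  ## --- step 1b
  s1b <- c("eedly", "ingly", "edly", "eed", "ing", "ed")
  suf <- s1b[vapply(s1b, function(s) endsWith(w, s), logical(1))][1]
  if (!is.na(suf)) {
    if (suf %in% c("eed", "eedly")) {
      if (in_r1(suf)) w <- paste0(chop(nchar(suf)), "ee")
    } else {
      pre <- chop(nchar(suf))
      if (.p2_has_vowel(pre)) {
        w <- pre
        doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
        last2 <- substr(w, max(1L, n() - 1L), n())
        if (last2 %in% c("at", "bl", "iz")) {
          w <- paste0(w, "e")
        } else if (last2 %in% doubles) {
          w <- chop(1)
        } else if (r1 > n() && .p2_ends_short_syllable(w)) {
          # word is short: ends in a short syllable and R1 is empty
          w <- paste0(w, "e")
        }
      }
    }
  }

  ## --- step 1c: y -> i when preceded by a non-vowel that is not the first letter
  last <- substr(w, n(), n())
  if ((last == "y" || last == "Y") && n() > 2L) {
    prev <- substr(w, n() - 1L, n() - 1L)
    if (!(prev %in% .p2_vowels)) w <- paste0(chop(1), "i")
  }

  ## --- step 2 (condition: suffix in R1); longest match wins, no fallback
  step2 <- list(
    c("ational", "ate"), c("fulness", "ful"), c("iveness", "ive"),
    c("ization", "ize"), c("ousness", "ous"),
    c("biliti", "ble"), c("lessli", "less"), c("tional", "tion"),
    c("alism", "al"), c("aliti", "al"), c("ation", "ate"), c("entli", "ent"),
    c("fulli", "ful"), c("iviti", "ive"), c("ousli", "ous"),
    c("abli", "able"), c("alli", "al"), c("anci", "ance"), c("ator", "ate"),
    c("enci", "ence"), c("izer", "ize"),
    c("bli", "ble"), c("ogi", "og"),
    c("li", "")
  )
  for (m in step2) {
    if (endsWith(w, m[1])) {
      if (in_r1(m[1])) {
        if (m[1] == "ogi") {
          if (substr(w, n() - 3L, n() - 3L) == "l") w <- paste0(chop(3), "og")
        } else if (m[1] == "li") {
          li_ok <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")
          if (substr(w, n() - 2L, n() - 2L) %in% li_ok) w <- chop(2)
        } else {
          w <- paste0(chop(nchar(m[1])), m[2])
        }
      }
      break
    }
  }

  ## --- step 3 (condition: suffix in R1; "ative" additionally needs R2)
  step3 <- list(
    c("ational", "ate"), c("tional", "tion"),
    c("alize", "al"), c("icate", "ic"), c("iciti", "ic"), c("ative", ""),
    c("ical", "ic"), c("ness", ""), c("ful", "")
  )
  for (m in step3) {
    if (endsWith(w, m[1])) {
      if (in_r1(m[1])) {
        if (m[1] == "ative") {
          if (in_r2("ative")) w <- chop(5)
        } else {
          w <- paste0(chop(nchar(m[1])), m[2])
        }
      }
      break
    }
  }

  ## --- step 4 (condition: suffix in R2)
  step4 <- c(
    "ement",
    "ance", "ence", "able", "ible", "ment",
    "ant", "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
    "al", "er", "ic"
  )
  for (suf in step4) {
    if (endsWith(w, suf)) {
      if (in_r2(suf)) {
        if (suf == "ion") {
          if (substr(w, n() - 3L, n() - 3L) %in% c("s", "t")) w <- chop(3)
        } else {
          w <- chop(nchar(suf))
        }
      }
      break
    }
  }

  ## --- step 5
  if (endsWith(w, "e")) {
    if (in_r2("e") || (in_r1("e") && !.p2_ends_short_syllable(chop(1)))) {
      w <- chop(1)
    }
  } else if (endsWith(w, "l")) {
    if (in_r2("l") && substr(w, n() - 1L, n() - 1L) == "l") w <- chop(1)
  }

  chartr("Y", "y", w)
}

# memo cache: narratives reuse a small vocabulary, so caching dominates cost
.p2_cache <- new.env(parent = emptyenv())

#' Stem words with the English Snowball (Porter2) algorithm
#'
#' Reduces each word to its Snowball stem, the same normalization the keyword
#' lexicon entries use (e.g. `"fencing"` -> `"fenc"`, `"hooves"` -> `"hoov"`,
#' `"irrigation"` -> `"irrig"`). Input is lower-cased first; results are
#' memoised across calls.
#'
#' @param words character vector of single words (no whitespace).
#' @return character vector of stems, same length as `words`.
#' @examples
#' snowball_stem(c("tractors", "fencing", "hooves", "pasture"))
#' @export
snowball_stem <- function(words) {
  if (!length(words)) {
    return(character(0))
  }
  words <- tolower(as.character(words))
  out <- character(length(words))
  for (u in unique(words)) {
    if (!nzchar(u)) next
    s <- .p2_cache[[u]]
    if (is.null(s)) {
      s <- .p2_stem_one(u)
      assign(u, s, envir = .p2_cache)
    }
    out[words == u] <- s
  }
  out
}
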