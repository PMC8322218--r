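## Keyword lexicon: stemmed keywords plus exclusion machinery.

#' Construct a keyword lexicon
#'
#' A lexicon bundles the stemmed keywords the narrative scanner looks for with
#' the three kinds of exclusion rules that cancel spurious matches:
#' `exclusion_phrases` (a keyword occurrence lying inside one of these token
#' sequences is suppressed - street names, business names, proper nouns),
#' `collision_words` (raw words removed *before* stemming because they stem to
#' the same value as a keyword, e.g. "animate" vs "animal"), and
#' `address_suffixes` (a keyword immediately followed by one of these tokens
#' is suppressed, e.g. "barn rd").
#'
#' @param stems character vector of Snowball stems; multi-word stems join
#'   their parts with `_` (e.g. `"grain_bin"`).
#' @param exclusion_phrases character vector of raw phrases.
#' @param collision_words character vector of raw (unstemmed) words.
#' @param address_suffixes character vector of address-suffix tokens.
#' @return an object of class `keyword_lexicon`.
#' @seealso [fixture_lexicon()] for the shipped default.
#' @export
keyword_lexicon <- function(stems,
                            exclusion_phrases = character(0),
                            collision_words = character(0),
                            address_suffixes = character(0)) {
  stems <- unique(tolower(as.character(stems)))
  if (!length(stems)) .stopf("lexicon must contain at least one stem")
  if (any(grepl("[[:space:]]", stems))) {
    .stopf("stems must not contain whitespace; join multi-word stems with '_'")
  }
  if (any(grepl("[^a-z0-9_]", stems))) {
    .stopf("stems must be lower-case alphanumeric (plus '_')")
  }
  structure(
    list(
      stems = stems,
      exclusion_phrases = unique(tolower(as.character(exclusion_phrases))),
      collision_words = unique(tolower(as.character(collision_words))),
      address_suffixes = unique(tolower(as.character(address_suffixes)))
    ),
    class = "keyword_lexicon"
  )
}

#' @export
print.keyword_lexicon <- function(x, ...) {
  cat(sprintf(
    "<keyword_lexicon> %d stems, %d exclusion phrases, %d collision words, %d address suffixes\n",
    length(x$stems), length(x$exclusion_phrases),
    length(x$collision_words), length(x$address_suffixes)
  ))
  invisible(x)
}

# The 119 published agricultural keyword stems.
.fixture_stems <- c(
  "3_point_hitch", "chain", "farmer", "hors", "plowshar", "stall",
  "agricultur", "chain_saw", "feed", "implement", "poultri", "straw",
  "anim", "chainsaw", "fenc", "irrig", "prune", "tedder",
  "arch", "chicken", "fenc_post", "kickback", "pto", "three_point_hitch",
  "auger", "choker", "fertil", "kicker", "ram", "tie_down",
  "bale", "chute", "fop", "limb", "sanit", "timber",
  "barn", "cleanser", "forestri", "livestock", "scraper", "tractor",
  "beater", "combin", "gator", "loader", "shear", "tree",
  "bind", "compost", "gear", "log", "sheav", "trough",
  "blade", "corral", "goat", "logger", "sheep", "turkey",
  "bobcat", "coveral", "grain_bin", "manur", "silag", "udder",
  "breed", "cow", "greenhous", "methan", "silo", "uncap",
  "buck", "crop", "guywir", "milk", "skid_steer", "unhitch",
  "buggi", "dairi", "harrow", "mower", "skidder", "vacuum_pump",
  "bull", "debark", "hay", "pastur", "skidsteer", "wagon",
  "bulldoz", "defac", "hitch", "pen", "slaughter", "winch",
  "bunker", "digger", "hog", "pesticid", "splitter", "wood",
  "cabl", "drive_line", "hoof", "pig", "sprayer", "yard",
  "calv", "entangl", "hoof_trimmer", "pipelin", "spreader", "yearl",
  "cart", "farm", "hoov", "plow", "spring_pole"
)

#' The shipped agricultural keyword lexicon
#'
#' The 119 published stemmed agricultural keywords (multi-word stems
#' underscore-joined, e.g. `"grain_bin"`, `"three_point_hitch"`,
#' `"skid_steer"`), together with a starter exclusion set: the
#' "animate" stem-collision word (it stems to the same value as "animal"),
#' a handful of proper-noun exclusion phrases of the kind iterative review
#' accumulates (place names and businesses that contain keywords), and the
#' common address-suffix tokens.
#'
#' @return a [keyword_lexicon].
#' @examples
#' lex <- fixture_lexicon()
#' "grain_bin" %in% lex$stems
#' @export
fixture_lexicon <- function() {
  keyword_lexicon(
    stems = .fixture_stems,
    exclusion_phrases = c(
      "farmington", "farmingdale", "state farm",
      "woodstock", "woodland heights", "penacook", "ramada"
    ),
    collision_words = c("animate", "animated", "animation"),
    address_suffixes = c(
      "rd", "road", "st", "street", "ln", "lane", "dr", "drive",
      "ave", "av", "avenue", "blvd", "hwy", "ct", "cir", "pl", "way"
    )
  )
}

#' Read / write a lexicon as YAML
#'
#' The on-disk format has four sections: `stems`, `exclusion_phrases`,
#' `collision_words`, `address_suffixes`.
#'
#' @param path file path.
#' @return `read_lexicon` returns a [keyword_lexicon]; `write_lexicon`
#'   invisibly returns `path`.
#' @export
read_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  keyword_lexicon(
    stems = raw$stems,
    exclusion_phrases = as.character(raw$exclusion_phrases),
    collision_words = as.character(raw$collision_words),
    address_suffixes = as.character(raw$address_suffixes)
  )
}

#' @rdname read_lexicon
#' @param lexicon a [keyword_lexicon].
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "keyword_lexicon"))
  yaml::write_yaml(unclass(lexicon), path)
  invisible(path)
}
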