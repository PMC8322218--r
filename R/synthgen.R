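## Synthetic PCR corpus generator.
##
## Emulates the statistical structure the pipeline assumes - class-conditional
## keyword occurrence in narratives, excluded-context confounders (street
## names, proper nouns containing keywords), dialect-varying categorical
## vocabularies, exact-field duplicates and no-interest records - without any
## claim of linguistic realism. Every record is drawn from its own counter-
## derived RNG substream, so output is a pure function of (config, seed).

# canonical categorical levels and their class-conditional distributions
.cat_levels <- list(
  incident_location = c("Farm", "Home", "Street", "Industrial", "Recreation"),
  mechanism_of_injury = c("Fall", "Struck by animal", "Machinery",
                          "Motor vehicle", "Cut/pierce", "Overexertion"),
  dispatch_reason = c("Injury", "Medical", "Fall",
                      "Transfer", "Lifting", "Intercept"),
  primary_impression = c("Traumatic injury", "Cardiac", "Respiratory",
                         "Behavioral", "Obstetric"),
  destination_type = c("Hospital", "Trauma center", "Clinic", "Nursing home")
)

# P(level | case) and P(level | non-case); last entry = P(missing)
.cat_probs <- list(
  incident_location = list(
    case = c(0.55, 0.20, 0.05, 0.05, 0.05, 0.10),
    noncase = c(0.02, 0.45, 0.25, 0.08, 0.10, 0.10)
  ),
  mechanism_of_injury = list(
    case = c(0.25, 0.25, 0.25, 0.05, 0.10, 0.05, 0.05),
    noncase = c(0.20, 0.01, 0.02, 0.25, 0.07, 0.15, 0.30)
  ),
  dispatch_reason = list( # transfer/lifting/intercept planted separately
    case = c(0.60, 0.10, 0.25, 0, 0, 0, 0.05),
    noncase = c(0.20, 0.50, 0.20, 0, 0, 0, 0.10)
  ),
  primary_impression = list(
    case = c(0.80, 0.05, 0.05, 0.02, 0.01, 0.07),
    noncase = c(0.25, 0.25, 0.20, 0.10, 0.05, 0.15)
  ),
  destination_type = list( # nursing home planted separately
    case = c(0.80, 0.15, 0.02, 0, 0.03),
    noncase = c(0.70, 0.05, 0.15, 0, 0.10)
  )
)

#' Default state dialect definitions
#'
#' Two dialects (ME, NH). ME uses the canonical labels verbatim; NH replaces
#' them with state-specific synonyms (e.g. canonical `"Farm"` appears as
#' `"FARM/RANCH"`), exercising the transformation maps. The no-interest
#' dispatch/destination labels differ only in case across dialects, so record
#' cleaning recognizes them before any harmonization.
#'
#' @return named list of dialects, each with `state`, `years`, and `vocab`
#'   (per-variable named character vectors canonical -> raw label).
#' @export
default_dialects <- function() {
  identity_vocab <- lapply(.cat_levels, function(lv) stats::setNames(lv, lv))
  nh_vocab <- list(
    incident_location = c(
      Farm = "FARM/RANCH", Home = "RESIDENCE", Street = "STREET/HIGHWAY",
      Industrial = "INDUSTRIAL SITE", Recreation = "REC AREA"
    ),
    mechanism_of_injury = c(
      "Fall" = "FALL/SLIP", "Struck by animal" = "ANIMAL STRIKE",
      "Machinery" = "MACHINERY/EQUIPMENT", "Motor vehicle" = "MVC",
      "Cut/pierce" = "CUT OR PIERCE", "Overexertion" = "OVEREXERTION INJ"
    ),
    dispatch_reason = c(
      Injury = "TRAUMATIC INJURY", Medical = "MEDICAL EMERGENCY",
      Fall = "FALL VICTIM",
      Transfer = "TRANSFER", Lifting = "LIFTING", Intercept = "INTERCEPT"
    ),
    primary_impression = c(
      "Traumatic injury" = "TRAUMA", Cardiac = "CARDIAC EVENT",
      Respiratory = "RESP DISTRESS", Behavioral = "BEHAVIORAL EMERGENCY",
      Obstetric = "OB/GYN"
    ),
    destination_type = c(
      Hospital = "ED", "Trauma center" = "TRAUMA CTR", Clinic = "URGENT CARE",
      "Nursing home" = "NURSING HOME"
    )
  )
  list(
    ME = list(state = "ME", years = c(2011L, 2016L), vocab = identity_vocab),
    NH = list(state = "NH", years = c(2011L, 2015L), vocab = nh_vocab)
  )
}

# natural surface forms for stems whose own string would not stem back to
# itself (or just read badly); everything else is emitted as the stem
.stem_surfaces <- c(
  hors = "horse", hoov = "hooves", silag = "silage", pastur = "pasture",
  dairi = "dairy", buggi = "buggy", poultri = "poultry", forestri = "forestry",
  anim = "animal", agricultur = "agriculture", fenc = "fencing",
  irrig = "irrigation", fertil = "fertilizer", manur = "manure",
  greenhous = "greenhouse", calv = "calving", combin = "combine",
  coveral = "coveralls", bulldoz = "bulldozer", plowshar = "plowshare",
  entangl = "entangled", methan = "methane", sanit = "sanitizer",
  pesticid = "pesticide", sheav = "sheave", guywir = "guywire",
  cabl = "cable", defac = "deface", yearl = "yearling", pipelin = "pipeline"
)

#' Surface word(s) realizing a lexicon stem
#'
#' Returns text that the narrative scanner will map back to `stem`
#' (multi-word stems become space-separated phrases).
#'
#' @param stem a lexicon stem string.
#' @return character scalar.
#' @export
stem_surface <- function(stem) {
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  out <- vapply(parts, function(p) {
    s <- .stem_surfaces[p]
    if (is.na(s)) p else unname(s)
  }, character(1))
  paste(out, collapse = " ")
}

# EMS-style filler vocabulary; none of these tokens stems to a prefix of any
# lexicon stem (asserted in the test suite)
.filler_tokens <- c(
  "pt", "patient", "male", "female", "elderly", "adult", "found", "fell",
  "reports", "denies", "complains", "of", "pain", "injury", "to", "left",
  "right", "arm", "leg", "head", "hip", "shoulder", "back", "on", "scene",
  "at", "residence", "alert", "oriented", "vitals", "stable", "transported",
  "without", "incident", "assisted", "onto", "stretcher", "secured", "en",
  "route", "no", "loss", "consciousness", "bleeding", "controlled", "ice",
  "applied", "refused", "transport", "per", "protocol"
)

# confounder phrase pool: proper nouns / businesses containing keywords,
# matching entries in the fixture exclusion list
.confounder_phrases <- c("farmington", "state farm", "woodstock", "penacook", "ramada")
# keywords commonly seen in street names
.confounder_street_stems <- c("barn", "farm", "hay")
.confounder_suffixes <- c("rd", "st", "ln", "ave")

#' Configuration of a synthetic PCR corpus
#'
#' @param n_records records to emit before duplication.
#' @param prevalence fraction of true cases (case class 1-3), strictly in
#'   (0,1).
#' @param keyword_enrichment per-keyword odds multiplier for case narratives
#'   (>= 1); the non-case per-slot keyword probability is 0.05 and case
#'   narratives get three slots at enrichment-multiplied odds.
#' @param confounder_rate fraction of non-case narratives receiving a keyword
#'   only inside an excluded context (address suffix or proper noun).
#' @param duplicate_rate fraction of records duplicated verbatim on the four
#'   identifier fields.
#' @param no_interest_rate fraction of non-case records given a no-interest
#'   dispatch reason or destination type.
#' @param class_mix distribution over case classes 1/2/3 among positives.
#' @param dialects dialect list as from [default_dialects()].
#' @param seed master RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_records = 1000L, prevalence = 0.05,
                         keyword_enrichment = 8, confounder_rate = 0.05,
                         duplicate_rate = 0.02, no_interest_rate = 0.05,
                         class_mix = c(0.4, 0.3, 0.3),
                         dialects = default_dialects(), seed = 1L) {
  if (!.scalar(n_records, function(x) x >= 1)) .stopf("n_records must be a positive integer")
  if (!.scalar(prevalence, function(x) x > 0 && x < 1)) {
    .stopf("prevalence must lie strictly in (0, 1)")
  }
  for (nm in c("confounder_rate", "duplicate_rate", "no_interest_rate")) {
    v <- get(nm)
    if (!.scalar(v, function(x) x >= 0 && x <= 1)) .stopf("%s must lie in [0, 1]", nm)
  }
  if (!.scalar(keyword_enrichment, function(x) x >= 1)) {
    .stopf("keyword_enrichment must be >= 1")
  }
  if (length(class_mix) != 3L || any(class_mix < 0) || sum(class_mix) <= 0) {
    .stopf("class_mix must be three non-negative weights")
  }
  if (!length(dialects)) .stopf("at least one dialect is required")
  structure(
    list(
      n_records = as.integer(n_records), prevalence = prevalence,
      keyword_enrichment = keyword_enrichment,
      confounder_rate = confounder_rate, duplicate_rate = duplicate_rate,
      no_interest_rate = no_interest_rate,
      class_mix = class_mix / sum(class_mix),
      dialects = dialects, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

.sample_level <- function(var, is_case) {
  lv <- c(.cat_levels[[var]], NA_character_)
  p <- .cat_probs[[var]][[if (is_case) "case" else "noncase"]]
  sample(lv, 1L, prob = p)
}

.render_label <- function(canonical, var, vocab) {
  if (is.na(canonical)) {
    return(NA_character_)
  }
  raw <- vocab[[var]][canonical]
  if (is.na(raw)) canonical else unname(raw)
}

#' Generate a synthetic PCR corpus with ground truth
#'
#' Emits exactly `config$n_records` records (plus exact-field duplicates) with
#' the configured prevalence of case classes 1-3, keyword-enriched case
#' narratives, excluded-context confounders in a share of non-case narratives,
#' dialect-specific categorical labels, and a ground-truth sidecar.
#'
#' @param config a [synth_config()].
#' @param lexicon a [keyword_lexicon]; keywords are planted from its stems.
#' @return list with `records` (PCR data frame, see [pcr_columns()]) and
#'   `truth` (data frame: record_id, case_class, planted_keywords and
#'   planted_exclusion_contexts semicolon-joined, no_interest flag,
#'   duplicate_of).
#' @export
generate_corpus <- function(config, lexicon = fixture_lexicon()) {
  if (!inherits(config, "synth_config")) .stopf("config must be a synth_config")
  if (!inherits(lexicon, "keyword_lexicon") || !length(lexicon$stems)) {
    .stopf("a non-empty keyword_lexicon is required")
  }
  n <- config$n_records
  p0 <- 0.05 # per-slot keyword probability in non-case narratives
  odds1 <- (p0 / (1 - p0)) * config$keyword_enrichment
  p1 <- odds1 / (1 + odds1)

  rec <- vector("list", n)
  tru <- vector("list", n)
  dialect_names <- names(config$dialects)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    dia <- config$dialects[[sample(dialect_names, 1L)]]
    is_case <- stats::runif(1) < config$prevalence
    case_class <- if (is_case) sample(1:3, 1L, prob = config$class_mix) else 0L

    # identifiers
    gender <- sample(c("Male", "Female", "Unknown"), 1L,
                     prob = if (is_case) c(0.70, 0.28, 0.02) else c(0.45, 0.53, 0.02))
    dob <- format(as.Date("1935-01-01") + sample.int(25000L, 1L), "%Y-%m-%d")
    zip <- sprintf("%05d", 3900L + sample.int(600L, 1L))
    yr <- sample(seq(dia$years[1], dia$years[2]), 1L)
    admit <- format(as.Date(sprintf("%d-01-01", yr)) + sample.int(365L, 1L) - 1L,
                    "%Y-%m-%d")

    # categorical fields (canonical draws; rendered through the dialect vocab)
    canon <- stats::setNames(
      vapply(names(.cat_levels), .sample_level, character(1), is_case = is_case),
      names(.cat_levels)
    )
    no_interest <- FALSE
    if (!is_case && stats::runif(1) < config$no_interest_rate) {
      no_interest <- TRUE
      if (stats::runif(1) < 0.75) {
        canon["dispatch_reason"] <- sample(c("Transfer", "Lifting", "Intercept"), 1L)
      } else {
        canon["destination_type"] <- "Nursing home"
      }
    }
    raw <- vapply(names(.cat_levels), function(v) {
      .render_label(canon[[v]], v, dia$vocab)
    }, character(1))

    # narrative: filler tokens plus inserted keyword / confounder units
    n_fill <- sample(5:30, 1L)
    fill <- sample(.filler_tokens, n_fill, replace = TRUE)
    planted <- character(0)
    if (is_case) {
      hits <- stats::runif(3) < p1
      if (any(hits)) planted <- unique(sample(lexicon$stems, sum(hits), replace = TRUE))
    } else if (stats::runif(1) < p0) {
      planted <- sample(lexicon$stems, 1L)
    }
    contexts <- character(0)
    units <- lapply(planted, stem_surface)
    if (!is_case && stats::runif(1) < config$confounder_rate) {
      if (stats::runif(1) < 0.5) {
        phrase <- paste(stem_surface(sample(.confounder_street_stems, 1L)),
                        sample(.confounder_suffixes, 1L))
      } else {
        phrase <- sample(.confounder_phrases, 1L)
      }
      contexts <- phrase
      units <- c(units, phrase)
    }
    if (length(units)) {
      # each unit occupies its own gap of the filler sequence, so units never
      # interleave and are always separated by at least one filler token
      gaps <- sort(sample.int(n_fill + 1L, length(units), replace = FALSE)) - 1L
      out <- character(0)
      prev <- 0L
      for (u in seq_along(units)) {
        out <- c(out, fill[seq_len(gaps[u] - prev) + prev], units[[u]])
        prev <- gaps[u]
      }
      narrative <- paste(c(out, fill[seq_len(n_fill - prev) + prev]), collapse = " ")
    } else {
      narrative <- paste(fill, collapse = " ")
    }

    rec[[i]] <- data.frame(
      record_id = sprintf("R%06d", i), state = dia$state,
      incident_id = sprintf("I%06d", i), date_of_birth = dob, gender = gender,
      admit_date = admit, zip_code = zip,
      incident_location = raw[["incident_location"]],
      dispatch_reason = raw[["dispatch_reason"]],
      primary_impression = raw[["primary_impression"]],
      mechanism_of_injury = raw[["mechanism_of_injury"]],
      destination_type = raw[["destination_type"]],
      narrative = narrative, case_class = case_class,
      stringsAsFactors = FALSE
    )
    tru[[i]] <- data.frame(
      record_id = sprintf("R%06d", i), case_class = case_class,
      planted_keywords = paste(planted, collapse = ";"),
      planted_exclusion_contexts = paste(contexts, collapse = ";"),
      no_interest = no_interest, duplicate_of = "",
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec)
  truth <- do.call(rbind, tru)

  # exact-field duplicates
  n_dup <- round(config$duplicate_rate * n)
  if (n_dup > 0) {
    set.seed(derive_seed(config$seed, 0L))
    src <- sample.int(n, n_dup)
    dup <- records[src, , drop = FALSE]
    dup$record_id <- sprintf("R%06dD", src)
    dup$incident_id <- sprintf("I%06dD", src)
    dt <- truth[src, , drop = FALSE]
    dt$record_id <- dup$record_id
    dt$duplicate_of <- records$record_id[src]
    records <- rbind(records, dup)
    truth <- rbind(truth, dt)
  }
  rownames(records) <- NULL
  rownames(truth) <- NULL
  list(records = validate_pcr(records), truth = truth)
}

#' Write the ground-truth sidecar CSV
#'
#' @param truth truth data frame from [generate_corpus()].
#' @param path file path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}
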