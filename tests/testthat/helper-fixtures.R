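# Shared fixtures, built in code.

# quick PCR data frame with sensible defaults, overridable per column
mk_records <- function(n, ...) {
  if (n == 0L) {
    return(mk_records(1L, ...)[0L, , drop = FALSE])
  }
  base <- data.frame(
    record_id = sprintf("T%04d", seq_len(n)),
    state = "ME",
    incident_id = sprintf("I%04d", seq_len(n)),
    date_of_birth = format(as.Date("1960-01-01") + seq_len(n), "%Y-%m-%d"),
    gender = "Male",
    admit_date = format(as.Date("2012-01-01") + seq_len(n), "%Y-%m-%d"),
    zip_code = sprintf("%05d", 4000 + seq_len(n)),
    incident_location = "Home",
    dispatch_reason = "Injury",
    primary_impression = "Traumatic injury",
    mechanism_of_injury = "Fall",
    destination_type = "Hospital",
    narrative = "pt found at residence",
    case_class = NA_integer_,
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}

# memoised large shared corpus (prevalence 0.03, enrichment 8, seed 42) and
# its labeled keyword-positive design matrix
.fixture_cache <- new.env(parent = emptyenv())

shared_corpus_10k <- function() {
  if (is.null(.fixture_cache$corpus)) {
    cfg <- synth_config(
      n_records = 10000L, prevalence = 0.03, keyword_enrichment = 8, seed = 42L
    )
    .fixture_cache$corpus <- generate_corpus(cfg, fixture_lexicon())
  }
  .fixture_cache$corpus
}

shared_dm_10k <- function() {
  if (is.null(.fixture_cache$dm)) {
    corp <- shared_corpus_10k()
    lex <- fixture_lexicon()
    cr <- clean(corp$records, seed = 11L)
    kept <- harmonize(cr$kept, default_maps())
    hits <- keyword_matrix(kept, lex)
    stratum <- kept[kept$record_id %in% hits$keyword_positive, , drop = FALSE]
    schema <- build_schema(kept)
    .fixture_cache$dm <- build_design_matrix(stratum, hits, schema)
  }
  .fixture_cache$dm
}

# draw a corpus from a known Bernoulli-NB generative model (design-matrix level)
simulate_bernoulli_nb <- function(n, theta0, theta1, prevalence, seed) {
  set.seed(seed)
  y <- stats::rbinom(n, 1, prevalence)
  J <- length(theta0)
  X <- matrix(0L, n, J, dimnames = list(NULL, sprintf("f%02d", seq_len(J))))
  theta <- rbind(theta0, theta1)
  for (j in seq_len(J)) {
    X[, j] <- stats::rbinom(n, 1, theta[y + 1L, j])
  }
  list(X = X, y = y)
}

# exhaustive joint-probability Bayes oracle for a Bernoulli NB model with few
# features: P(y=1|x) computed by enumerating P(x, y) directly
brute_force_posterior <- function(prior1, theta0, theta1, x) {
  px_y <- function(theta) prod(ifelse(x == 1, theta, 1 - theta))
  j1 <- prior1 * px_y(theta1)
  j0 <- (1 - prior1) * px_y(theta0)
  j1 / (j1 + j0)
}

# Mann-Whitney pairwise AUC oracle with tie correction
mann_whitney_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  u <- 0
  for (a in sp) for (b in sn) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(sp) * length(sn))
}
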