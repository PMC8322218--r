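# Threshold selection, ROC/AUC, repeated-split calibration, cross-scenario.

test_that("select_threshold reproduces the published worked example", {
  # 100 positives; capturing 90 of them requires tagging 3,012 records
  set.seed(1)
  pos_high <- runif(90, 0.20, 0.95)
  pos_low <- runif(10, 0.01, 0.05)
  neg_high <- runif(2922, min(pos_high) + 1e-9, 0.99)
  neg_low <- runif(7000, 0.001, min(pos_high) - 1e-6)
  scores <- c(pos_high, pos_low, neg_high, neg_low)
  labels <- c(rep(1, 100), rep(0, 9922))
  sel <- select_threshold(scores, labels, target = 0.90)
  expect_equal(sel$threshold, min(pos_high))
  expect_equal(sum(scores >= sel$threshold), 3012)
  expect_equal(sel$precision, 90 / 3012)            # = 0.0299
  expect_equal(round(sel$precision, 4), 0.0299)
  expect_equal(sel$sensitivity, 0.90)
})

test_that("perfect separation tags exactly the positives at precision 1", {
  s <- c(rep(0.9, 12), rep(0.1, 88))
  y <- c(rep(1, 12), rep(0, 88))
  sel <- select_threshold(s, y, 0.9)
  expect_equal(sel$threshold, 0.9)
  expect_equal(sel$tagged_fraction, 0.12)
  expect_equal(sel$precision, 1)

  # target 1.0: threshold is the minimum positive score
  s2 <- runif(50)
  y2 <- rbinom(50, 1, 0.3)
  y2[1] <- 1
  expect_equal(select_threshold(s2, y2, 1)$threshold, min(s2[y2 == 1]))
  expect_error(select_threshold(s2, rep(0, 50), 0.9), "positive")
})

test_that("the selected threshold is minimal for the sensitivity guarantee (oracle)", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    scores <- round(runif(n), sample(c(1, 2, 7), 1)) # induce ties sometimes
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1
    target <- sample(c(0.5, 0.8, 0.9, 1), 1)
    sel <- select_threshold(scores, labels, target)
    # guarantee on the selection set
    pos <- scores[labels == 1]
    expect_gte(mean(pos >= sel$threshold), target)
    # brute-force scan: no higher distinct cutoff still meets the target
    higher <- sort(unique(scores[scores > sel$threshold]))
    if (length(higher)) {
      expect_lt(mean(pos >= higher[1]), target)
    }
    # tagged count equals the smallest achievable at any cutoff meeting target
    cuts <- sort(unique(scores))
    feasible <- cuts[vapply(cuts, function(t) mean(pos >= t) >= target, logical(1))]
    expect_equal(sum(scores >= sel$threshold),
                 min(vapply(feasible, function(t) sum(scores >= t), numeric(1))))
  }
})

test_that("tagged count is monotone non-decreasing in the target", {
  set.seed(6)
  scores <- runif(500)
  labels <- rbinom(500, 1, 0.2)
  tagged <- vapply(c(0.5, 0.9, 1.0), function(tg) {
    sum(scores >= select_threshold(scores, labels, tg)$threshold)
  }, numeric(1))
  expect_true(all(diff(tagged) >= 0))
})

test_that("ROC endpoints, monotonicity, tie handling and AUC oracles", {
  # perfect separation
  expect_equal(roc_curve(c(9, 8, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")

  set.seed(14)
  for (i in 1:15) {
    n <- sample(20:60, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    rc <- roc_curve(scores, labels)
    expect_equal(rc$points$fpr[1], 0)
    expect_equal(rc$points$tpr[1], 0)
    expect_equal(rc$points$fpr[nrow(rc$points)], 1)
    expect_equal(rc$points$tpr[nrow(rc$points)], 1)
    expect_true(all(diff(rc$points$tpr) >= 0))
    # exact agreement with the Mann-Whitney pairwise oracle, ties corrected
    expect_equal(rc$auc, mann_whitney_auc(scores, labels), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(roc_curve(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels)$auc,
                 roc_curve(pmin(pmax(scores, 0.01), 0.99), labels)$auc)
  }
})

test_that("AUC of label-independent scores is near 0.5 and matches pROC", {
  set.seed(99)
  n <- 10000
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.3)
  rc <- roc_curve(scores, labels)
  expect_lt(abs(rc$auc - 0.5), 0.02)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rc$auc, ref, tolerance = 1e-12)
})

test_that("calibration is deterministic and honors its defaults", {
  cfg <- calibration_config(seed = 3, n_iterations = 5)
  expect_equal(calibration_config()$target_sensitivity, 0.90)
  expect_equal(calibration_config()$n_iterations, 100L)
  expect_equal(calibration_config()$train_fraction, 0.80)
  dm <- shared_dm_10k()
  a <- calibrate(dm, cfg)
  b <- calibrate(dm, cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$per_iteration), 5)
  expect_true(all(a$per_iteration$threshold > 0 & a$per_iteration$threshold <= 1))
  expect_true(all(a$per_iteration$sensitivity >= 0.90))
  # aggregates match a brute-force recomputation
  expect_equal(a$threshold_mean, mean(a$per_iteration$threshold))
  expect_equal(a$threshold_sd, sd(a$per_iteration$threshold))
  expect_equal(a$auc_sd, sd(a$per_iteration$auc))
})

test_that("calibration with target 1 captures every validation positive", {
  dm <- shared_dm_10k()
  cal <- calibrate(dm, calibration_config(target_sensitivity = 1,
                                          n_iterations = 3, seed = 8))
  expect_true(all(cal$per_iteration$sensitivity == 1))
})

test_that("on a separable corpus precision beats prevalence and workload shrinks", {
  dm <- shared_dm_10k()
  corp <- shared_corpus_10k()
  prevalence <- mean(corp$truth$case_class %in% 1:3)
  cal <- calibrate(dm, calibration_config(seed = 4, n_iterations = 10))
  expect_gt(cal$precision_mean, prevalence)
  expect_lt(cal$tagged_fraction_mean, 1)
  expect_gt(cal$auc_mean, 0.8)
})

test_that("cross-scenario evaluation: schema guard, perfect case, dialect transfer", {
  # identical train/test with perfect separation: required FPR is 0
  X <- cbind(sig = rep(c(1L, 0L), each = 25), noise = rbinom(50, 1, 0.5))
  rownames(X) <- sprintf("r%02d", 1:50)
  dm <- structure(list(row_ids = rownames(X), X = X,
                       label = rep(c(1L, 0L), each = 25),
                       schema = structure(list(variables = list()),
                                          class = "feature_schema")),
                  class = "design_matrix")
  res <- cross_scenario_eval(dm, dm, target = 0.9)
  expect_equal(res$auc, 1.0)
  expect_equal(res$required_fpr, 0)

  dm2 <- dm
  colnames(dm2$X) <- c("sig", "other")
  expect_error(cross_scenario_eval(dm, dm2), "schema")
})

test_that("harmonization improves cross-dialect transfer (paired simulation)", {
  lex <- fixture_lexicon()
  dial <- default_dialects()
  mk_dm <- function(state, seed, maps) {
    cfg <- synth_config(n_records = 1500, prevalence = 0.15, seed = seed,
                        dialects = dial[state], duplicate_rate = 0,
                        no_interest_rate = 0)
    corp <- generate_corpus(cfg, lex)
    kept <- corp$records
    if (!is.null(maps)) kept <- harmonize(kept, maps)
    hits <- keyword_matrix(kept, lex)
    stratum <- kept[kept$record_id %in% hits$keyword_positive, , drop = FALSE]
    list(stratum = stratum, hits = hits)
  }
  maps <- default_maps()
  me_h <- mk_dm("ME", 51, maps)
  nh_h <- mk_dm("NH", 52, maps)
  nh_r <- mk_dm("NH", 52, NULL) # same corpus, unharmonized
  schema <- build_schema(me_h$stratum)
  dm_me <- build_design_matrix(me_h$stratum, me_h$hits, schema)
  dm_nh_h <- build_design_matrix(nh_h$stratum, nh_h$hits, schema)
  dm_nh_r <- build_design_matrix(nh_r$stratum, nh_r$hits, schema)

  harmonized <- cross_scenario_eval(dm_me, dm_nh_h)
  raw <- cross_scenario_eval(dm_me, dm_nh_r)
  expect_gt(harmonized$auc, raw$auc)

  # with a shared generative model, cross-dialect AUC sits near within-state AUC
  me_b <- mk_dm("ME", 53, maps)
  dm_me_b <- build_design_matrix(me_b$stratum, me_b$hits, schema)
  within <- cross_scenario_eval(dm_me, dm_me_b)
  expect_lt(abs(within$auc - harmonized$auc), 0.1)
})
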