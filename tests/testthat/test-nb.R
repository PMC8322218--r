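# Bernoulli Naive Bayes: estimator arithmetic, posterior correctness against
# exhaustive enumeration, importance statistic, reference-library agreement.

test_that("theta-hat and priors follow the smoothed estimator exactly", {
  X <- matrix(0L, 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c(1L, 0L), each = 10)
  X[1:8, 1] <- 1L # f1 present in 8 of 10 positives
  X[11:13, 2] <- 1L
  fit <- nb_fit(X, y, alpha = 1)
  expect_equal(exp(fit$log_theta["f1", "1"]), 9 / 12)
  expect_equal(exp(fit$log_theta["f1", "0"]), 1 / 12)
  expect_equal(exp(fit$log_theta["f2", "0"]), 4 / 12)
  # balanced labels: both log-priors are log(0.5)
  expect_equal(unname(fit$log_prior), rep(log(0.5), 2))
  # model invariants
  expect_equal(exp(fit$log_prior[["0"]]) + exp(fit$log_prior[["1"]]), 1,
               tolerance = 1e-12)
  expect_true(all(abs(exp(fit$log_theta) + exp(fit$log_one_minus_theta) - 1) < 1e-12))
  expect_true(all(exp(fit$log_theta) > 0 & exp(fit$log_theta) < 1))

  expect_error(nb_fit(X, rep(1L, 20)), "both classes")
  expect_error(nb_fit(X, y, alpha = 0), "alpha")
})

test_that("posterior equals the exhaustive joint-probability Bayes oracle", {
  # symmetric model: posterior is 0.5 for any x
  Xs <- matrix(c(0L, 1L, 1L, 0L), 2, 2, dimnames = list(NULL, c("a", "b")))
  fit <- nb_fit(rbind(Xs, Xs), c(0L, 0L, 1L, 1L), alpha = 1)
  # by construction theta_{j,0} = theta_{j,1} and priors are equal
  expect_equal(nb_posterior(fit, c(a = 1L, b = 1L)), 0.5, tolerance = 1e-12)

  # random small models, every feature vector enumerated
  set.seed(31)
  for (rep in 1:5) {
    J <- sample(2:6, 1)
    n <- 40
    X <- matrix(rbinom(n * J, 1, runif(1, 0.2, 0.7)), n, J,
                dimnames = list(NULL, paste0("v", seq_len(J))))
    y <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    fit <- nb_fit(X, y, alpha = runif(1, 0.5, 2))
    theta0 <- exp(fit$log_theta[, "0"])
    theta1 <- exp(fit$log_theta[, "1"])
    prior1 <- exp(fit$log_prior[["1"]])
    grid <- as.matrix(expand.grid(rep(list(0:1), J)))
    colnames(grid) <- colnames(X)
    want <- apply(grid, 1, function(x) brute_force_posterior(prior1, theta0, theta1, x))
    got <- nb_posterior(fit, grid)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("posterior is monotone in flipping on any positively weighted feature", {
  set.seed(5)
  n <- 200
  J <- 10
  X <- matrix(rbinom(n * J, 1, 0.3), n, J, dimnames = list(NULL, paste0("v", 1:J)))
  y <- rbinom(n, 1, 0.4)
  y[1:2] <- 0:1
  fit <- nb_fit(X, y)
  grid <- as.matrix(expand.grid(rep(list(0:1), J)))
  colnames(grid) <- colnames(X)
  post <- nb_posterior(fit, grid)
  up <- which(fit$log_theta[, "1"] > fit$log_theta[, "0"])
  for (j in up) {
    zero <- grid[, j] == 0
    flipped <- grid[zero, , drop = FALSE]
    flipped[, j] <- 1L
    idx <- match(apply(flipped, 1, paste, collapse = ""),
                 apply(grid, 1, paste, collapse = ""))
    expect_true(all(post[idx] >= post[zero]))
  }
})

test_that("permuting feature columns never changes the posterior", {
  set.seed(9)
  X <- matrix(rbinom(300, 1, 0.4), 50, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- c(0L, 1L, rbinom(48, 1, 0.5))
  fit <- nb_fit(X, y)
  perm <- sample(6)
  fitp <- nb_fit(X[, perm], y)
  x <- rbinom(6, 1, 0.5)
  names(x) <- colnames(X)
  expect_equal(nb_posterior(fit, x), nb_posterior(fitp, x[perm]), tolerance = 1e-14)
})

test_that("parameters are recovered from a known generative model (n = 50,000)", {
  theta0 <- c(0.02, 0.10, 0.30, 0.50, 0.05, 0.15)
  theta1 <- c(0.40, 0.12, 0.30, 0.20, 0.60, 0.45)
  sim <- simulate_bernoulli_nb(50000, theta0, theta1, prevalence = 0.3, seed = 77)
  fit <- nb_fit(sim$X, sim$y)
  expect_lt(max(abs(exp(fit$log_theta[, "0"]) - theta0)), 0.01)
  expect_lt(max(abs(exp(fit$log_theta[, "1"]) - theta1)), 0.01)
  expect_lt(abs(exp(fit$log_prior[["1"]]) - 0.3), 0.01)
})

test_that("posteriors agree with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  n <- 120
  J <- 7
  X <- matrix(rbinom(n * J, 1, 0.35), n, J, dimnames = list(NULL, paste0("v", 1:J)))
  y <- c(0L, 1L, rbinom(n - 2, 1, 0.45))
  fit <- nb_fit(X, y, alpha = 1)
  df <- as.data.frame(lapply(as.data.frame(X), factor, levels = 0:1))
  ref <- e1071::naiveBayes(df, factor(y, levels = 0:1), laplace = 1)
  newx <- as.matrix(expand.grid(rep(list(0:1), J)))[sample(2^J, 40), ]
  colnames(newx) <- colnames(X)
  newdf <- as.data.frame(lapply(as.data.frame(newx), factor, levels = 0:1))
  want <- unname(stats::predict(ref, newdf, type = "raw")[, "1"])
  expect_equal(nb_posterior(fit, newx), want, tolerance = 1e-8)
})

test_that("importance is the smoothed log-probability difference with Table-style counts", {
  # synthetic contingency: a=8, b=1, c=524, d=31303 (N1=532, N0=31304)
  y <- c(rep(1L, 532), rep(0L, 31304))
  x <- c(rep(1L, 8), rep(0L, 524), rep(1L, 1), rep(0L, 31303))
  X <- cbind(kw = x, other = 0L)
  fit <- nb_fit(X, y, alpha = 1)
  imp <- nb_importance(fit)
  row <- imp[imp$feature == "kw", ]
  expect_equal(row$log_prob_difference, log(9 / 534) - log(2 / 31306),
               tolerance = 1e-12)
  expect_equal(unlist(row[c("a", "b", "c", "d")]),
               c(a = 8L, b = 1L, c = 524L, d = 31303L))
  # a + c = N1, b + d = N0
  expect_equal(row$a + row$c, 532L)
  expect_equal(row$b + row$d, 31304L)

  # identical prevalence in both classes with equal class sizes -> 0
  y2 <- rep(0:1, each = 50)
  x2 <- rep(c(0L, 1L), 50)
  fit2 <- nb_fit(cbind(f = x2, g = 1L - x2), y2)
  expect_equal(nb_importance(fit2)$log_prob_difference, c(0, 0), tolerance = 1e-12)

  # a feature exclusive to positives outranks one equally common in both
  y3 <- rep(0:1, each = 40)
  a3 <- c(rep(0L, 40), rep(1L, 10), rep(0L, 30))
  b3 <- rep(c(1L, 0L, 0L, 0L), 20)
  fit3 <- nb_fit(cbind(onlypos = a3, both = b3), y3)
  imp3 <- nb_importance(fit3)
  expect_identical(imp3$feature[1], "onlypos")
})

test_that("importance sign matches the posterior's response to flipping the feature", {
  set.seed(4)
  X <- matrix(rbinom(400, 1, 0.4), 80, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- c(0L, 1L, rbinom(78, 1, 0.5))
  fit <- nb_fit(X, y)
  imp <- nb_importance(fit)
  x0 <- setNames(rep(0L, 5), colnames(X))
  for (j in colnames(X)) {
    x1 <- x0
    x1[j] <- 1L
    delta <- nb_posterior(fit, x1) - nb_posterior(fit, x0)
    d <- imp$log_prob_difference[imp$feature == j]
    expect_equal(sign(delta), sign(d))
  }
})

test_that("model JSON serialization round-trips", {
  set.seed(2)
  X <- matrix(rbinom(200, 1, 0.3), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- c(0L, 1L, rbinom(38, 1, 0.5))
  fit <- nb_fit(X, y, alpha = 0.7)
  tf <- tempfile(fileext = ".json")
  write_nb_model(fit, tf)
  back <- read_nb_model(tf)
  expect_identical(back$feature_names, fit$feature_names)
  expect_equal(back$class_counts, fit$class_counts)
  xs <- matrix(rbinom(50, 1, 0.5), 10, 5, dimnames = list(NULL, colnames(X)))
  expect_equal(nb_posterior(back, xs), nb_posterior(fit, xs), tolerance = 1e-12)
})
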