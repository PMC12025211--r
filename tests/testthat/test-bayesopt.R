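test_that("encode/decode handles log, linear and integer axes", {
  sp <- default_design_space("detection")
  d <- midrange_design()
  x <- encode_design(d, sp)
  expect_true(all(x >= 0 & x <= 1))
  # geometric midpoint of a log axis maps to 0.5
  expect_equal(x[1], 0.5, tolerance = 1e-12)
  expect_equal(x[2], 0.5, tolerance = 1e-12)
  # bound mapping for the learning rate
  d$initial_learning_rate <- 1e-4
  expect_equal(encode_design(d, sp)[2], 0)
  d$initial_learning_rate <- 1e-2
  expect_equal(encode_design(d, sp)[2], 1)
  # batch-size decode of 0.5 on [10, 32] -> 21
  dec <- decode_design(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), sp)
  expect_equal(dec$batch_size, 21L)
  expect_equal(dec$initial_learning_rate, 1e-3, tolerance = 1e-12)
  # round trip for continuous variables
  set.seed(20)
  for (i in 1:10) {
    pt <- runif(6)
    dd <- decode_design(pt, sp)
    expect_equal(decode_design(encode_design(dd, sp), sp), dd)
  }
  bad <- midrange_design(); bad$momentum <- 0.5
  expect_error(encode_design(bad, sp), "outside bounds")
})

test_that("inverse-F1 objective follows the precision/recall arithmetic", {
  perfect <- rbind(`0` = c(TP = 5, FP = 0, FN = 0, TN = 10),
                   `1` = c(TP = 10, FP = 0, FN = 0, TN = 5))
  rownames(perfect) <- c("0", "1")
  expect_equal(objective_from_counts(perfect, classes = 1), 1)
  half <- rbind(`0` = c(TP = 0, FP = 0, FN = 0, TN = 0),
                `1` = c(TP = 5, FP = 5, FN = 5, TN = 5))
  rownames(half) <- c("0", "1")
  expect_equal(objective_from_counts(half, classes = 1), 2)
  zero <- rbind(`0` = c(TP = 1, FP = 1, FN = 1, TN = 1),
                `1` = c(TP = 0, FP = 2, FN = 3, TN = 1))
  rownames(zero) <- c("0", "1")
  expect_equal(objective_from_counts(zero, classes = 1), 1e6)
  set.seed(21)
  for (i in 1:10) {
    cc <- confusion(random_mask(), random_mask(), 5)
    obj <- objective_from_counts(cc, classes = 1:4)
    expect_gte(obj, 1 - 1e-12)
  }
})

test_that("GP posterior matches a direct kernel-matrix oracle", {
  set.seed(22)
  for (n in c(5, 12, 20)) {
    X <- matrix(runif(n * 2), n, 2)
    y <- (X[, 1] - 0.4)^2 + 0.5 * (X[, 2] - 0.6)^2 + 0.01 * rnorm(n)
    fit <- gp_fit(X, y)
    Xq <- matrix(runif(10 * 2), 10, 2)
    got <- gp_predict(fit, Xq)
    want <- bf_gp_posterior(fit, Xq)
    expect_equal(got$mean, want$mean, tolerance = 1e-6)
    expect_equal(got$sd, want$sd, tolerance = 1e-6)
  }
})

test_that("GP interpolates at the noise floor and reverts to the prior", {
  set.seed(23)
  X <- matrix(runif(8), 8, 1)
  y <- sin(6 * X[, 1])
  fit <- gp_fit(X, y, noise = 1e-8)
  at_obs <- gp_predict(fit, X)
  expect_equal(at_obs$mean, y, tolerance = 1e-5)
  # far from all data the predictive sd approaches the prior signal sd
  far <- gp_predict(fit, matrix(100, 1, 1))
  expect_equal(far$sd, fit$y_sd * sqrt(fit$signal_var), tolerance = 1e-3)
  expect_error(gp_fit(X[1, , drop = FALSE], y[1]), "2 observations")
})

test_that("expected improvement follows the closed form", {
  # degenerate sigma = 0
  expect_equal(expected_improvement(0.7, 0, 1.0), 0.3)
  expect_equal(expected_improvement(1.5, 0, 1.0), 0)
  # mu at the incumbent with unit sd: EI = phi(0)
  expect_equal(expected_improvement(1, 1, 1), dnorm(0), tolerance = 1e-12)
  set.seed(24)
  mu <- rnorm(50); sg <- runif(50); inc <- rnorm(50)
  expect_true(all(expected_improvement(mu, sg, inc) >= 0))
  # EI of the incumbent's own location with zero variance is 0
  expect_equal(expected_improvement(1.3, 0, 1.3), 0)
  expect_error(expected_improvement(0, -1, 0), "nonnegative")
})

test_that("proposals maximise EI against a dense grid oracle", {
  set.seed(25)
  X <- matrix(c(0.05, 0.25, 0.5, 0.75, 0.95), 5, 1)
  y <- (X[, 1] - 0.3)^2
  fit <- gp_fit(X, y, noise = 1e-8)
  sp <- design_space(data.frame(name = "x", kind = "continuous",
                                lower = 0, upper = 1))
  set.seed(1)
  prop <- propose_next(fit, sp, n_candidates = 2048)
  grid <- matrix(seq(0, 1, length.out = 1e4), ncol = 1)
  pr <- gp_predict(fit, grid)
  ei_grid <- expected_improvement(pr$mean, pr$sd, min(fit$y))
  expect_gte(prop$ei, max(ei_grid) - 1e-9)
  expect_true(prop$design$x >= 0 && prop$design$x <= 1)
})

test_that("Bayesian optimisation finds the quadratic minimum", {
  sp <- design_space(data.frame(name = "x", kind = "continuous",
                                lower = 0, upper = 1))
  res <- bo_optimize(function(d) (d$x - 0.3)^2, sp, budget = 30, seed = 1)
  expect_lt(abs(res$best_design$x - 0.3), 0.05)
  expect_equal(nrow(res$history), 30)
  expect_equal(res$best_objective, min(res$history$objective))
  trace <- incumbent_trace(res)
  expect_true(all(diff(trace) <= 0))
  # reproducibility
  res2 <- bo_optimize(function(d) (d$x - 0.3)^2, sp, budget = 30, seed = 1)
  expect_identical(res$history, res2$history)
})

test_that("failed objective evaluations are capped and the loop continues", {
  sp <- design_space(data.frame(name = "x", kind = "continuous",
                                lower = 0, upper = 1))
  f <- function(d) if (d$x > 0.9) stop("boom") else (d$x - 0.3)^2
  res <- NULL
  w <- testthat::capture_warnings(
    res <- bo_optimize(f, sp, budget = 12, n_init = 6, seed = 3,
                       objective_cap = 50))
  expect_true(any(grepl("recording cap", w)))
  expect_equal(nrow(res$history), 12)
  expect_true(all(res$history$objective <= 50))
})

test_that("planted augmentation-ratio optimum is recovered", {
  # synthetic objective with an analytic minimum at d_a* = 0.35
  sp <- design_space(data.frame(
    name = c("d_a", "lr"), kind = c("continuous", "log_continuous"),
    lower = c(0.05, 1e-4), upper = c(1, 1e-2)))
  target <- 0.35
  hits <- 0
  for (s in 1:5) {
    res <- bo_optimize(function(d) 1 + (d$d_a - target)^2 +
                         0.1 * (log10(d$lr) + 3)^2,
                       sp, budget = 30, n_init = 10, seed = s)
    if (abs(res$best_design$d_a - target) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
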