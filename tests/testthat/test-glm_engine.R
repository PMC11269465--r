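test_that("design matrix has (degree + 1) * paths labelled columns", {
  bm2 <- data.frame(path = rep(c("A", "B"), each = 5),
                    bin_index = rep(1:5, 2))
  X <- build_design(bm2, degree = 2, reference_path = "A")
  expect_identical(ncol(X), 6L)
  expect_identical(colnames(X),
                   c("(Intercept)", "t", "t2", "z_B", "t:z_B", "t2:z_B"))
  expect_identical(ncol(build_design(bm2, degree = 3)), 8L)
  bm3 <- data.frame(path = rep(c("A", "B", "C"), each = 5),
                    bin_index = rep(1:5, 3))
  expect_identical(ncol(build_design(bm3, degree = 2)), 9L)
  # reference path rows are all-zero outside the shared columns
  expect_true(all(X[bm2$path == "A", c("z_B", "t:z_B", "t2:z_B")] == 0))
  expect_error(build_design(bm2, reference_path = "Z"), "unknown reference")
  expect_error(build_design(bm2, degree = 0), "degree")
})

test_that("intercept-only NB fit recovers the log mean", {
  f <- fit_glm(rep(5, 10), matrix(1, 10, 1))
  expect_equal(unname(f$coefficients[1]), log(5), tolerance = 1e-8)
})

test_that("IRLS matches the independent glm oracle at fixed theta", {
  skip_if_not_installed("MASS")
  set.seed(101)
  for (i in 1:40) {
    nb <- sample(8:30, 1)
    d <- sample(1:3, 1)
    bm <- data.frame(path = rep(c("A", "B"), each = nb),
                     bin_index = rep(seq_len(nb), 2))
    X <- build_design(bm, degree = d, reference_path = "A")
    off <- rnorm(nrow(X), 0, 0.3)
    slope <- runif(1, -0.1, 0.1)
    mu <- exp(log(20) + slope * bm$bin_index + off)
    th <- runif(1, 2, 50)
    y <- rnbinom(nrow(X), mu = mu, size = th)
    if (all(y == 0)) next
    ours <- fit_glm(y, X, off, theta = th)
    oracle <- suppressWarnings(
      glm(y ~ X - 1 + offset(off), family = MASS::negative.binomial(th),
          control = list(epsilon = 1e-14, maxit = 250)))
    expect_equal(unname(ours$coefficients), unname(coef(oracle)),
                 tolerance = 1e-6)
    expect_equal(ours$deviance, deviance(oracle), tolerance = 1e-8)
  }
})

test_that("aliased columns are dropped with a warning, fit unchanged", {
  set.seed(8)
  X <- cbind(1, 1:10, 2 * (1:10))
  colnames(X) <- c("(Intercept)", "t", "t_dup")
  y <- rpois(10, exp(1 + 0.1 * (1:10)))
  expect_warning(f <- fit_glm(y, X, theta = 10), "aliased")
  f2 <- fit_glm(y, X[, 1:2], theta = 10)
  expect_equal(f$coefficients[1:2], f2$coefficients, tolerance = 1e-10)
  expect_true(is.na(f$coefficients["t_dup"]))
})

test_that("adding a column never increases the residual deviance", {
  set.seed(77)
  for (i in 1:15) {
    n <- 20
    X1 <- cbind(1, rnorm(n))
    X2 <- cbind(X1, rnorm(n))
    y <- rnbinom(n, mu = exp(1 + 0.3 * X1[, 2]), size = 5)
    if (all(y == 0)) next
    f1 <- fit_glm(y, X1, theta = 5)
    f2 <- fit_glm(y, X2, theta = 5)
    expect_lte(f2$deviance, f1$deviance + 1e-8)
  }
})

test_that("NB at huge theta reproduces the Poisson fit", {
  set.seed(12)
  X <- cbind(1, scale(1:15))
  y <- rpois(15, exp(2 + 0.5 * X[, 2]))
  f_nb <- fit_glm(y, X, theta = 1e8)
  f_po <- fit_glm(y, X, family = "poisson")
  expect_equal(f_nb$coefficients, f_po$coefficients, tolerance = 1e-4)
})

test_that("underdispersed data triggers the Poisson fallback flag", {
  set.seed(3)
  X <- matrix(1, 30, 1)
  y <- rpois(30, 20)
  f <- fit_glm(y, X)
  expect_true(f$poisson_fallback)
  expect_identical(f$theta_capped, "upper")
})

test_that("all-zero responses are flagged degenerate, not fitted", {
  f <- fit_glm(rep(0, 12), cbind(1, 1:12))
  expect_true(f$degenerate)
  expect_false(f$converged)
})

test_that("likelihood-ratio p-values follow the stated conventions", {
  mk <- function(ll, rank, n = 26) {
    structure(list(loglik = ll, rank = rank, n = n, y = NULL),
              class = "GLMFit")
  }
  # identical log-likelihoods -> p = 1
  expect_equal(lrt_pvalue(mk(-50, 8), mk(-50, 1)), 1)
  # chi-square reference: Lambda = 11.07, df = 5 -> p ~ 0.0500
  expect_equal(lrt_pvalue(mk(-50 + 11.07 / 2, 6), mk(-50, 1),
                          reference = "chisq"),
               0.05, tolerance = 1e-3)
  # numerically negative statistic clamps to zero -> p = 1
  expect_equal(lrt_pvalue(mk(-50 - 1e-9, 6), mk(-50, 1)), 1)
})

test_that("screening keeps its nominal size on flat NB genes", {
  set.seed(19)
  bm <- data.frame(path = rep(c("A", "B"), each = 13),
                   bin_index = rep(1:13, 2))
  X <- build_design(bm, degree = 3, reference_path = "A")
  n <- nrow(X)
  rej <- 0; total <- 400
  for (i in seq_len(total)) {
    y <- rnbinom(n, mu = exp(runif(1, log(10), log(150))), size = 5)
    full <- suppressWarnings(fit_glm(y, X))
    if (full$degenerate || !full$converged) { total <- total - 1; next }
    null <- if (full$poisson_fallback)
      fit_glm(y, matrix(1, n, 1), family = "poisson")
    else fit_glm(y, matrix(1, n, 1), theta = full$theta)
    if (lrt_pvalue(full, null) <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / total, 0.02)
  expect_lt(rej / total, 0.09)
})

test_that("deviance R-squared identities and guards hold", {
  mk <- function(dev, null) structure(list(deviance = dev,
                                           null_deviance = null),
                                      class = "GLMFit")
  expect_equal(deviance_r2(mk(100, 100)), 0)
  expect_equal(deviance_r2(mk(0, 100)), 1)
  expect_equal(deviance_r2(mk(25, 100)), 0.75)
  expect_equal(deviance_r2(mk(5, 0)), 0)       # constant gene
})

test_that("gaussian identity fits match least squares", {
  set.seed(4)
  X <- cbind(1, rnorm(20))
  y <- 2 + 0.5 * X[, 2] + rnorm(20, 0, 0.3)
  f <- fit_glm(y, X, family = "gaussian")
  expect_equal(unname(f$coefficients), unname(coef(lm(y ~ X[, 2]))),
               tolerance = 1e-8)
})
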