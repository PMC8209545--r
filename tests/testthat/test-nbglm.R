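test_that("the NB fit matches closed forms and reference implementations", {
  # symmetry: identical groups give a zero condition coefficient
  x <- cbind(intercept = 1, g = rep(0:1, each = 4))
  y <- rep(c(5L, 9L, 7L, 11L), 2)
  f <- nb_glm(y, x)
  expect_lt(abs(coef(f)[["g"]]), 1e-8)

  # Poisson limit, two-group saturated model: coefficient = log of mean ratio
  y2 <- c(rep(10L, 6), rep(20L, 6))
  x2 <- cbind(intercept = 1, g = rep(0:1, each = 6))
  f2 <- nb_glm(y2, x2, dispersion = 0)
  expect_equal(unname(coef(f2)), c(log(10), log(2)), tolerance = 1e-8)

  # agreement with glm.nb on an overdispersed draw
  set.seed(22)
  x3 <- cbind(1, rnorm(60))
  y3 <- rnbinom(60, mu = exp(2.5 + 0.6 * x3[, 2]), size = 4)
  f3 <- nb_glm(y3, x3)
  m3 <- MASS::glm.nb(y3 ~ x3[, 2])
  # dispersion estimators differ (Cox-Reid adjusted vs plain MLE), so the
  # coefficients agree closely but not to machine precision
  expect_equal(unname(coef(f3)), unname(coef(m3)), tolerance = 2e-3)
})

test_that("with dispersion pinned to zero the fit equals a Poisson GLM", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(15:40, 1)
    x <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    off <- rnorm(n, 0, 0.2)
    y <- rpois(n, lambda = exp(1.5 + 0.4 * x[, 2] - 0.3 * x[, 3] + off))
    mine <- nb_glm(y, x, offset = off, dispersion = 0)
    ref <- glm(y ~ x[, 2] + x[, 3] + offset(off), family = poisson)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-6)
    # standard errors depend on the exact stopping point of the two IRLS
    # loops (deviance- vs coefficient-based), hence the slightly looser band
    expect_equal(unname(sqrt(diag(vcov(mine)))),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  }
})

test_that("coefficient estimates tighten as the sample count grows", {
  set.seed(55)
  err_for_n <- function(n) {
    errs <- replicate(60, {
      x <- cbind(1, rep(0:1, each = n / 2))
      y <- rnbinom(n, mu = exp(3 + 1 * x[, 2]), size = 1 / 0.05)
      abs(coef(nb_glm(y, x))[[2]] - 1)
    })
    median(errs)
  }
  expect_lt(err_for_n(40), err_for_n(10))
})

test_that("degenerate and edge-case responses are flagged, not mangled", {
  x <- cbind(1, rep(0:1, each = 3))
  f0 <- nb_glm(rep(0L, 6), x)
  expect_true(f0$degenerate)
  expect_false(f0$converged)
  expect_error(wald_test(f0, "x2"), "refused")
  expect_error(nb_glm(c(1.5, 2, 1, 2, 1, 2), x), "non-negative integer")
  expect_error(nb_glm(1:6, x, offset = c(Inf, rep(0, 5))), "finite")
})

test_that("nb_fit methods are mutually consistent", {
  set.seed(77)
  x <- cbind(intercept = 1, g = rep(0:1, each = 10), c2 = rnorm(20))
  off <- rep(c(0, 0.3), 10)
  y <- rnbinom(20, mu = exp(2 + 0.5 * x[, 2] + off), size = 8)
  f <- nb_glm(y, x, offset = off)
  expect_equal(predict(f, type = "response"), fitted(f))
  expect_equal(predict(f, newdata = x, newoffset = off), f$linear.predictors)
  expect_equal(mean(residuals(f, "pearson")^2), 1, tolerance = 0.8)
  expect_identical(dim(simulate(f, nsim = 3, seed = 1)), c(20L, 3L))
  expect_identical(simulate(f, nsim = 2, seed = 4), simulate(f, nsim = 2, seed = 4))
  s <- summary(f)
  expect_equal(s$coefficients[, "Estimate"], coef(f))
  expect_equal(unname(s$coefficients[, "Std. Error"]),
               unname(sqrt(diag(vcov(f)))))
  expect_output(print(f), "dispersion")
})

test_that("the Wald test converts scales and tails correctly", {
  fake <- structure(list(coefficients = c(b = log(2)),
                         vcov = matrix(1, dimnames = list("b", "b")),
                         converged = TRUE, degenerate = FALSE),
                    class = "nb_fit")
  wt <- wald_test(fake, "b")
  expect_equal(wt$log2fc, 1)                         # ln 2 on the link scale
  expect_equal(wt$stat, log(2))
  fake$coefficients <- c(b = 0)
  expect_equal(wald_test(fake, "b")$p, 1)
  fake$coefficients <- c(b = 1.96)
  expect_equal(wald_test(fake, "b")$p, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_error(wald_test(fake, "nope"), "no coefficient")
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)                  # single p unchanged
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (r in 1:25) {
    p <- runif(sample(2:40, 1))
    q <- adjust_bh(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  # missing values propagate and shrink m
  p <- c(0.01, NA, 0.04)
  q <- adjust_bh(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_brute(p[c(1, 3)]))
})
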