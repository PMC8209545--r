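test_that("mean-expression filters apply closed thresholds and compose", {
  m <- matrix(0L, 3, 15, dimnames = list(c("low", "edge", "high"), paste0("s", 1:15)))
  m["low", 1:7] <- 1L       # 7 reads / 15 libraries = 0.467 < 0.5 -> removed
  m["edge", 1:8] <- 1L      # 8 / 15 = 0.533 >= 0.5 -> kept
  m["high", ] <- 25L        # mean exactly 25 -> kept by the moderate filter
  cm <- count_matrix(m, c("mRNA", "mRNA", "mRNA"))

  f <- filter_by_mean(cm, 0.5)
  expect_identical(rownames(f$counts), c("edge", "high"))
  expect_identical(filter_by_mean(cm, 0), cm)                 # threshold 0 = identity
  expect_identical(filter_by_mean(f, 0.5), f)                 # idempotent

  fm <- filter_moderate(cm, 25)
  expect_identical(rownames(fm$counts), "high")
  m2 <- m; m2["high", 1] <- 24L                               # mean 24.93 < 25
  expect_warning(
    out <- filter_moderate(count_matrix(m2, rep("mRNA", 3)), 25),
    "no genes")
  expect_identical(nrow(out$counts), 0L)
  # filters commute
  expect_identical(filter_moderate(filter_by_mean(cm, 0.5), 25),
                   filter_by_mean(filter_moderate(cm, 25), 0.5))
})

test_that("median-of-ratios size factors match hand computation and a brute-force oracle", {
  # sample 2 = 2 x sample 1 -> factors (1/sqrt(2), sqrt(2)) after geomean-1 rescale
  m <- matrix(c(10L, 20L, 50L, 100L, 3L, 6L), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- estimate_size_factors(count_matrix(m, rep("mRNA", 3)))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- matrix(7L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(estimate_size_factors(count_matrix(ident, rep("mRNA", 4)))),
               rep(1, 3), tolerance = 1e-12)

  # oracle: literal formula on random matrices
  set.seed(41)
  for (r in 1:50) {
    mm <- matrix(rpois(8 * 4, lambda = 50) + 1L, 8, 4,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
    sf <- estimate_size_factors(count_matrix(mm, rep("mRNA", 8)))
    ref <- exp(rowMeans(log(mm)))
    raw <- apply(mm / ref, 2, median)
    expect_equal(unname(sf), unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  }

  expect_error(estimate_size_factors(
    count_matrix(matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                 rep("mRNA", 2))), "cannot normalize")

  # scale equivariance: scaling one sample by c scales its factor by c
  # relative to the others (ratios preserved after geomean-1 rescaling)
  set.seed(42)
  base <- matrix(rpois(6 * 5, 40) + 1L, 6, 5,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  scaled <- base; scaled[, 3] <- scaled[, 3] * 4L
  sf0 <- estimate_size_factors(count_matrix(base, rep("mRNA", 6)))
  sf1 <- estimate_size_factors(count_matrix(scaled, rep("mRNA", 6)))
  expect_equal(unname(sf1[3] / sf1[1]), unname(4 * sf0[3] / sf0[1]),
               tolerance = 1e-12)
  expect_equal(unname(sf1[-3] / sf0[-3]),
               rep(unname(sf1[1] / sf0[1]), 4), tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 estimator up to its scaling convention", {
  set.seed(17)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 5), 200, 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  mine <- estimate_size_factors(count_matrix(m, rep("mRNA", 200)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  # DESeq2 interpolates the even-count median on the log scale, we take the
  # raw-scale median of the ratios; the two conventions agree closely but
  # not to machine precision
  expect_equal(unname(mine / ref), rep(unname(mine[1] / ref[1]), 6),
               tolerance = 1e-4)
})

test_that("shifted-log normalization reproduces its defining formula", {
  cm <- tiny_counts()
  norm <- log_normalize(cm, size_factors = c(1, 1, 2, 1), pseudocount = 1)
  expect_equal(norm$values["gB", "s1"], 0)                 # count 0 -> log2(1)
  expect_equal(norm$values["gA", "s2"], log2(21))
  expect_equal(norm$values["gB", "s4"], log2(3))           # count 2 / sf 1 + 1
  m <- cm$counts
  expect_equal(norm$values,
               log2(sweep(m, 2, c(1, 1, 2, 1), `/`) + 1))
  expect_error(log_normalize(cm, pseudocount = 0), "positive")
})

test_that("classical MDS recovers planted configurations and preserves distances", {
  # two samples at distance d -> coordinates +/- d/2
  two <- matrix(c(0, 3, 0, 7), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  mds2 <- classical_mds(two, n_dims = 1)  # samples (0,3) and (0,7): distance 4
  expect_equal(sort(unname(mds2$points[, 1])), c(-2, 2))

  # exact 2-D configuration recovered up to rotation/reflection
  set.seed(9)
  conf <- cbind(runif(8, -3, 3), runif(8, -3, 3))
  basis <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]          # embed in 5-D
  vals <- t(conf %*% t(basis))                            # 5 "genes" x 8 samples
  colnames(vals) <- paste0("s", 1:8)
  fit <- classical_mds(vals, n_dims = 2)
  expect_lt(procrustes_error(conf, fit$points), 1e-8)
  # distance preservation at full rank
  expect_equal(as.matrix(dist(fit$points)), as.matrix(dist(t(vals))),
               ignore_attr = TRUE, tolerance = 1e-8)

  # collinear points: second eigenvalue ~ 0 and rank error is informative
  line <- rbind(x = c(0, 1, 2, 3), y = 0, z = 0)
  colnames(line) <- paste0("s", 1:4)
  fit1 <- classical_mds(line, n_dims = 1)
  expect_lt(fit1$eigenvalues[2] / fit1$eigenvalues[1], 1e-9)
  expect_error(classical_mds(line, n_dims = 2), "attainable rank 1")

  # sign convention: largest-|coordinate| loading is positive
  expect_true(all(apply(fit$points, 2, function(v) v[which.max(abs(v))] > 0)))
})
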