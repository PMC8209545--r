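test_that("the Gaussian co-expression test is the partial-correlation t test", {
  set.seed(61)
  for (r in 1:15) {
    n <- sample(20:60, 1)
    z <- cbind(1, matrix(rnorm(n * 2), n))
    x <- rnorm(n) + z[, 2]
    y <- rnorm(n) + 0.5 * z[, 2] - z[, 3]
    ct <- coexpression_test(y, x, z, family = "gaussian")
    or <- partial_cor_t(x, y, z)
    expect_equal(ct$stat, or$t, tolerance = 1e-10)
    expect_equal(ct$p, or$p, tolerance = 1e-10)
    expect_identical(ct$df, or$df)
  }
})

test_that("input degeneracies are rejected, never absorbed", {
  n <- 30
  z <- cbind(1, rnorm(n))
  y <- rnorm(n)
  expect_error(coexpression_test(y, rep(2, n), z, family = "gaussian"),
               "degenerate")
  expect_error(coexpression_test(y, rnorm(n), cbind(z, z[, 2]),
                                 family = "gaussian"),
               "rank deficient")
  expect_error(coexpression_test(y[-1], rnorm(n), z, family = "gaussian"),
               "sample-aligned")
})

test_that("adjusting for the confounder removes the spurious association", {
  # on the confounded triple: adjusted test ~ nominal, unadjusted fires
  rej_adj <- rej_raw <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    tri <- simulate_confounded_triple(50, seed = 5000 + r)
    adj <- coexpression_test(tri$y, tri$x, cbind(1, tri$z), family = "gaussian")
    raw <- coexpression_test(tri$y, tri$x, matrix(1, 50), family = "gaussian")
    rej_adj <- rej_adj + (adj$p < 0.05)
    rej_raw <- rej_raw + (raw$p < 0.05)
  }
  expect_lt(rej_adj / reps, 0.10)
  expect_gt(rej_raw / reps, 0.5)
})

test_that("the NB co-expression test finds a planted edge with the right sign", {
  sim <- simulate_experiment(sim_config(seed = 44))
  d <- sim$design[sim$design$experiment_set == "hypoxia_set", ]
  class(d) <- c("sample_design", "data.frame")
  smp <- d$sample_id
  cs <- sim$counts[, smp]
  norm <- log_normalize(cs)
  z <- suppressWarnings(confounder_matrix(d))
  edge <- sim$truth$edges[1, ]
  ct <- coexpression_test(cs$counts[edge$target_id, ],
                          norm$values[edge$regulator_id, ], z,
                          offsets = log(norm$size_factors),
                          family = "negative_binomial")
  expect_lt(ct$p, 0.01)
  expect_identical(if (ct$a > 0) "positive" else "negative", edge$sign)
})

test_that("build_network adjusts within regulator-biotype families and filters", {
  sim <- simulate_experiment(sim_config(seed = 52))
  d <- sim$design
  smp <- d$sample_id[d$experiment_set == "hypoxia_set"]
  cs <- filter_by_mean(sim$counts[, smp], 0.5)
  norm <- log_normalize(cs)
  regs <- unique(sim$truth$edges$regulator_id)
  tgts <- unique(sim$truth$edges$target_id)
  decoy_t <- head(setdiff(rownames(cs$counts)[cs$biotypes == "mRNA"], tgts), 10)
  all_edges <- suppressWarnings(
    build_network(cs, norm, d, regs, c(tgts, decoy_t),
                  experiment_set = "hypoxia_set", keep_all = TRUE))
  expect_identical(nrow(all_edges), length(regs) * (length(tgts) + 10L))
  # BH within each biotype family reproduces adjust_bh on that family
  for (bt in unique(all_edges$regulator_biotype)) {
    sel <- all_edges$regulator_biotype == bt
    expect_equal(all_edges$padj[sel], adjust_bh(all_edges$p[sel]))
  }
  sig <- suppressWarnings(
    build_network(cs, norm, d, regs, c(tgts, decoy_t),
                  experiment_set = "hypoxia_set"))
  expect_true(all(sig$padj < 0.05))
  expect_identical(sig$sign, ifelse(sig$a > 0, "positive", "negative"))
  # planted edges dominate the significant list
  key_true <- paste(sim$truth$edges$regulator_id, sim$truth$edges$target_id)
  expect_gt(mean(key_true %in% paste(sig$regulator_id, sig$target_id)), 0.7)

  expect_error(
    build_network(cs, norm, d, "not_a_gene", tgts,
                  experiment_set = "hypoxia_set"),
    "not in normalized")
})

test_that("concordant_edges keeps pairs significant with the same sign in both sets", {
  e1 <- data.frame(regulator_id = c("l1", "l1", "m1"),
                   regulator_biotype = c("lncRNA", "lncRNA", "miRNA"),
                   target_id = c("t1", "t2", "t3"),
                   a = c(1, -1, 2), se_a = 0.1, p = 1e-4, padj = 1e-3,
                   sign = c("positive", "negative", "positive"),
                   stringsAsFactors = FALSE)
  e2 <- e1[c(1, 3), ]
  e2$sign[2] <- "negative"; e2$a[2] <- -2
  out <- concordant_edges(e1, e2)
  expect_identical(out$target_id, "t1")    # t2 absent in set 2, t3 flips sign
  expect_identical(out$a_set2, 1)
})
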