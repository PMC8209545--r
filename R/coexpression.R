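#' Confounder matrix for the co-expression model
#'
#' Builds the Z of the co-expression model `g(E[Y | X, Z]) = a X + B Z`:
#' intercept, condition indicators (reference `std_48h` when present),
#' placenta indicators, and batch indicators only where not aliased with
#' placenta. Aliased batch columns are dropped with a warning; any remaining
#' collinearity is an error.
#'
#' @param design a [sample_design()] restricted to the samples being modelled.
#' @return Numeric matrix with sample ids as rownames, full column rank.
#' @export
confounder_matrix <- function(design) {
  conds <- unique(design$condition)
  ref <- if ("std_48h" %in% conds) "std_48h" else conds[1L]
  x <- cbind(intercept = rep(1, nrow(design)))
  for (cond in setdiff(conds, ref)) {
    x <- cbind(x, as.numeric(design$condition == cond))
    colnames(x)[ncol(x)] <- paste0("condition_", cond)
  }
  placentas <- sort(unique(design$placenta_id))
  for (p in placentas[-1L]) {
    x <- cbind(x, as.numeric(design$placenta_id == p))
    colnames(x)[ncol(x)] <- paste0("placenta_", p)
  }
  dropped <- character()
  for (b in sort(unique(design$batch_id))[-1L]) {
    cand <- cbind(x, as.numeric(design$batch_id == b))
    if (qr(cand)$rank == ncol(cand)) {
      x <- cand
      colnames(x)[ncol(x)] <- paste0("batch_", b)
    } else dropped <- c(dropped, b)
  }
  if (length(dropped)) {
    warning("batch column(s) aliased with placenta, dropped: ",
            paste(dropped, collapse = ", "))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop_validation("confounder matrix is collinear in column(s): ",
                    paste(bad, collapse = ", "))
  }
  rownames(x) <- design$sample_id
  x
}

#' Model-based co-expression test
#'
#' Tests whether two genes are co-expressed beyond what known confounders
#' explain, by fitting `g(E[Y | X, Z]) = a X + B Z` and testing `a = 0`.
#' With the negative binomial family, Y is the target gene's count, g is the
#' log link, offsets carry the log size factors, and the test is the Wald
#' test of `a` from [nb_glm()]. With the Gaussian family (identity link,
#' ordinary least squares) the t test of `a` on `n - rank(Z) - 1` residual
#' degrees of freedom is numerically identical to the test of zero partial
#' correlation between X and Y given Z.
#'
#' @param y response: target gene counts (NB family) or any numeric response
#'   (Gaussian family).
#' @param x regulator covariate: log-transformed normalized expression of the
#'   partner gene, sample-aligned with `y`.
#' @param z confounder matrix including the intercept (see
#'   [confounder_matrix()]).
#' @param offsets log size factors (NB family only; default 0).
#' @param dispersion_prior optional `c(meanlog, sdlog)` log-normal prior on
#'   the NB dispersion, passed to [nb_glm()].
#' @param family `"negative_binomial"` or `"gaussian"`.
#' @return A list of class `coexpression_test`: `a`, `se_a`, `stat`, `p`,
#'   `df` (Gaussian), `family`, `converged`.
#' @export
coexpression_test <- function(y, x, z, offsets = NULL,
                              family = c("negative_binomial", "gaussian"),
                              dispersion_prior = NULL) {
  family <- match.arg(family)
  z <- as.matrix(z)
  n <- length(y)
  if (length(x) != n || nrow(z) != n) {
    stop_validation("y, x and z must be sample-aligned")
  }
  if (stats::sd(x) == 0) stop_validation("regulator expression degenerate (constant x)")
  if (qr(z)$rank < ncol(z)) stop_validation("confounder matrix z is rank deficient")
  xm <- cbind(z, regulator = x)

  if (family == "gaussian") {
    fit <- stats::lm.fit(xm, y)
    if (fit$rank < ncol(xm)) stop_validation("model matrix is rank deficient")
    df <- n - fit$rank
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(chol(crossprod(xm)))
    se <- sqrt(rss / df * xtx_inv[ncol(xm), ncol(xm)])
    a <- fit$coefficients[["regulator"]]
    stat <- a / se
    out <- list(a = a, se_a = se, stat = stat,
                p = 2 * stats::pt(-abs(stat), df), df = df,
                family = family, converged = TRUE)
  } else {
    fit <- nb_glm(y, xm, offset = offsets %||% rep(0, n),
                  dispersion_prior = dispersion_prior)
    if (fit$degenerate || !fit$converged) {
      out <- list(a = NA_real_, se_a = NA_real_, stat = NA_real_, p = NA_real_,
                  df = NA_integer_, family = family, converged = FALSE)
    } else {
      wt <- wald_test(fit, "regulator")
      # `a` reported on the natural-log link scale, as fitted
      out <- list(a = unname(fit$coefficients[["regulator"]]),
                  se_a = wt$se * log(2), stat = wt$stat, p = wt$p,
                  df = fit$df.residual, family = family, converged = TRUE)
    }
  }
  class(out) <- "coexpression_test"
  out
}

#' @rdname coexpression_test
#' @param ... ignored.
#' @export
print.coexpression_test <- function(x, ...) {
  cat(sprintf("coexpression_test (%s): a = %.4g (se %.3g), stat = %.3f, p = %.3g\n",
              x$family, x$a, x$se_a, x$stat, x$p))
  invisible(x)
}

#' Assemble the regulator-to-mRNA co-expression network
#'
#' Tests every (regulator, target) pair within one experiment set with the
#' negative binomial co-expression model — Y the target mRNA's counts, X the
#' regulator's normalized log expression, Z the exposure + placenta (+batch
#' when estimable) confounders — and adjusts p-values by Benjamini-Hochberg
#' within each regulator-biotype family. The target's dispersion is
#' re-estimated under each pair's model.
#'
#' @param counts a [count_matrix()] holding the target genes' counts.
#' @param normalized a `normalized_matrix` holding the regulators' expression
#'   (and the size factors used as offsets).
#' @param design [sample_design()] rows for the samples to use.
#' @param regulators character vector of regulator gene ids (lncRNA/miRNA).
#' @param targets character vector of mRNA target gene ids.
#' @param alpha FDR threshold for reported edges.
#' @param experiment_set optional: restrict to one experiment set.
#' @param keep_all return all tested pairs rather than significant edges only.
#' @param moderate_dispersion moderate the per-pair dispersion with an
#'   empirical log-normal prior estimated from the target genes under the
#'   confounder-only model (default TRUE); see [run_de()] for the rationale.
#' @return Data.frame of edges: `regulator_id`, `regulator_biotype`,
#'   `target_id`, `a`, `se_a`, `p`, `padj`, `sign` — rows with
#'   `padj < alpha` unless `keep_all`.
#' @export
build_network <- function(counts, normalized, design, regulators, targets,
                          alpha = 0.05, experiment_set = NULL, keep_all = FALSE,
                          moderate_dispersion = TRUE) {
  design <- align_design(counts, design)
  if (!is.null(experiment_set)) {
    design <- design[design$experiment_set == experiment_set, , drop = FALSE]
    class(design) <- c("sample_design", "data.frame")
  }
  samples <- design$sample_id
  missing_r <- setdiff(regulators, rownames(normalized$values))
  missing_t <- setdiff(targets, gene_ids(counts))
  if (length(missing_r)) stop_validation("regulator(s) not in normalized matrix: ",
                                         paste(missing_r, collapse = ", "))
  if (length(missing_t)) stop_validation("target(s) not in count matrix: ",
                                         paste(missing_t, collapse = ", "))
  z <- confounder_matrix(design)
  offsets <- log(normalized$size_factors[samples])
  prior <- NULL
  if (moderate_dispersion && length(targets) >= 10L) {
    ymat <- counts$counts[targets, samples, drop = FALSE]
    nonzero <- rowSums(ymat) > 0
    alpha_mle <- vapply(which(nonzero), function(i) {
      f <- tryCatch(nb_glm(ymat[i, ], z, offset = offsets),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) NA_real_ else f$dispersion
    }, numeric(1))
    keep <- which(nonzero)[!is.na(alpha_mle)]
    if (length(keep) >= 10L) {
      prior <- dispersion_prior(ymat[keep, , drop = FALSE], z, offsets,
                                alpha_mle[!is.na(alpha_mle)])
    }
  }

  grid <- expand.grid(target_id = targets, regulator_id = regulators,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  res <- data.frame(grid,
                    regulator_biotype = unname(normalized$biotypes[grid$regulator_id]),
                    a = NA_real_, se_a = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in regulators) {
    xr <- normalized$values[r, samples]
    idx <- which(res$regulator_id == r)
    for (i in idx) {
      ct <- tryCatch(
        coexpression_test(counts$counts[res$target_id[i], samples], xr, z,
                          offsets = offsets, family = "negative_binomial",
                          dispersion_prior = prior),
        error = function(e) NULL)
      if (is.null(ct) || !ct$converged) next
      res$a[i] <- ct$a; res$se_a[i] <- ct$se_a; res$p[i] <- ct$p
    }
  }
  res$padj <- NA_real_
  for (bt in unique(res$regulator_biotype)) {
    sel <- res$regulator_biotype == bt
    res$padj[sel] <- adjust_bh(res$p[sel])
  }
  res$sign <- ifelse(res$a > 0, "positive", "negative")
  res <- res[, c("regulator_id", "regulator_biotype", "target_id",
                 "a", "se_a", "p", "padj", "sign")]
  if (!keep_all) {
    res <- res[!is.na(res$padj) & res$padj < alpha, , drop = FALSE]
  }
  res <- res[order(res$padj, res$regulator_id, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Edges significant with the same sign in both experiment sets
#'
#' Mirrors the concordance logic used for differential expression: an edge
#' enters the final network when it is significant (padj below the threshold
#' used to build each set's edges) with the same sign in both sets.
#'
#' @param edges1,edges2 edge tables from [build_network()] for the two sets.
#' @return The rows of `edges1` (with `a_set2` appended) whose
#'   (regulator, target, sign) also occur in `edges2`.
#' @export
concordant_edges <- function(edges1, edges2) {
  key1 <- paste(edges1$regulator_id, edges1$target_id, edges1$sign)
  key2 <- paste(edges2$regulator_id, edges2$target_id, edges2$sign)
  hit <- key1 %in% key2
  out <- edges1[hit, , drop = FALSE]
  out$a_set2 <- edges2$a[match(key1[hit], key2)]
  rownames(out) <- NULL
  out
}
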