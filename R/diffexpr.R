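#' Build the per-contrast design matrix
#'
#' Encodes the two-factor model used for differential expression: an
#' intercept, a treatment-coded condition column (the second element of
#' `contrast`; the first is the reference, `std_48h` throughout the
#' analysis), placenta indicators (first placenta as reference), and batch
#' indicators only where batch is not aliased with placenta (each placenta is
#' processed in one lab, so batch is usually a coarsening of placenta and is
#' dropped with a warning).
#'
#' @param design a [sample_design()] already restricted to the samples of
#'   interest.
#' @param contrast character vector `c(reference, treatment)` of condition
#'   tokens.
#' @return A list of class `design_matrix`: `x` (numeric matrix with sample
#'   ids as rownames), `contrast_col` (name of the treatment column),
#'   `contrast`.
#' @export
build_design <- function(design, contrast = c("std_48h", "hpx_48h")) {
  if (length(contrast) != 2L) stop_validation("`contrast` must be c(reference, treatment)")
  keep <- design$condition %in% contrast
  design <- design[keep, , drop = FALSE]
  for (cond in contrast) {
    if (!any(design$condition == cond)) {
      stop_validation("contrast condition '", cond, "' has no samples")
    }
  }
  placentas <- sort(unique(design$placenta_id))
  if (length(placentas) < 2L) stop_validation("need >= 2 placentas")
  x <- cbind(intercept = rep(1, nrow(design)))
  x <- cbind(x, as.numeric(design$condition == contrast[2L]))
  colnames(x)[2L] <- paste0("condition_", contrast[2L])
  for (p in placentas[-1L]) {
    x <- cbind(x, as.numeric(design$placenta_id == p))
    colnames(x)[ncol(x)] <- paste0("placenta_", p)
  }
  batches <- sort(unique(design$batch_id))
  dropped <- character()
  for (b in batches[-1L]) {
    cand <- cbind(x, as.numeric(design$batch_id == b))
    if (qr(cand)$rank == ncol(cand)) {
      x <- cand
      colnames(x)[ncol(x)] <- paste0("batch_", b)
    } else {
      dropped <- c(dropped, b)
    }
  }
  if (length(dropped)) {
    warning("batch column(s) aliased with placenta, dropped: ",
            paste(dropped, collapse = ", "))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop_validation("design matrix is collinear in column(s): ",
                    paste(bad, collapse = ", "))
  }
  if (nrow(x) <= ncol(x)) stop_validation("more design columns than samples")
  rownames(x) <- design$sample_id
  structure(list(x = x, contrast_col = colnames(x)[2L], contrast = contrast),
            class = "design_matrix")
}

#' Wald test of a fitted coefficient
#'
#' Tests a single coefficient of an [nb_glm()] fit against zero: the statistic
#' is the estimate over its standard error on the natural-log scale, the
#' p-value the two-sided normal tail probability, and the effect is reported
#' as a log2 fold change with its (log2-scale) standard error.
#'
#' @param fit a converged `nb_fit`.
#' @param column name of the coefficient to test.
#' @return A list with `log2fc`, `se` (of the log2 fold change), `stat`, `p`.
#' @export
wald_test <- function(fit, column) {
  if (fit$degenerate || !fit$converged) {
    stop_validation("Wald test refused: fit did not converge")
  }
  if (!column %in% names(fit$coefficients)) {
    stop_validation("no coefficient named '", column, "'")
  }
  b <- fit$coefficients[[column]]
  se <- sqrt(fit$vcov[column, column])
  stat <- b / se
  list(log2fc = b / log(2), se = se / log(2), stat = stat,
       p = 2 * stats::pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Missing p-values are propagated
#' and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_validation("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-gene negative binomial differential expression
#'
#' Fits [nb_glm()] to every gene with the contrast design of
#' [build_design()] and log size-factor offsets, Wald-tests the condition
#' coefficient, and adjusts p-values by Benjamini-Hochberg jointly across all
#' tested genes of all biotypes. Genes whose fit fails to converge (or that
#' are all zero) are reported with missing p-values and excluded from the
#' adjustment, never dropped.
#'
#' By default the per-gene dispersions are moderated across genes
#' (`moderate_dispersion = TRUE`): after a first pass of per-gene profile
#' MLEs, a common dispersion is estimated by maximising the pooled Cox-Reid
#' adjusted profile likelihood, a log-normal prior is centred on it with a
#' width estimated from the spread of the per-gene estimates in excess of
#' their sampling variability (floored at 0.25 on the log-variance scale),
#' and each gene's dispersion is re-estimated at the maximum a posteriori
#' value. With a handful of residual degrees of freedom per gene the
#' unmoderated MLE occasionally collapses to zero and produces grossly
#' inflated Wald statistics; the moderation removes that failure mode while
#' leaving well-estimated dispersions essentially unchanged. Set
#' `moderate_dispersion = FALSE` for plain per-gene MLEs.
#'
#' @param counts a [count_matrix()], already filtered for minimal expression.
#' @param design a [sample_design()] covering the counts' samples.
#' @param contrast `c(reference, treatment)` condition pair.
#' @param alpha FDR level for direction calls (default 0.05).
#' @param experiment_set optional: restrict to one experiment set (needed for
#'   contrasts like `ctrl_0h` vs `std_48h` whose conditions occur in both
#'   sets).
#' @param size_factors optional per-sample factors; estimated from the
#'   restricted counts when absent.
#' @param moderate_dispersion share dispersion information across genes via
#'   an empirical log-normal prior (default TRUE).
#' @return A data.frame of class `de_result` with columns `gene_id`,
#'   `biotype`, `log2fc`, `se`, `stat`, `p`, `padj`, `direction`
#'   (`up` / `down` / `ns`), `converged`.
#' @export
run_de <- function(counts, design, contrast = c("std_48h", "hpx_48h"),
                   alpha = 0.05, experiment_set = NULL, size_factors = NULL,
                   moderate_dispersion = TRUE) {
  design <- align_design(counts, design)
  keep <- design$condition %in% contrast
  if (!is.null(experiment_set)) keep <- keep & design$experiment_set == experiment_set
  design_sub <- design[keep, , drop = FALSE]
  class(design_sub) <- c("sample_design", "data.frame")
  dm <- build_design(design_sub, contrast)
  counts_sub <- counts[, rownames(dm$x)]
  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(counts_sub)
  } else {
    size_factors <- size_factors[rownames(dm$x)]
  }
  offsets <- log(size_factors)

  genes <- gene_ids(counts_sub)
  res <- data.frame(gene_id = genes,
                    biotype = unname(counts_sub$biotypes[genes]),
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_,
                    direction = "ns", converged = FALSE,
                    stringsAsFactors = FALSE)
  fit_all <- function(prior) {
    lapply(seq_along(genes), function(i) {
      tryCatch(nb_glm(counts_sub$counts[i, ], dm$x, offset = offsets,
                      dispersion_prior = prior),
               error = function(e) NULL)
    })
  }
  fits <- fit_all(NULL)
  ok <- vapply(fits, function(f) !is.null(f) && !f$degenerate && f$converged,
               logical(1))
  if (moderate_dispersion && sum(ok) >= 10L) {
    alpha_mle <- vapply(fits[ok], `[[`, numeric(1), "dispersion")
    prior <- dispersion_prior(counts_sub$counts[ok, , drop = FALSE], dm$x,
                              offsets, alpha_mle)
    fits <- fit_all(prior)
    ok <- vapply(fits, function(f) !is.null(f) && !f$degenerate && f$converged,
                 logical(1))
  }
  for (i in which(ok)) {
    wt <- wald_test(fits[[i]], dm$contrast_col)
    res$log2fc[i] <- wt$log2fc; res$se[i] <- wt$se
    res$stat[i] <- wt$stat; res$p[i] <- wt$p
    res$converged[i] <- TRUE
  }
  n_failed <- sum(!res$converged)
  if (n_failed) message(n_failed, " gene(s) without a converged fit (missing p)")
  res$padj <- adjust_bh(res$p)
  sig <- !is.na(res$padj) & res$padj < alpha
  res$direction[sig & res$log2fc > 0] <- "up"
  res$direction[sig & res$log2fc < 0] <- "down"
  class(res) <- c("de_result", "data.frame")
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  res
}

# Empirical log-normal dispersion prior: centre = common dispersion maximising
# the pooled Cox-Reid adjusted profile likelihood over all genes; width = the
# spread of per-gene MLEs in excess of their sampling variability
# (trigamma(df/2) on the log scale), floored at 0.25 log-variance.
dispersion_prior <- function(ymat, x, offsets, alpha_mle,
                             interval = c(1e-8, 100)) {
  betas <- vector("list", nrow(ymat))
  pooled_nll <- function(log_alpha) {
    a <- exp(log_alpha)
    tot <- 0
    for (i in seq_len(nrow(ymat))) {
      y <- ymat[i, ]
      b0 <- betas[[i]] %||% qr.coef(qr(x), log(y + 0.5) - offsets)
      f <- nb_irls(y, x, offsets, a, b0, tol = 1e-6, max_iter = 50L)
      betas[[i]] <<- f$beta
      tot <- tot + (f$loglik - 0.5 * f$logdet_info)
    }
    -tot
  }
  common <- exp(stats::optimize(pooled_nll, log(interval), tol = 1e-4)$minimum)
  interior <- alpha_mle > 2 * interval[1]
  df <- length(offsets) - ncol(x)
  s2 <- if (sum(interior) >= 3L) {
    stats::mad(log(alpha_mle[interior]) - log(common))^2
  } else 0
  c(log(common), sqrt(max(s2 - trigamma(df / 2), 0.25)))
}

#' @rdname run_de
#' @param x a `de_result`.
#' @param ... ignored.
#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("de_result: %d genes, contrast %s vs %s (reference)\n",
              nrow(x), ct[2L], ct[1L]))
  cat(sprintf("up: %d, down: %d, ns: %d (FDR %g)\n",
              sum(x$direction == "up"), sum(x$direction == "down"),
              sum(x$direction == "ns"), attr(x, "alpha")))
  invisible(x)
}
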