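#' Expression filters
#'
#' `filter_by_mean()` keeps genes whose average count per library is at least
#' `min_mean_per_library` (default 0.5, the detection cutoff used to define
#' the expressed transcriptome). `filter_moderate()` is the same rule at a
#' higher threshold (default 25 reads per library) defining moderately
#' expressed genes, the enrichment universe. Both filters are idempotent,
#' commute, and preserve gene order.
#'
#' @param counts a [count_matrix()].
#' @param min_mean_per_library,min_reads_per_library non-negative threshold on
#'   the per-gene mean count per library (closed boundary: mean >= threshold
#'   is kept).
#' @return A `count_matrix` restricted to the retained genes.
#' @export
filter_by_mean <- function(counts, min_mean_per_library = 0.5) {
  if (min_mean_per_library < 0) stop_validation("threshold must be >= 0")
  keep <- rowMeans(counts$counts) >= min_mean_per_library
  if (!any(keep)) warning("no genes pass the mean-expression filter")
  counts[keep, ]
}

#' @rdname filter_by_mean
#' @export
filter_moderate <- function(counts, min_reads_per_library = 25) {
  filter_by_mean(counts, min_reads_per_library)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making libraries comparable: for each sample
#' the factor is the median, over genes with strictly positive counts in all
#' samples, of the ratio of the sample's count to the gene's geometric mean
#' across samples. Factors are rescaled to geometric mean 1. If no gene is
#' positive everywhere, falls back to total-count ratios with a warning.
#'
#' @param counts a [count_matrix()] (or a bare numeric matrix).
#' @return Named numeric vector of positive size factors, one per sample,
#'   with geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (all(m == 0)) stop_validation("cannot normalize: all counts are zero")
  pos <- rowSums(m == 0) == 0L
  if (any(pos)) {
    logm <- log(m[pos, , drop = FALSE])
    ref <- rowMeans(logm)                       # log geometric mean per gene
    sf <- apply(exp(logm - ref), 2, stats::median)
  } else {
    warning("no gene positive in all samples; using total-count ratios")
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
  }
  sf <- sf / exp(mean(log(sf)))                 # geometric mean exactly 1
  names(sf) <- colnames(m)
  sf
}

#' Shifted-log normalization
#'
#' Transforms counts to `log2(count / size_factor + pseudocount)`. A
#' transparent, monotone stand-in for regularized-log transforms, adequate
#' both for ordination and as the regulator covariate X of the co-expression
#' model.
#'
#' @param counts a [count_matrix()].
#' @param size_factors per-sample positive factors (default: estimated with
#'   [estimate_size_factors()]).
#' @param pseudocount positive shift (default 1).
#' @return An object of class `normalized_matrix`: list with `values`
#'   (numeric matrix, log2 scale), `size_factors`, `pseudocount`, `biotypes`.
#' @export
log_normalize <- function(counts, size_factors = NULL, pseudocount = 1) {
  if (pseudocount <= 0) stop_validation("pseudocount must be positive")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  m <- counts$counts
  if (length(size_factors) != ncol(m) || any(size_factors <= 0)) {
    stop_validation("size_factors must be positive, one per sample")
  }
  vals <- log2(sweep(m, 2, size_factors, `/`) + pseudocount)
  structure(list(values = vals, size_factors = size_factors,
                 pseudocount = pseudocount, biotypes = counts$biotypes),
            class = "normalized_matrix")
}

#' @rdname log_normalize
#' @param x a `normalized_matrix`.
#' @param ... ignored.
#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2, pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Embeds samples in `n_dims` dimensions from the sample-by-sample Euclidean
#' distance matrix of normalized expression: double-center -D^2/2,
#' eigendecompose, scale eigenvectors by the square root of their
#' eigenvalues. The sign of each axis is fixed by making its
#' largest-magnitude coordinate positive, so output is reproducible across
#' platforms.
#'
#' @param normalized a `normalized_matrix` (or a bare samples-in-columns
#'   numeric matrix).
#' @param n_dims number of dimensions to return.
#' @return List with `points` (samples x n_dims coordinate matrix) and
#'   `eigenvalues` (all eigenvalues of the doubly centered matrix,
#'   descending).
#' @export
classical_mds <- function(normalized, n_dims = 2) {
  vals <- if (inherits(normalized, "normalized_matrix")) normalized$values else normalized
  n <- ncol(vals)
  if (n < n_dims + 1) stop_validation("need at least n_dims + 1 samples")
  d <- stats::dist(t(vals))
  # cmdscale warns when the configuration has fewer positive eigenvalues
  # than k; that is expected here since we ask for all of them and check
  # the attainable rank ourselves
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  attainable <- sum(eig > max(eig) * 1e-9)
  if (n_dims > attainable) {
    stop_validation("n_dims = ", n_dims, " exceeds the attainable rank ", attainable)
  }
  pts <- fit$points[, seq_len(n_dims), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("MDS", seq_len(n_dims))
  list(points = pts, eigenvalues = eig)
}
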