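#' Gene-by-sample count matrix with biotype annotation
#'
#' The universal input container of the package: a non-negative integer matrix
#' of read counts (genes in rows, samples in columns) together with a biotype
#' label for every gene. Biotypes use a four-label vocabulary:
#' `"mRNA"`, `"lncRNA"`, `"miRNA"`, `"other"` — finer long-non-coding classes
#' (antisense, sense-intronic, processed transcripts, sense-overlapping) are
#' all collapsed into `"lncRNA"`.
#'
#' @param counts integer matrix, genes x samples, with unique rownames
#'   (gene ids) and unique colnames (sample ids). No missing cells.
#' @param biotypes character vector of biotype labels, one per gene, in row
#'   order (or named by gene id).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `biotypes` (named character vector).
#' @examples
#' m <- matrix(c(1L, 2L, 0L, 0L, 5L, 7L), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' cm <- count_matrix(m, c("mRNA", "lncRNA", "miRNA"))
#' dim(cm)
#' @export
count_matrix <- function(counts, biotypes) {
  if (!is.matrix(counts)) stop_validation("`counts` must be a matrix")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_validation("`counts` must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(gene_ids)) {
    stop_validation("duplicate gene id(s): ",
                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop_validation("duplicate sample id(s): ",
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(counts)) stop_validation("counts contain missing cells")
  if (!is.numeric(counts)) stop_validation("counts must be numeric")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop_format("negative count at gene ", gene_ids[bad[1L]],
                ", sample ", sample_ids[bad[2L]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop_format("non-integer count at gene ", gene_ids[bad[1L]],
                ", sample ", sample_ids[bad[2L]])
  }
  storage.mode(counts) <- "integer"
  if (!is.null(names(biotypes))) biotypes <- biotypes[gene_ids]
  biotypes <- as.character(biotypes)
  if (length(biotypes) != nrow(counts) || anyNA(biotypes)) {
    stop_validation("`biotypes` must give one label per gene")
  }
  bad <- setdiff(unique(biotypes), BIOTYPES)
  if (length(bad)) {
    stop_validation("unknown biotype(s): ", paste(bad, collapse = ", "),
                    " (allowed: ", paste(BIOTYPES, collapse = ", "), ")")
  }
  names(biotypes) <- gene_ids
  structure(list(counts = counts, biotypes = biotypes), class = "count_matrix")
}

#' Biotype vocabulary
#'
#' The four gene biotype labels recognised throughout the package.
#' @format Character vector of length 4.
#' @export
BIOTYPES <- c("mRNA", "lncRNA", "miRNA", "other")

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @rdname count_matrix
#' @param ... ignored.
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(factor(x$biotypes, levels = BIOTYPES))
  cat("biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count matrix by genes and/or samples
#'
#' @param x a `count_matrix`.
#' @param i gene index (logical, integer or character).
#' @param j sample index.
#' @param ... ignored.
#' @return A `count_matrix` restricted to the selected genes/samples.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  structure(list(counts = counts, biotypes = x$biotypes[rownames(counts)]),
            class = "count_matrix")
}

gene_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)
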