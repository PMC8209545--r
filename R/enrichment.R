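#' Over-representation test of a gene set against a term map
#'
#' For every term, builds the 2x2 table (in term / not in term, selected /
#' not selected) over the universe and computes the one-sided
#' over-representation p-value — the hypergeometric upper tail, i.e. the
#' one-sided Fisher exact test — then adjusts across terms with
#' Benjamini-Hochberg and ranks by adjusted p-value ascending.
#'
#' @param selected character vector of selected gene ids; must be a subset of
#'   the map's universe.
#' @param gene_sets a [gene_set_map()].
#' @return Data.frame of class `enrichment_result` with columns `term_id`,
#'   `term_name`, `k` (selected in term), `K` (universe in term), `n`
#'   (selected total), `N` (universe size), `odds_ratio` (sample OR), `p`,
#'   `padj`.
#' @export
enrich <- function(selected, gene_sets) {
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, gene_sets$universe)
  if (length(outside)) {
    stop_validation("selected gene(s) outside the universe: ",
                    paste(outside, collapse = ", "))
  }
  N <- length(gene_sets$universe)
  n <- length(selected)
  terms <- names(gene_sets$sets)
  K <- lengths(gene_sets$sets)
  k <- vapply(gene_sets$sets, function(g) length(intersect(g, selected)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  num <- k * (N - K - n + k)
  den <- (K - k) * (n - k)
  odds_ratio <- ifelse(num == 0 & den == 0, NA_real_,
                       ifelse(den == 0, Inf, num / den))
  res <- data.frame(term_id = terms,
                    term_name = unname(gene_sets$term_names[terms]),
                    k = unname(k), K = unname(K), n = n, N = N,
                    odds_ratio = unname(odds_ratio),
                    p = unname(p), padj = unname(adjust_bh(p)),
                    stringsAsFactors = FALSE)
  res <- res[order(res$padj, res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Restrict a gene set map to a new universe
#'
#' Used to match the enrichment background to the genes actually analysed
#' (e.g. the moderately expressed mRNAs).
#'
#' @param gene_sets a [gene_set_map()].
#' @param universe the new background gene set.
#' @return A [gene_set_map()] over the intersected universe.
#' @export
restrict_universe <- function(gene_sets, universe) {
  gene_set_map(gene_sets$sets, intersect(gene_sets$universe, universe),
               gene_sets$term_names)
}

#' Direct GO enrichment of differentially expressed mRNAs
#'
#' Applies [enrich()] to the differentially expressed genes of one biotype
#' (direction-agnostic by default; optionally only up- or down-regulated
#' genes) against the map's universe — which should be the moderately
#' expressed mRNA background (see [restrict_universe()]).
#'
#' @param de a [run_de()] result computed on moderately expressed genes.
#' @param gene_sets a [gene_set_map()].
#' @param biotype biotype whose DE genes are tested (default `"mRNA"`).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return An `enrichment_result`.
#' @export
direct_go <- function(de, gene_sets, biotype = "mRNA",
                      direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  sel <- de$biotype == biotype & de$direction != "ns"
  if (direction != "both") sel <- sel & de$direction == direction
  genes <- intersect(de$gene_id[sel], gene_sets$universe)
  enrich(genes, gene_sets)
}

#' Indirect GO enrichment via co-expressed mRNAs
#'
#' Attributes biological processes to a set of lncRNA/miRNA regulators that
#' have no GO annotation of their own: collects the mRNAs with at least one
#' significant co-expression edge (`padj < alpha`) to a regulator in the set,
#' ranks them by their best edge's adjusted p-value, truncates to the
#' `top_k` best, and runs [enrich()] on them. With
#' `semantics = "intersection"` an mRNA qualifies only when it has a
#' significant edge to at least one lncRNA *and* one miRNA of the set.
#'
#' @param regulator_set character vector of regulator gene ids.
#' @param edges edge table from [build_network()] (use `keep_all = TRUE` or
#'   the significant edge list).
#' @param gene_sets a [gene_set_map()] over the moderately expressed mRNA
#'   universe.
#' @param top_k cap on the number of top-ranked mRNAs carried into
#'   enrichment.
#' @param alpha edge significance threshold.
#' @param semantics `"union"` (any regulator) or `"intersection"` (both a
#'   lncRNA and a miRNA edge required).
#' @return An `enrichment_result` (zero selected genes give `k = 0`
#'   everywhere and p = 1).
#' @export
indirect_go <- function(regulator_set, edges, gene_sets, top_k = 500,
                        alpha = 0.05, semantics = c("union", "intersection")) {
  semantics <- match.arg(semantics)
  e <- edges[edges$regulator_id %in% regulator_set &
               !is.na(edges$padj) & edges$padj < alpha, , drop = FALSE]
  if (nrow(e) == 0L) {
    message("no significant edges for this regulator set")
    return(enrich(character(), gene_sets))
  }
  if (semantics == "intersection") {
    by_bt <- split(e$target_id, e$regulator_biotype)
    need <- intersect(c("lncRNA", "miRNA"), names(by_bt))
    keep_targets <- Reduce(intersect, by_bt[need])
    e <- e[e$target_id %in% keep_targets, , drop = FALSE]
    if (nrow(e) == 0L) return(enrich(character(), gene_sets))
  }
  best <- tapply(e$padj, e$target_id, min)
  ranked <- names(sort(best))
  top <- utils::head(ranked, top_k)
  enrich(intersect(top, gene_sets$universe), gene_sets)
}
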