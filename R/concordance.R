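#' Fisher exact test for a 2x2 table
#'
#' Two-sided exact test conditioning on the margins: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. The reported odds
#' ratio is the sample odds ratio `(a d) / (b c)` (with `Inf`, `0` or `NA`
#' when cells vanish), not the conditional MLE.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_validation("`table` must be 2x2")
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    stop_validation("table entries must be non-negative integers")
  }
  storage.mode(table) <- "integer"
  p <- if (sum(table) == 0L) 1 else stats::fisher.test(table)$p.value
  num <- as.numeric(table[1, 1]) * table[2, 2]
  den <- as.numeric(table[1, 2]) * table[2, 1]
  odds_ratio <- if (num == 0 && den == 0) NA_real_ else if (den == 0) Inf else num / den
  list(odds_ratio = odds_ratio, p = min(p, 1))
}

#' Cross-experiment concordance of differential expression calls
#'
#' For each biotype, tabulates — among genes called differentially expressed
#' in both experimental sets — the 2x2 table of direction (up/down in set 1
#' by up/down in set 2), tests direction agreement with the Fisher exact
#' test, and extracts the concordantly up- and down-regulated gene sets that
#' feed the network stage. Genes DE in only one set are counted separately
#' (Venn counts).
#'
#' @param de1,de2 [run_de()] results from the two experiment sets; gene ids
#'   are intersected.
#' @param biotypes biotypes to tabulate (default all four).
#' @return A list of class `concordance_result`, one element per biotype,
#'   each with `table` (2x2), `odds_ratio`, `p`, `concordant_up`,
#'   `concordant_down`, `n_de1_only`, `n_de2_only`.
#' @export
concordance_analysis <- function(de1, de2, biotypes = BIOTYPES) {
  shared <- intersect(de1$gene_id, de2$gene_id)
  d1 <- de1[match(shared, de1$gene_id), ]
  d2 <- de2[match(shared, de2$gene_id), ]
  out <- list()
  for (bt in biotypes) {
    in_bt <- d1$biotype == bt
    s1 <- d1$direction[in_bt]; s2 <- d2$direction[in_bt]
    g <- d1$gene_id[in_bt]
    both <- s1 != "ns" & s2 != "ns"
    tab <- matrix(0L, 2, 2, dimnames = list(set1 = c("up", "down"),
                                            set2 = c("up", "down")))
    for (r in c("up", "down")) for (cc in c("up", "down")) {
      tab[r, cc] <- sum(both & s1 == r & s2 == cc)
    }
    ft <- fisher_exact_2x2(tab)
    out[[bt]] <- list(
      biotype = bt, table = tab,
      odds_ratio = ft$odds_ratio, p = ft$p,
      concordant_up = g[both & s1 == "up" & s2 == "up"],
      concordant_down = g[both & s1 == "down" & s2 == "down"],
      n_de1_only = sum(s1 != "ns" & s2 == "ns"),
      n_de2_only = sum(s1 == "ns" & s2 != "ns"))
  }
  class(out) <- "concordance_result"
  out
}

#' @rdname concordance_analysis
#' @param x a `concordance_result`.
#' @param ... ignored.
#' @export
print.concordance_result <- function(x, ...) {
  for (el in x) {
    cat(sprintf("%s: concordant up %d, down %d; discordant %d; Fisher p = %.3g\n",
                el$biotype, length(el$concordant_up), length(el$concordant_down),
                el$table[1, 2] + el$table[2, 1], el$p))
  }
  invisible(x)
}

#' Concordant differentially expressed genes
#'
#' Convenience accessor: genes significant in both sets with the same
#' direction, optionally restricted to some biotypes.
#'
#' @param conc a `concordance_result`.
#' @param biotypes biotypes to pool.
#' @return Character vector of gene ids.
#' @export
concordant_genes <- function(conc, biotypes = BIOTYPES) {
  unlist(lapply(conc[intersect(names(conc), biotypes)], function(el) {
    c(el$concordant_up, el$concordant_down)
  }), use.names = FALSE)
}
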