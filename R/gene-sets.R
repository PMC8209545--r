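#' Gene set map for enrichment analysis
#'
#' A flat term -> gene-set annotation (e.g. GO biological processes) restricted
#' to a background universe. Every annotated gene must belong to the universe;
#' terms that become empty after restriction are dropped.
#'
#' @param sets named list of character vectors (term id -> gene ids).
#' @param universe character vector: the background gene set.
#' @param term_names optional named character vector of free-text term names.
#' @return An object of class `gene_set_map` with elements `sets` (list of
#'   character vectors, all subsets of `universe`), `term_names`, `universe`.
#' @export
gene_set_map <- function(sets, universe, term_names = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop_validation("`sets` must be a named list of gene id vectors")
  }
  if (anyDuplicated(names(sets))) {
    stop_validation("duplicate term id(s): ",
                    paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(g) intersect(unique(as.character(g)), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    message(sum(empty), " term(s) dropped: no genes in universe")
    restricted <- restricted[!empty]
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(restricted), names(restricted))
  } else {
    term_names <- stats::setNames(as.character(term_names[names(restricted)]),
                                  names(restricted))
    term_names[is.na(term_names)] <- names(restricted)[is.na(term_names)]
  }
  structure(list(sets = restricted, term_names = term_names, universe = universe),
            class = "gene_set_map")
}

#' @rdname gene_set_map
#' @param x a `gene_set_map`.
#' @param ... ignored.
#' @export
print.gene_set_map <- function(x, ...) {
  cat(sprintf("gene_set_map: %d terms over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @rdname gene_set_map
#' @export
length.gene_set_map <- function(x) length(x$sets)
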