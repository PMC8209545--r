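#' Read a count matrix and its gene annotation
#'
#' Reads a tab-separated counts file (one gene per row, header row of sample
#' ids, first column of gene ids) and a two-column annotation TSV
#' (`gene_id`, `biotype`). Genes absent from the annotation receive biotype
#' `"other"` with a warning.
#'
#' @param path counts TSV.
#' @param annotation_path gene annotation TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, annotation_path) {
  raw <- read_tsv(path, colClasses = "character")
  if (ncol(raw) < 2L) stop_format("counts file needs a gene id column and >= 1 sample")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop_validation("duplicate gene id(s) in ", path, ": ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- names(raw)[-1L]
  mat <- matrix(NA_real_, nrow(raw), length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop_format("invalid count '", raw[[j + 1L]][bad[1L]], "' at gene ",
                  ids[bad[1L]], ", sample ", samples[j])
    }
    mat[, j] <- v
  }
  ann <- read_tsv(annotation_path, colClasses = "character")
  if (!all(c("gene_id", "biotype") %in% names(ann))) {
    stop_format("annotation file must have columns gene_id, biotype")
  }
  biotypes <- stats::setNames(ann$biotype, ann$gene_id)[ids]
  if (anyNA(biotypes)) {
    warning(sum(is.na(biotypes)), " gene(s) missing from annotation; biotype set to 'other'")
    biotypes[is.na(biotypes)] <- "other"
  }
  names(biotypes) <- ids
  count_matrix(mat, biotypes)
}

#' Write a count matrix and its annotation
#'
#' Inverse of [read_count_matrix()]: writes `counts.tsv`-style and
#' `genes.tsv`-style files that round-trip exactly.
#'
#' @param x a `count_matrix`.
#' @param path counts TSV to write.
#' @param annotation_path annotation TSV to write.
#' @export
write_count_matrix <- function(x, path, annotation_path) {
  df <- data.frame(gene_id = gene_ids(x), x$counts, check.names = FALSE)
  write_tsv(df, path)
  write_tsv(data.frame(gene_id = gene_ids(x), biotype = unname(x$biotypes)),
            annotation_path)
  invisible(x)
}

#' Read a sample design sheet
#'
#' @param path TSV with columns `sample_id`, `experiment_set`, `condition`,
#'   `placenta_id`, `batch_id`.
#' @return A validated [sample_design()] data.frame.
#' @export
read_sample_design <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (nrow(df) == 0L) stop_validation("no samples in ", path)
  sample_design(df)
}

#' @rdname read_sample_design
#' @param design a `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  write_tsv(as.data.frame(design), path)
  invisible(design)
}

#' Read a GMT gene-set file
#'
#' Parses the GMT dialect (`term_id<TAB>term_name<TAB>gene1<TAB>gene2...`),
#' intersects every term with the supplied universe and drops terms left
#' empty (with a message giving the count).
#'
#' @param path GMT file.
#' @param universe character vector of background gene ids.
#' @return A [gene_set_map()].
#' @export
read_gene_sets <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); term_names <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_format("malformed GMT line ", i, ": fewer than 3 fields")
    }
    id <- parts[1L]
    if (id %in% names(sets)) stop_validation("duplicate term id '", id, "' at line ", i)
    sets[[id]] <- parts[-(1:2)]
    term_names[id] <- parts[2L]
  }
  gene_set_map(sets, universe, term_names)
}

#' @rdname read_gene_sets
#' @param gsm a `gene_set_map` to write.
#' @export
write_gene_sets <- function(gsm, path) {
  lines <- vapply(names(gsm$sets), function(id) {
    paste(c(id, gsm$term_names[[id]], gsm$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(gsm)
}

#' Write a co-expression edge table
#'
#' Writes edges as TSV with columns `regulator_id`, `regulator_biotype`,
#' `target_id`, `a`, `se_a`, `p`, `padj`, `sign`, ordered by `padj` ascending
#' then `regulator_id`, `target_id` — a deterministic tabular stand-in for a
#' network (Circos) rendering.
#'
#' @param edges data.frame of co-expression edges (see [build_network()]).
#' @param path output TSV.
#' @export
write_edges <- function(edges, path) {
  cols <- c("regulator_id", "regulator_biotype", "target_id",
            "a", "se_a", "p", "padj", "sign")
  missing_cols <- setdiff(cols, names(edges))
  if (length(missing_cols)) {
    stop_validation("edge table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges <- edges[cols]
  if (nrow(edges)) {
    edges <- edges[order(edges$padj, edges$regulator_id, edges$target_id), , drop = FALSE]
  }
  write_tsv(edges, path)
  invisible(edges)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- read_tsv(path)
  for (col in c("a", "se_a", "p", "padj")) df[[col]] <- as.numeric(df[[col]])
  df
}
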