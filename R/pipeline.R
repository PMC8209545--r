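#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (or load) -> preprocess -> differential expression
#' per experiment set -> cross-set concordance -> co-expression network ->
#' direct and indirect GO enrichment, writing every intermediate table plus a
#' run manifest into `out_dir`. Re-running with the same configuration and
#' seed reproduces byte-identical tables.
#'
#' The configuration (YAML file or equivalent list) must name `contrasts`
#' (per experiment set, `[reference, treatment]`), and either `simulate: true`
#' (with an optional `sim:` block of [sim_config()] overrides) or an
#' `inputs:` block with paths `counts`, `genes`, `design`, `gmt`. Optional
#' blocks: `thresholds` (`min_mean` 0.5, `min_moderate` 25, `alpha` 0.05)
#' and `network` (`max_regulators` 12, `max_targets` 40, `top_k` 500) — the
#' caps keep the pair scan at the scale of the strongest DE regulators and
#' targets.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param out_dir output directory (default: `out` entry of the config).
#' @return The run directory path, invisibly; side effect: tables and
#'   `manifest.json` under `out_dir`. On failure a `FAILED` marker naming
#'   the stage is left behind.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  if (is.null(config[["contrasts"]])) {
    stop_validation("config is missing `contrasts`")
  }
  out_dir <- out_dir %||% config[["out"]] %||% stop_validation("config is missing `out`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config[["thresholds"]] %||% list()
  min_mean <- th$min_mean %||% 0.5
  min_moderate <- th$min_moderate %||% 25
  alpha <- th$alpha %||% 0.05
  nw <- config[["network"]] %||% list()
  max_reg <- nw$max_regulators %||% 12L
  max_tgt <- nw$max_targets %||% 40L
  top_k <- nw$top_k %||% 500L
  seed <- config[["seed"]] %||% 1L

  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name), failed_marker)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("trophonet")),
                   thresholds = list(min_mean = min_mean, min_moderate = min_moderate,
                                     alpha = alpha),
                   stages = list())
  if (!is.null(config_path)) {
    manifest$config_md5 <- unname(tools::md5sum(config_path))
  }

  ## stage 1: inputs ---------------------------------------------------------
  dat <- stage("inputs", {
    if (isTRUE(config[["simulate"]])) {
      cfg <- do.call(sim_config, c(config[["sim"]] %||% list(), list(seed = seed)))
      sim <- simulate_experiment(cfg)
      write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"),
                         file.path(out_dir, "genes.tsv"))
      write_sample_design(sim$design, file.path(out_dir, "design.tsv"))
      write_gene_sets(sim$gene_sets, file.path(out_dir, "go.gmt"))
      jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      sim
    } else {
      inp <- config[["inputs"]] %||% stop_validation("config needs `simulate: true` or `inputs`")
      counts <- read_count_matrix(inp$counts, inp$genes)
      list(counts = counts,
           design = read_sample_design(inp$design),
           gene_sets = read_gene_sets(inp$gmt, gene_ids(counts)),
           truth = NULL)
    }
  })
  counts <- dat$counts; design <- align_design(counts, dat$design)
  sets <- intersect(EXPERIMENT_SETS, unique(design$experiment_set))
  manifest$stages$inputs <- list(n_genes = nrow(counts$counts),
                                 n_samples = ncol(counts$counts))

  ## stage 2: preprocess per set --------------------------------------------
  pp <- stage("preprocess", {
    out <- list()
    for (s in sets) {
      smp <- design$sample_id[design$experiment_set == s]
      cs <- filter_by_mean(counts[, smp], min_mean)
      norm <- log_normalize(cs)
      mds <- classical_mds(norm, n_dims = 2)
      write_tsv(data.frame(gene_id = gene_ids(cs),
                           round(norm$values, 6), check.names = FALSE),
                file.path(out_dir, paste0("normalized_", s, ".tsv")))
      write_tsv(data.frame(sample_id = names(norm$size_factors),
                           size_factor = round(norm$size_factors, 6)),
                file.path(out_dir, paste0("size_factors_", s, ".tsv")))
      write_tsv(data.frame(sample_id = rownames(mds$points),
                           round(mds$points, 6)),
                file.path(out_dir, paste0("mds_", s, ".tsv")))
      out[[s]] <- list(counts = cs, normalized = norm)
    }
    out
  })
  manifest$stages$preprocess <- lapply(pp, function(el) {
    list(n_genes = nrow(el$counts$counts))
  })

  ## stage 3: differential expression per set --------------------------------
  de <- stage("diffexpr", {
    out <- list()
    for (s in sets) {
      ct <- config[["contrasts"]][[s]]
      if (is.null(ct)) stop_validation("no contrast for ", s)
      r <- suppressMessages(
        run_de(pp[[s]]$counts, design, contrast = unlist(ct), alpha = alpha,
               experiment_set = s,
               size_factors = pp[[s]]$normalized$size_factors))
      write_tsv(within(as.data.frame(r), {
        log2fc <- round(log2fc, 6); se <- round(se, 6); stat <- round(stat, 6)
      }), file.path(out_dir, paste0("de_", s, ".tsv")))
      out[[s]] <- r
    }
    out
  })
  manifest$stages$diffexpr <- lapply(de, function(r) {
    list(n_up = sum(r$direction == "up"), n_down = sum(r$direction == "down"))
  })

  ## stage 4: concordance ----------------------------------------------------
  conc <- stage("concordance", {
    cc <- concordance_analysis(de[[sets[1L]]], de[[sets[2L]]])
    rows <- do.call(rbind, lapply(cc, function(el) {
      data.frame(biotype = el$biotype,
                 up_up = el$table[1, 1], up_down = el$table[1, 2],
                 down_up = el$table[2, 1], down_down = el$table[2, 2],
                 odds_ratio = el$odds_ratio, p = el$p,
                 n_set1_only = el$n_de1_only, n_set2_only = el$n_de2_only,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rows, file.path(out_dir, "concordance.tsv"))
    genes <- do.call(rbind, lapply(cc, function(el) {
      if (!length(el$concordant_up) && !length(el$concordant_down)) return(NULL)
      data.frame(gene_id = c(el$concordant_up, el$concordant_down),
                 biotype = el$biotype,
                 direction = rep(c("up", "down"),
                                 c(length(el$concordant_up), length(el$concordant_down))),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(genes)) {
      genes <- data.frame(gene_id = character(), biotype = character(),
                          direction = character())
    }
    write_tsv(genes, file.path(out_dir, "concordant_genes.tsv"))
    cc
  })
  manifest$stages$concordance <- list(n_concordant = length(concordant_genes(conc)))

  ## stage 5: co-expression network -----------------------------------------
  edges <- stage("coexpression", {
    pick <- function(r, biotypes, cap) {
      cand <- r[r$biotype %in% biotypes & r$direction != "ns" & !is.na(r$padj), ]
      cand <- cand[order(cand$padj, cand$gene_id), ]
      utils::head(cand$gene_id, cap)
    }
    # regulators: strongest DE ncRNAs seen in both sets; targets: concordant mRNAs
    regs <- intersect(pick(de[[sets[1L]]], c("lncRNA", "miRNA"), 10 * max_reg),
                      pick(de[[sets[2L]]], c("lncRNA", "miRNA"), 10 * max_reg))
    regs <- utils::head(regs, max_reg)
    tgts <- utils::head(concordant_genes(conc, "mRNA"), max_tgt)
    per_set <- list()
    for (s in sets) {
      e <- build_network(pp[[s]]$counts, pp[[s]]$normalized, design,
                         regulators = intersect(regs, rownames(pp[[s]]$normalized$values)),
                         targets = intersect(tgts, gene_ids(pp[[s]]$counts)),
                         alpha = alpha, experiment_set = s)
      write_edges(e, file.path(out_dir, paste0("edges_", s, ".tsv")))
      per_set[[s]] <- e
    }
    final <- concordant_edges(per_set[[sets[1L]]], per_set[[sets[2L]]])
    write_edges(final, file.path(out_dir, "edges.tsv"))
    list(per_set = per_set, final = final)
  })
  manifest$stages$coexpression <- list(
    n_edges_set1 = nrow(edges$per_set[[sets[1L]]]),
    n_edges_set2 = nrow(edges$per_set[[sets[2L]]]),
    n_edges_concordant = nrow(edges$final))

  ## stage 6: GO enrichment --------------------------------------------------
  go <- stage("go_enrichment", {
    out <- list()
    for (s in sets) {
      moderate <- filter_moderate(pp[[s]]$counts, min_moderate)
      gsm <- suppressMessages(
        restrict_universe(dat$gene_sets,
                          gene_ids(moderate)[moderate$biotypes == "mRNA"]))
      res <- direct_go(de[[s]], gsm)
      write_tsv(round_cols(res, c("odds_ratio", "p", "padj")),
                file.path(out_dir, paste0("enrichment_direct_", s, ".tsv")))
      out[[paste0("direct_", s)]] <- res
    }
    moderate <- filter_moderate(pp[[sets[1L]]]$counts, min_moderate)
    gsm <- suppressMessages(
      restrict_universe(dat$gene_sets,
                        gene_ids(moderate)[moderate$biotypes == "mRNA"]))
    all_regs <- unique(edges$final$regulator_id)
    ind <- suppressMessages(
      indirect_go(all_regs, edges$final, gsm, top_k = top_k, alpha = alpha))
    write_tsv(round_cols(ind, c("odds_ratio", "p", "padj")),
              file.path(out_dir, "enrichment_indirect.tsv"))
    out$indirect <- ind
    out
  })
  manifest$stages$go_enrichment <- list(
    n_direct_sig = sum(go[[paste0("direct_", sets[1L])]]$padj < alpha, na.rm = TRUE),
    n_indirect_sig = sum(go$indirect$padj < alpha, na.rm = TRUE))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

round_cols <- function(df, cols, digits = 6) {
  for (cc in intersect(cols, names(df))) df[[cc]] <- round(df[[cc]], digits)
  df
}

#' Summarize a completed pipeline run
#'
#' Re-tabulates, from the emitted tables, the up/down differential expression
#' counts per biotype and experiment set, the concordant gene counts, the
#' edge counts and the top enriched terms.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return A list of class `run_summary` with `de_counts` (data.frame, rows
#'   mRNA/lncRNA/miRNA/other, columns set x up/down), `concordant`,
#'   `n_edges`, `top_terms`.
#' @export
summarize_run <- function(run_dir) {
  de_files <- list.files(run_dir, pattern = "^de_.*\\.tsv$", full.names = TRUE)
  if (!length(de_files)) stop_validation("incomplete run: no de_*.tsv in ", run_dir)
  for (f in c("concordance.tsv", "edges.tsv", "enrichment_indirect.tsv")) {
    if (!file.exists(file.path(run_dir, f))) {
      stop_validation("incomplete run: missing ", f)
    }
  }
  de_counts <- data.frame(row.names = BIOTYPES)
  for (f in de_files) {
    s <- sub("^de_(.*)\\.tsv$", "\\1", basename(f))
    d <- read_tsv(f)
    for (dir in c("up", "down")) {
      de_counts[[paste(s, dir, sep = "_")]] <-
        vapply(BIOTYPES, function(bt) sum(d$biotype == bt & d$direction == dir),
               integer(1))
    }
  }
  concord <- read_tsv(file.path(run_dir, "concordance.tsv"))
  edges <- read_edges(file.path(run_dir, "edges.tsv"))
  terms <- read_tsv(file.path(run_dir, "enrichment_indirect.tsv"))
  out <- list(de_counts = de_counts,
              concordant = concord,
              n_edges = nrow(edges),
              top_terms = utils::head(terms, 5))
  class(out) <- "run_summary"
  out
}

#' @rdname summarize_run
#' @param x a `run_summary`.
#' @param ... ignored.
#' @export
print.run_summary <- function(x, ...) {
  cat("Differentially expressed genes (biotype x set/direction):\n")
  print(x$de_counts)
  cat(sprintf("\nConcordant network edges: %d\n", x$n_edges))
  cat("Top enriched terms (indirect GO):\n")
  print(x$top_terms[, c("term_id", "term_name", "k", "K", "padj")])
  invisible(x)
}
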