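#' Simulation configuration
#'
#' Parameters of the synthetic experiment generator. Defaults emulate the
#' study design at desk scale: two experimental sets (a hypoxia set with 5
#' placentas and a DMSO set with 6), each placenta sampled under three
#' conditions (`ctrl_0h`, `std_48h` and the set's exposure), negative-binomial
#' counts with gene-specific dispersion, log-normal library-size variation,
#' placenta and batch random effects, planted differentially expressed genes
#' with known log2 fold changes, planted regulator-to-mRNA co-expression
#' edges, and a flat GO map in which planted edge targets concentrate in a
#' few enriched terms.
#'
#' @param n_mrna,n_lncrna,n_mirna gene counts per biotype.
#' @param placentas_per_set named integer vector: placentas in the hypoxia
#'   and DMSO sets.
#' @param baseline_meanlog,baseline_sdlog natural-log mean and sd of the
#'   per-gene baseline expression distribution (counts per library).
#' @param disp_meanlog,disp_sdlog log-normal parameters of the per-gene NB
#'   dispersion alpha (variance = mu + alpha * mu^2). Because inter-placenta
#'   variation is injected separately through `placenta_sd` (and absorbed by
#'   placenta indicators at fitting time), alpha here is the residual
#'   within-placenta library noise, centred at 0.03.
#' @param frac_de fraction of genes differentially expressed under the
#'   exposure contrast (shared, with a common sign, across both sets).
#' @param de_log2fc magnitude of the planted log2 fold change.
#' @param n_true_edges number of planted regulator -> mRNA edges.
#' @param edge_strength slope of the target's log mean on the regulator's
#'   latent (log-scale) deviation.
#' @param regulator_sd sd of the per-sample latent biological variation given
#'   to regulator genes; this is the signal the co-expression test must find
#'   after conditioning on exposure and placenta.
#' @param placenta_sd,batch_sd sd of per-gene placenta and batch random
#'   effects on the log scale.
#' @param libsize_log_sd sd of log library-size factors.
#' @param n_go_terms,genes_per_term,n_enriched_terms flat GO map geometry;
#'   the first `n_enriched_terms` terms absorb the planted edge targets.
#' @param seed integer seed; the only source of randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 200L, n_lncrna = 60L, n_mirna = 40L,
                       placentas_per_set = c(hypoxia_set = 5L, dmso_set = 6L),
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       disp_meanlog = log(0.03), disp_sdlog = 0.5,
                       frac_de = 0.1, de_log2fc = 2,
                       n_true_edges = 10L, edge_strength = 1.5,
                       regulator_sd = 0.8,
                       placenta_sd = 0.4, batch_sd = 0.3,
                       libsize_log_sd = 0.3,
                       n_go_terms = 30L, genes_per_term = 10L,
                       n_enriched_terms = 2L,
                       seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              placentas_per_set = placentas_per_set,
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              disp_meanlog = disp_meanlog, disp_sdlog = disp_sdlog,
              frac_de = frac_de, de_log2fc = de_log2fc,
              n_true_edges = as.integer(n_true_edges),
              edge_strength = edge_strength, regulator_sd = regulator_sd,
              placenta_sd = placenta_sd, batch_sd = batch_sd,
              libsize_log_sd = libsize_log_sd,
              n_go_terms = as.integer(n_go_terms),
              genes_per_term = as.integer(genes_per_term),
              n_enriched_terms = as.integer(n_enriched_terms),
              seed = as.integer(seed))
  if (any(c(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna) <= 0L)) {
    stop_validation("gene counts must be positive")
  }
  if (length(cfg$placentas_per_set) != 2L || any(cfg$placentas_per_set < 2L)) {
    stop_validation("placentas_per_set must give >= 2 placentas for each of the 2 sets")
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop_validation("frac_de must be in [0, 1]")
  sds <- c(cfg$baseline_sdlog, cfg$disp_sdlog, cfg$regulator_sd,
           cfg$placenta_sd, cfg$batch_sd, cfg$libsize_log_sd)
  if (any(sds < 0)) stop_validation("standard deviations must be >= 0")
  if (cfg$n_true_edges < 0L) stop_validation("n_true_edges must be >= 0")
  if (cfg$n_true_edges > 0L && cfg$n_true_edges > cfg$n_mrna) {
    stop_validation("n_true_edges exceeds the number of mRNAs")
  }
  if (cfg$n_go_terms < cfg$n_enriched_terms) {
    stop_validation("n_go_terms must be >= n_enriched_terms")
  }
  if (cfg$genes_per_term > cfg$n_mrna) {
    stop_validation("genes_per_term exceeds the number of mRNAs")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-set trophoblast RNA-seq experiment with known ground truth
#'
#' Draws counts `Y[g, s] ~ NB(mean = sf[s] * exp(eta[g, s]), dispersion
#' alpha[g])` where the log mean `eta` sums a gene baseline, the condition
#' effect (the planted log fold change for DE genes), per-gene placenta and
#' batch random effects, an extra per-sample latent deviation for regulator
#' genes, and — for planted edge targets — `edge_strength` times the
#' regulator's latent deviation (placenta + batch + per-sample noise). The
#' edge term deliberately excludes the condition effect, so planted
#' co-expression is exactly the conditional association the adjusted test is
#' designed to detect.
#'
#' Batches: the hypoxia set is processed in two labs (placentas split 3/2),
#' the DMSO set in one; batch is therefore a coarsening of placenta and is
#' absorbed by the placenta indicators at fitting time.
#'
#' @param config a [sim_config()].
#' @return A list with elements `counts` ([count_matrix()] over all samples of
#'   both sets), `design` ([sample_design()]), `gene_sets` ([gene_set_map()]
#'   over the mRNA universe), and `truth`: a list with `de` (data.frame
#'   gene_id, log2fc — shared across both exposure contrasts), `time_de`
#'   (genes changing between 0 h and 48 h), `edges` (data.frame regulator_id,
#'   target_id, sign), `enriched_terms` (character).
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  ids <- c(sprintf("mRNA_%03d", seq_len(cfg$n_mrna)),
           sprintf("lnc_%03d", seq_len(cfg$n_lncrna)),
           sprintf("mir_%03d", seq_len(cfg$n_mirna)))
  biotypes <- stats::setNames(rep(c("mRNA", "lncRNA", "miRNA"),
                                  c(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna)), ids)
  n_genes <- length(ids)

  baseline <- stats::rnorm(n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(baseline) <- ids
  alpha <- stats::rlnorm(n_genes, cfg$disp_meanlog, cfg$disp_sdlog)
  names(alpha) <- ids

  ## ---- planted regulators, targets and GO geometry -----------------------
  mrna_ids <- ids[biotypes == "mRNA"]
  nc_ids <- ids[biotypes %in% c("lncRNA", "miRNA")]
  truth_edges <- data.frame(regulator_id = character(), target_id = character(),
                            sign = character(), stringsAsFactors = FALSE)
  regulators <- character(); targets <- character()
  if (cfg$n_true_edges > 0L) {
    n_reg <- max(1L, ceiling(cfg$n_true_edges / 2))
    lnc_pool <- ids[biotypes == "lncRNA"]
    mir_pool <- ids[biotypes == "miRNA"]
    n_lnc_reg <- ceiling(n_reg / 2); n_mir_reg <- n_reg - n_lnc_reg
    regulators <- c(sample(lnc_pool, min(n_lnc_reg, length(lnc_pool))),
                    sample(mir_pool, min(n_mir_reg, length(mir_pool))))
    targets <- sample(mrna_ids, cfg$n_true_edges)
    truth_edges <- data.frame(
      regulator_id = rep_len(regulators, cfg$n_true_edges),
      target_id = targets,
      sign = sample(c("positive", "negative"), cfg$n_true_edges, replace = TRUE),
      stringsAsFactors = FALSE)
    # planted genes must be comfortably expressed so the analysis can see them
    baseline[c(regulators, targets)] <- pmax(baseline[c(regulators, targets)], log(100))
  }

  ## ---- planted DE genes (shared sign across the two exposure sets) -------
  n_de <- round(cfg$frac_de * n_genes)
  de_genes <- if (n_de > 0L) sample(ids, n_de) else character()
  if (cfg$n_true_edges > 0L && n_de > 0L) {
    # regulators and their targets are part of the exposure response, so the
    # DE-based regulator/target selection of the pipeline can recover them
    de_genes <- unique(c(de_genes, regulators, targets))
  }
  de_sign <- sample(c(1, -1), length(de_genes), replace = TRUE)
  de_lfc <- stats::setNames(de_sign * cfg$de_log2fc, de_genes)
  time_genes <- if (n_de > 0L) sample(ids, n_de) else character()
  time_lfc <- stats::setNames(sample(c(1, -1), length(time_genes), replace = TRUE) *
                                cfg$de_log2fc, time_genes)

  ## ---- sample sheet -------------------------------------------------------
  n_plac <- cfg$placentas_per_set
  plac_hpx <- sprintf("P%02d", seq_len(n_plac[["hypoxia_set"]]))
  plac_dmso <- sprintf("P%02d", n_plac[["hypoxia_set"]] + seq_len(n_plac[["dmso_set"]]))
  batch_of <- c(stats::setNames(rep(c("B1", "B2"),
                                    c(ceiling(length(plac_hpx) / 2),
                                      floor(length(plac_hpx) / 2))), plac_hpx),
                stats::setNames(rep("B3", length(plac_dmso)), plac_dmso))
  rows <- list()
  for (p in plac_hpx) {
    for (cond in c("ctrl_0h", "std_48h", "hpx_48h")) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste("hpx", p, cond, sep = "_"),
        experiment_set = "hypoxia_set", condition = cond,
        placenta_id = p, batch_id = batch_of[[p]], stringsAsFactors = FALSE)
    }
  }
  for (p in plac_dmso) {
    for (cond in c("ctrl_0h", "std_48h", "dmso_48h")) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste("dmso", p, cond, sep = "_"),
        experiment_set = "dmso_set", condition = cond,
        placenta_id = p, batch_id = batch_of[[p]], stringsAsFactors = FALSE)
    }
  }
  design <- sample_design(do.call(rbind, rows))
  n_samples <- nrow(design)

  ## ---- random effects and linear predictor --------------------------------
  placentas <- unique(design$placenta_id)
  batches <- unique(design$batch_id)
  plac_eff <- matrix(stats::rnorm(n_genes * length(placentas), 0, cfg$placenta_sd),
                     n_genes, length(placentas), dimnames = list(ids, placentas))
  batch_eff <- matrix(stats::rnorm(n_genes * length(batches), 0, cfg$batch_sd),
                      n_genes, length(batches), dimnames = list(ids, batches))
  u <- matrix(0, n_genes, n_samples, dimnames = list(ids, design$sample_id))
  if (length(regulators)) {
    u[regulators, ] <- stats::rnorm(length(regulators) * n_samples, 0, cfg$regulator_sd)
  }

  eta <- matrix(baseline, n_genes, n_samples, dimnames = list(ids, design$sample_id))
  eta <- eta + plac_eff[, design$placenta_id] + batch_eff[, design$batch_id] + u

  exposed <- design$condition %in% c("hpx_48h", "dmso_48h")
  if (length(de_genes)) {
    eta[de_genes, exposed] <- eta[de_genes, exposed] + de_lfc[de_genes] * log(2)
  }
  at_0h <- design$condition == "ctrl_0h"
  if (length(time_genes)) {
    eta[time_genes, at_0h] <- eta[time_genes, at_0h] + time_lfc[time_genes] * log(2)
  }
  if (nrow(truth_edges)) {
    latent <- (plac_eff[, design$placenta_id, drop = FALSE] +
                 batch_eff[, design$batch_id, drop = FALSE] + u)
    for (k in seq_len(nrow(truth_edges))) {
      s <- if (truth_edges$sign[k] == "positive") 1 else -1
      eta[truth_edges$target_id[k], ] <- eta[truth_edges$target_id[k], ] +
        s * cfg$edge_strength * latent[truth_edges$regulator_id[k], ]
    }
  }

  ## ---- counts --------------------------------------------------------------
  sf <- exp(stats::rnorm(n_samples, 0, cfg$libsize_log_sd))
  mu <- sweep(exp(pmin(eta, 30)), 2, sf, `*`)
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                  size = 1 / pmax(alpha, 1e-12)),
                   n_genes, n_samples, dimnames = dimnames(mu))

  ## ---- GO map over the mRNA universe --------------------------------------
  term_ids <- sprintf("GO:%04d", seq_len(cfg$n_go_terms))
  sets <- vector("list", cfg$n_go_terms); names(sets) <- term_ids
  enriched <- character()
  if (cfg$n_enriched_terms > 0L && length(targets)) {
    enriched <- term_ids[seq_len(cfg$n_enriched_terms)]
    split_tgt <- split(targets, rep_len(seq_along(enriched), length(targets)))
    for (i in seq_along(enriched)) {
      core <- split_tgt[[i]]
      fill <- sample(setdiff(mrna_ids, core),
                     max(0L, cfg$genes_per_term - length(core)))
      sets[[enriched[i]]] <- c(core, fill)
    }
  }
  for (t in term_ids[!(term_ids %in% enriched)]) {
    sets[[t]] <- sample(mrna_ids, cfg$genes_per_term)
  }
  gsm <- gene_set_map(sets, universe = mrna_ids,
                      term_names = stats::setNames(
                        sprintf("synthetic process %02d", seq_len(cfg$n_go_terms)),
                        term_ids))

  truth <- list(
    de = data.frame(gene_id = de_genes, log2fc = unname(de_lfc[de_genes]),
                    stringsAsFactors = FALSE),
    time_de = data.frame(gene_id = time_genes, log2fc = unname(time_lfc[time_genes]),
                         stringsAsFactors = FALSE),
    edges = truth_edges,
    enriched_terms = enriched,
    gene_params = data.frame(gene_id = ids, baseline_log = unname(baseline),
                             dispersion = unname(alpha), stringsAsFactors = FALSE),
    size_factors = stats::setNames(sf, design$sample_id))

  list(counts = count_matrix(counts, biotypes), design = design,
       gene_sets = gsm, truth = truth)
}

#' Simulate the confounded gene pair of the worked example
#'
#' Draws `Z ~ N(0, 1)` and two "gene expressions" that are conditionally
#' independent given the confounder: `X = Z + e1`, `Y = Z + e2` with
#' `e1, e2 ~ N(0, 1)` independent. Marginally X and Y have Pearson
#' correlation 1/2, while their partial correlation given Z is 0 — the
#' textbook spurious-correlation situation the confounder-adjusted
#' co-expression test is built to handle.
#'
#' @param n number of samples (>= 3).
#' @param seed integer seed.
#' @return A list with numeric vectors `x`, `y`, `z` of length `n`.
#' @examples
#' tri <- simulate_confounded_triple(1e4, seed = 1)
#' cor(tri$x, tri$y)  # about 0.5
#' @export
simulate_confounded_triple <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    stop_validation("`n` must be a single number >= 3")
  }
  n <- as.integer(n)
  with_seed(seed, {
    z <- stats::rnorm(n)
    x <- z + stats::rnorm(n)
    y <- z + stats::rnorm(n)
    list(x = x, y = y, z = z)
  })
}
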