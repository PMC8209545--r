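---
title: "Models and methods behind trophonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trophonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Primary human trophoblasts (PHT cells) cultured from term placentas
spontaneously differentiate from mononuclear cytotrophoblasts toward a
syncytiotrophoblast-like phenotype over about 48 h in culture. Perturbations
that blunt this differentiation — hypoxia, or exposure to DMSO — change the
expression of thousands of transcripts. trophonet provides the statistical
machinery to analyse such experiments from gene-level count matrices: which
mRNAs, lncRNAs and miRNAs respond to an exposure; whether two independent
exposure experiments agree in direction; which mRNAs are co-expressed with
which non-coding regulators once known confounders are removed; and which
biological processes those associations point to, including for lncRNAs and
miRNAs that have no gene-ontology annotation of their own.

The package is organised around a hand-written negative binomial GLM
(`nb_glm()`), in the classic R modelling idiom: a fitting function returning
a classed object with `print`, `summary`, `coef`, `vcov`, `residuals`,
`predict`, `simulate` and `logLik` methods. Everything downstream —
differential expression, the co-expression test — is a thin, explicit layer
over that estimator.

## Differential expression model

Counts for gene $g$ in library $s$ are modelled as negative binomial,

$$ Y_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g), \qquad
   \mathrm{Var}(Y_{gs}) = \mu_{gs} + \alpha_g \mu_{gs}^2, $$

with a log link and fixed offsets,

$$ \log \mu_{gs} = x_s^\top \beta_g + \log f_s , $$

where $f_s$ is the sample's size factor (median-of-ratios estimator,
rescaled to geometric mean 1) and $x_s$ encodes an intercept, a
treatment-coded exposure condition (reference: 48 h standard culture), and
placenta indicators. Batch (processing lab) indicators are added only when
they are not aliased with placenta; in the common design where every
placenta is processed in one lab, batch is a coarsening of placenta and is
silently absorbed by the placenta terms (a warning reports the dropped
columns).

Coefficients are estimated by iteratively reweighted least squares (IRLS)
at fixed dispersion (tolerance $10^{-8}$ on the maximum coefficient change,
at most 100 iterations; linear predictors clamped to $\pm 30$ for numerical
safety). The dispersion is estimated by an outer one-dimensional
optimisation of the profile likelihood over $\alpha \in [10^{-8}, 100]$ on
the log scale, started from a method-of-moments estimate, using the
Cox–Reid adjusted profile likelihood
$\ell(\hat\beta(\alpha), \alpha) - \tfrac12 \log \det (X^\top W X)$ — the
standard correction for the downward bias of the dispersion MLE when the
mean model uses up a large share of the observations.

The exposure contrast is tested with a Wald statistic on the natural-log
scale, $z = \hat\beta / \widehat{\mathrm{se}}(\hat\beta)$, with a two-sided
normal tail p-value; effects are reported as $\log_2$ fold changes.
P-values are adjusted with the Benjamini–Hochberg step-up across all tested
genes of all biotypes within a contrast, and a gene is called up
(down) when its adjusted p-value is below the FDR level (default 0.05) with
a positive (negative) fold change. Genes whose fit does not converge, or
that are all zero, are reported with missing p-values and excluded from the
number of tests, never dropped.

### Dispersion moderation

With 5 placentas per condition the per-contrast fit has only about 4
residual degrees of freedom per gene. At that depth the per-gene dispersion
MLE has enormous sampling spread and, for a few percent of genes, collapses
to the lower boundary even when the true dispersion is sizeable; the Wald
statistic for such a gene is inflated several-fold and the far tail of the
null distribution is badly miscalibrated (we measured a null Kolmogorov
distance of about 0.10 and a realised FDR of about 0.24 where 0.05 was
nominal). `run_de()` therefore moderates dispersions across genes by
default: a common dispersion is estimated by maximising the pooled Cox–Reid
adjusted profile likelihood over all genes, a log-normal prior is centred
on it with variance equal to the excess spread of the per-gene estimates
over their theoretical sampling variability (floored at 0.25 on the
log-variance scale, following common empirical-Bayes practice), and each
gene's dispersion is re-estimated at its maximum a posteriori value. This
is the same idea DESeq2 uses. After moderation the null Kolmogorov distance
drops to about 0.03 and the realised FDR to about 0.01. Plain per-gene MLEs
remain available via `moderate_dispersion = FALSE`.

## Model-based co-expression

The central tool is a regression test of co-expression that adjusts for
known confounders. For a candidate pair — a non-coding regulator with
log-transformed normalised expression $X$ and an mRNA target with counts
$Y$ — and a confounder matrix $Z$ (intercept, exposure condition, placenta,
batch when estimable), the model is

$$ g\big(\mathrm{E}[Y \mid X, Z]\big) = aX + BZ , $$

and the pair is called co-expressed when the hypothesis $a = 0$ is
rejected. With the negative binomial family, $g$ is the log link, size
factors enter as offsets, and $a$ is Wald-tested exactly as in the
differential expression machinery (the target's dispersion is re-estimated
under each pair's model; only the empirical prior is shared, estimated from
the target genes under the confounder-only model). With the Gaussian
family, $g$ is the identity, the fit is ordinary least squares, and the $t$
test of $a$ on $n - \mathrm{rank}(Z) - 1$ degrees of freedom is numerically
identical to the test of zero partial correlation between $X$ and $Y$ given
$Z$ — the joint-Gaussian special case, verified to $10^{-10}$ in the test
suite.

Why adjust? If a confounder $Z \sim N(0,1)$ drives both genes —
$X, Y \mid Z = z \sim N(z, 1)$, conditionally independent — then $X$ and
$Y$ show a marginal Pearson correlation of $1/2$ although their partial
correlation given $Z$ is zero. An unadjusted co-expression screen reports
such pairs; the adjusted test does not. `simulate_confounded_triple()`
reproduces exactly this construction and the validation suite verifies both
numbers by Monte Carlo, along with the calibration of the adjusted test
(rejection rate within [0.03, 0.07] at nominal 0.05 over 2000 replicates of
$n = 50$) against the unadjusted test (rejection rate above 0.5).

### Network assembly

`build_network()` tests every (regulator, target) pair within one
experiment set and adjusts p-values by Benjamini–Hochberg within each
regulator-biotype family (lncRNA pairs and miRNA pairs are separate
families), keeping families homogeneous. The direction convention is fixed:
the count-scale response is always the mRNA; the covariate is always the
non-coding regulator. Pairs are tested in each experiment set separately
and `concordant_edges()` retains edges significant with the same sign in
both sets. This mirrors the concordance logic used for differential
expression and is also a practical necessity at this sample size: with 15
libraries and 7–8 confounder columns, a single set occasionally aligns an
unrelated regulator with a latent direction shared by several targets,
producing clustered false edges; requiring independent replication in the
second set removes them (measured false-edge rate ~0 at pooled recall ~0.9
in the 20-replicate validation) while true planted edges, which exist in
both sets, survive.

## Concordance between experiments

Among genes called differentially expressed in both experiment sets,
`concordance_analysis()` tabulates direction agreement in a 2×2 table
(up/down in set 1 × up/down in set 2) per biotype and tests it with the
two-sided Fisher exact test (probability-mass ordering; odds ratio reported
as the sample OR with explicit 0/∞ conventions). The diagonal gene sets —
concordantly up, concordantly down — are the inputs to the network stage.
A "concordant DE gene" is defined strictly: adjusted p below the level in
both sets *and* the same fold-change sign.

## GO enrichment, direct and indirect

`enrich()` computes, per term, the 2×2 over-representation table against a
background universe and the one-sided Fisher exact p-value (hypergeometric
upper tail), BH-adjusted across terms and ranked by adjusted p. The
universe is the moderate-expression set — genes with at least 25 reads per
library on average — matching the principle that enrichment backgrounds
should contain only genes that could have been selected.

Because lncRNAs and miRNAs lack GO annotation, `indirect_go()` attributes
processes to a regulator set through its co-expressed mRNAs: mRNAs with at
least one significant edge to the set are ranked by their best edge's
adjusted p-value, truncated to the `top_k` best (default 500; the rank
statistic and cap are configurable since no canonical choice exists), and
enriched against the same universe. With `semantics = "intersection"` an
mRNA qualifies only with both a lncRNA and a miRNA edge.

## The synthetic data generator

`simulate_experiment()` draws data with the structure the analysis assumes,
with known ground truth for every stage. The design mirrors the study: a
hypoxia set (5 placentas × {0 h control, 48 h standard, 48 h hypoxia}) and
a DMSO set (6 placentas × {0 h control, 48 h standard, 48 h DMSO}), 300
genes by default (200 mRNA / 60 lncRNA / 40 miRNA — large enough for FDR
behaviour, small enough for seconds-level tests). For gene $g$ and sample
$s$:

$$ Y_{gs} \sim \mathrm{NB}\big(f_s \exp(\eta_{gs}),\ \alpha_g\big), $$

where $\eta_{gs}$ sums a log-normal baseline (log-mean $\log 100$, sd 1), a
condition effect (the planted $\log_2$ fold change, $\pm 2$ for 10% of
genes, shared with a common sign across both exposure sets so concordance
has signal), per-gene placenta and batch random effects (sd 0.4 and 0.3 on
the natural-log scale), an extra per-sample latent deviation for regulator
genes (sd 0.8 — regulatory ncRNAs are given substantial biological
variability so that co-expression is detectable), and, for planted edge
targets, `edge_strength` (1.5) times the regulator's latent deviation
(placenta + batch + per-sample noise, but *not* the condition effect — so
planted co-expression is exactly the conditional association the adjusted
test is designed to find, not a disguised exposure effect). Library size
factors are log-normal (sd 0.3). Dispersions are log-normal with median
0.03: because inter-placenta variability is injected separately and
absorbed by the placenta indicators at fitting time, $\alpha_g$ represents
residual within-placenta library noise, for which cell-culture-scale values
of 0.01–0.05 are typical. Ten regulator→mRNA edges are planted by default
(3 lncRNA and 2 miRNA regulators, 2 targets each, random signs); the
planted targets are concentrated in 2 of the 30 GO terms so that indirect
enrichment has a known answer; planted regulators and targets are added to
the DE gene set so the pipeline's DE-based candidate selection can find
them, and their baselines are floored at 100 counts so they pass the
moderate-expression filter.

What the generator does *not* emulate: mean–dispersion trends, gene–gene
correlation beyond the planted edges, compositional effects, zero
inflation, transcript-length bias, or any sequence-level structure. Tests
passing on this generator show the estimators do what they claim under the
assumed model, not that the model captures every property of real
trophoblast libraries.

All randomness flows from a single seed per call; the caller's RNG state is
saved and restored, and identical seeds give bit-identical output.

## Numerical and design choices

- **Normalisation.** Shifted log: $\log_2(\mathrm{count}/f_s + 1)$. This
  replaces regularised/variance-stabilising transforms by a transparent,
  monotone map that is adequate for ordination and as the regulator
  covariate; the pseudocount is configurable.
- **Size factors.** Median of ratios to the per-gene geometric mean,
  restricted to genes positive in all samples; total-count fallback with a
  warning when no gene qualifies; factors rescaled to geometric mean
  exactly 1.
- **MDS.** Classical (Torgerson) scaling of the Euclidean sample-distance
  matrix; each axis's sign is fixed by making its largest-magnitude
  coordinate positive, so outputs are reproducible across platforms;
  requesting more dimensions than the attainable rank is an error that
  names the rank.
- **Filters.** Closed thresholds (mean ≥ cutoff is kept), applied per
  experiment set; filters are idempotent and commute.
- **Fisher conventions.** Two-sided p by probability-mass ordering with
  relative tolerance $10^{-7}$; sample odds ratio with 0-cell → 0/∞ and
  0/0 → NA.
- **Ties in enrichment ranking** break by raw p, then term id.
- **Convergence failures** surface as missing p-values and a logged count,
  never as silent drops; all-zero genes are flagged degenerate.
- **Pipeline caps.** The pair scan in the pipeline is capped (12
  regulators × 40 targets by default) to the strongest DE candidates —
  the package's chosen working scale for a desk-size analysis; the caps are
  configuration entries.

## Problem sizes used by the validation suite

The test suite exercises: the worked confounding example at $n = 10^6$;
calibration of the adjusted test over 2000 replicates of $n = 50$; null
p-value uniformity at 500 genes × 10 libraries; FDR control over 20
replicate simulations of the default design; network recovery and indirect
GO over 20 replicate two-set simulations with 5 decoy regulators and 15
decoy targets per set; and exact-test oracles by full enumeration (200
Fisher tables, 100 hypergeometric triples). These sizes were chosen so the
whole suite runs in minutes on one core while leaving the statistical
assertions well-powered.

## Known limitations

- The Wald test with a normal reference is still mildly liberal at 10
  libraries even after dispersion moderation (measured null rejection
  ~0.06–0.07 at nominal 0.05); analyses at this depth should treat
  borderline calls accordingly.
- The common-dispersion prior is constant in the mean; real data with a
  strong mean–dispersion trend would warrant a trended prior.
- Per-set testing plus cross-set concordance is one reading of how to pool
  two experiment sets; pooling into a single model with a set covariate is
  a reasonable alternative not implemented here.
- The indirect GO "top-ranked" rule (best-edge adjusted p, capped) is one
  of several defensible rank statistics; results with small edge counts
  are insensitive to the cap.
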