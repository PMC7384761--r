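# taeqtl

Tissue-augmented empirical-Bayes mapping of local (cis) eQTL in inbred
panels.

## The problem

An expression quantitative trait locus (eQTL) is a genetic variant associated
with a gene's RNA expression level. The conventional local-eQTL analysis
regresses each gene's strain-mean expression on each SNP within 1 Mb of the
gene's transcription start site, tissue by tissue, and ranks genes by the
minimum P-value — discarding everything already known about the same gene's
regulation in other tissues. In small panels (tens of recombinant inbred
strains) this costs real power, even though local genetic control of
expression is substantially conserved across tissues.

`taeqtl` implements **TA-eQTL**: the eQTL evidence from a *secondary* tissue
becomes an informative prior for the effect in the *primary* tissue, via a
conjugate normal model with a closed-form posterior. Because the prior uses
only gene-level summary statistics (a P-value and an effect sign), the two
tissues may come from different expression platforms with different probeset
coverage. The package is aimed at quantitative geneticists working with
recombinant-inbred or similar binary-genotype panels (e.g. the BXD mouse
panel) who want to borrow cross-tissue strength without a full multi-tissue
joint model.

## The model

Stage one, per tissue, for gene *g* and SNP *k* (genotype coded 0/1):

    y_gi = alpha_gk + beta_gk x_ki + eps_gki,   eps ~ N(0, sigma_gk^2)

fit by least squares; per gene, only the SNP with the minimum P-value is
kept (gene-level, not probeset-level, so unequal platforms are fine).

Stage two, across genes, with z_g the secondary tissue's signed evidence
(the sign of the primary slope times −log10 of the secondary P-value):

    beta_g = gamma1 + gamma2 z_g + U_g,   U_g ~ N(0, tau^2)

estimated by regressing the primary-tissue slope estimates on z across
genes. Conjugacy then gives per gene, in closed form:

    S^-1       = tau^-2 + sigma^-2                     (posterior variance)
    lambda     = tau^2 / (tau^2 + sigma^2)             (shrinkage weight)
    beta_tilde = c (1 - lambda) (gamma1 + gamma2 z) + lambda beta_hat

where `c = max|beta_hat| / max|fitted prior mean|` corrects the prior's
systematically smaller scale. Genes are ranked by the contour probability
`2 * pnorm(-|beta_tilde| / sqrt(S))`, the Bayesian analogue of a two-sided
test. Comparators (conventional per-tissue scan, Stouffer inverse-normal
meta-analysis), ROC/AUC benchmarking with stratified-bootstrap CIs and
DeLong tests, cross-tissue overlap enrichment, a strain sub-sampling
protocol, and a truth-known two-tissue panel simulator are all included.

## Worked example

```r
library(taeqtl)

sim <- simulate_panel(sim_config(n_genes = 500, seed = 42))
#> <ta_sim> 30 strains, 500 genes (150 positive), 2500 SNPs; seed 42

aligned_p <- align_strains(sim$genotypes, sim$primary)
aligned_s <- align_strains(sim$genotypes, sim$secondary)
liver <- collapse_to_gene(scan_tissue(aligned_p$expr, aligned_p$genotypes))
lung  <- collapse_to_gene(scan_tissue(aligned_s$expr, aligned_s$genotypes))

ta <- run_ta_eqtl(liver, lung)
attr(ta, "prior_fit")
#> <ta_prior_fit> 500 genes | gamma = (-0.0443, 0.668) | tau2 = 0.7497 | c = 0.67

dplyr::arrange(ta, score)[1:4, c("gene_id", "beta_hat", "prior_mean",
                                 "lambda", "beta_tilde", "contour_p")]
#>   gene_id   beta_hat prior_mean lambda beta_tilde   contour_p
#> 1 gene00406     3.43       4.75  0.419       3.29 0.000000641
#> 2 gene00116    -3.31      -5.12  0.361      -3.39 0.000000972
#> 3 gene00212    -3.36      -3.72  0.390      -2.83 0.0000280
#> 4 gene00085    -3.05      -4.13  0.299      -2.85 0.0000829
```

The prior fit says: across genes, each unit of signed secondary-tissue
evidence moves the expected primary slope by 0.668 expression units, with
residual spread `tau2 = 0.75`; `c = 0.67` rescales the fitted prior means to
the slope estimates' range. For the top gene, 42% of the posterior mean
(`lambda = 0.419`) comes from the gene's own slope and the rest from the
cross-tissue prior; the contour probability `6.4e-7` is its ranking score.

Benchmark both rankings against the simulated truth:

```r
gold <- sim$truth$gene_id[sim$truth$is_positive]
roc_auc(dplyr::tibble(gene_id = liver$gene_id, score = liver$p_value), gold, seed = 42)
#> <ta_roc> AUC = 0.8187 (95% CI 0.773-0.861, 2000 boot) | 150 positives / 350 negatives
roc_auc(dplyr::tibble(gene_id = ta$gene_id, score = ta$score), gold, seed = 42)
#> <ta_roc> AUC = 0.8132 (95% CI 0.771-0.854, 2000 boot) | 150 positives / 350 negatives

overlap_analysis(liver, lung, thresholds = c(0.05, 0.01))[, c(1:2, 3, 5:7)]
#>   threshold n_sig_t1 n_sig_t2 observed_shared expected_shared ratio
#> 1      0.05      122       84              45            20.5  2.20
#> 2      0.01       74       48              31            7.10  4.36
```

At the full panel size of 30 strains the two methods are statistically
indistinguishable (DeLong p = 0.79); the prior's value appears at small n —
re-run the scan on 10 strains via `subsample_protocol()` and the TA-eQTL AUC
advantage over the conventional scan grows (the acceptance suite quantifies
this over 20 seeded replicates). The overlap ratios > 1 show the two
simulated tissues share local eQTL well in excess of independence, the
premise that makes cross-tissue borrowing worthwhile.

A command-line interface over the same functions is installed as
`exec/ta-eqtl` (subcommands `simulate`, `scan`, `run`, `meta`, `evaluate`,
`subsample`; see `cli_main()`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's full pipeline from scratch on the default synthetic
world — simulation, both tissue scans, TA-eQTL, meta-analysis, ROC/AUC with
bootstrap CIs, overlap enrichment, and a small sub-sampling run — logging the
summary statistics to standard error and writing the JSON report to `--out`.

## Vignette

`vignettes/ta-eqtl-methods.Rmd` documents the model and its assumptions, the
tunable parameters and their defaults, what the simulator does and does not
emulate, numerical safeguards, and known limitations (including the
calibration caveat for the contour probability under a global null).
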