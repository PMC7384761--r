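---
title: "TA-eQTL: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TA-eQTL: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taeqtl)
```

# The method in outline

`taeqtl` detects genes with a local (cis) eQTL in a *primary* tissue of an
inbred panel, borrowing strength from eQTL summary evidence in a *secondary*
tissue. The pipeline has three stages.

**Stage 1 — conventional scan, per tissue.** For every probeset and every
SNP within `window_bp` (default 1 Mb, closed interval) of the gene's
transcription start site, ordinary least squares of strain-mean expression
on the 0/1 genotype gives a slope $\hat\beta$, residual variance
$\hat\sigma^2 = \mathrm{SSE}/(n-2)$, and a two-sided $t$ P-value on $n-2$
degrees of freedom. Each gene keeps the single (probeset, SNP) pair with the
minimum P-value across *all* of its probesets — a gene-level collapse, which
is what lets the two tissues come from different platforms: they need share
only gene identifiers, not probesets or even selected SNPs.

**Stage 2 — the cross-tissue prior.** The prior covariate is
$z_g = \mathrm{sign}(\hat\beta_g^{\,\text{primary}})\cdot
(-\log_{10} p_g^{\,\text{secondary}})$. Regressing the primary slope
estimates on $(1, z_g)$ across genes gives $\hat\Gamma = (\hat\gamma_1,
\hat\gamma_2)$ and the residual variance $\hat\tau^2$: an empirical prior
$\beta_g \sim N(Z_g\hat\Gamma, \hat\tau^2)$ with common variance across
genes.

**Stage 3 — conjugate posterior.** With the first-stage estimate treated as
$\hat\beta_g \sim N(\beta_g, \hat\sigma_g^2)$, the posterior is normal with

$$S_g^{-1} = \hat\tau^{-2} + \hat\sigma_g^{-2}, \qquad
\lambda_g = \frac{\hat\tau^2}{\hat\tau^2 + \hat\sigma_g^2}, \qquad
\tilde\beta_g = c\,(1-\lambda_g)\,Z_g\hat\Gamma + \lambda_g\hat\beta_g .$$

$\lambda_g \to 1$ as the prior becomes uninformative (large $\hat\tau^2$),
recovering the data-only estimate; $\lambda_g \to 0$ defers to the prior
mean. The rescaling weight $c$ (below) corrects the prior means'
systematically compressed scale. Genes are ranked by the contour probability
$2\Phi(-|\tilde\beta_g|/\sqrt{S_g})$, smaller meaning stronger evidence.

# Parameters that matter

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `window_bp` | 1e6 | base pairs | the conventional local-SNP window on either side of the TSS |
| `log_base` | 10 | — | matches the usual $-\log_{10}P$ evidence scale; natural log is one flag away |
| `sign_source` | `"primary"` | — | effect direction does not transfer across tissues (the tissues may select different SNPs), so the sign that keeps prior mean and data estimate on one convention is the primary tissue's own slope sign |
| `c_mode` | `"abs"` | — | $c=\max\lvert\hat\beta\rvert / \max\lvert Z\hat\Gamma\rvert$; with a signed covariate the raw (signed) maximum would depend on the arbitrary sign convention, so the absolute-value reading is the default and `"raw"` preserves the literal signed form |
| `sigma_mode` | `"residual"` | expr.\ units$^2$ | $\hat\sigma^2$ in the posterior is the first-stage *residual* variance, the model read verbatim; `"beta_se2"` substitutes the slope's squared standard error, the sampling-variance reading — see "Known limitations" |
| `weighted` | `TRUE` | — | applies $c$; `FALSE` fixes $c=1$, the unweighted posterior mean |
| `min_n` | 5 | strains | smallest informative fit: both genotype classes present, below which a pair is skipped, not imputed |
| `n_boot` | 2000 | replicates | stratified percentile bootstrap for the AUC CI |

Missing genotypes (heterozygous or unknown calls) are dropped pairwise per
SNP, never imputed; this maximizes the usable strain count for each test.

# The rescaling weight c

The second-stage fitted values $Z\hat\Gamma$ live on a much narrower range
than the slope estimates they predict (regression attenuation: the fit
explains only part of the slope variance). Left alone, every posterior mean
would be pulled toward a compressed prior scale. $c$ stretches the prior
mean so that its extreme matches the extreme of the slope estimates. It is
one global constant, estimated once per analysis; setting `weighted = FALSE`
removes it.

# What the simulator emulates — and what it does not

`simulate_panel()` generates the stated world the tests run in:

* **Genotypes.** Binary RI-style calls for `n_strains` (default 30, the
  primary-panel size of the motivating data), simulated as a two-state
  Markov chain along each chromosome: switch probability 0.02 between
  adjacent SNPs inside a gene's 5-SNP block, 0.45 between blocks. This
  produces the high local LD that makes cis-window SNP selection meaningful,
  *without* modelling real pedigree descent, recombination maps, or
  genotyping error. Allele frequencies are held inside `maf_range` (default
  0.10–0.90) by minimally flipping violating SNPs.
* **Expression.** Per gene, $y = \beta x_{\text{causal}} + \varepsilon$ on a
  raw scale with $\beta \sim N(0, 1)$ for the 30% of genes with a true
  primary effect and $\varepsilon \sim N(0,1)$, then an affine rescale per
  gene to mean 8, SD 2 — the strain-mean log2 convention of GeneNetwork-style
  data sets. The truth table records effects on the *emitted* scale, so
  parameter-recovery tests are well defined.
* **Sharing.** 70% of true effects recur in the secondary tissue with the
  same magnitude and an independently random sign (the method deliberately
  discards cross-tissue directionality). `fraction_platform_specific`
  removes genes from the secondary panel to emulate unequal probeset
  coverage.

A green test on this world establishes that the implementation does what
the model says under the stated structure. It does **not** establish
performance under correlated noise across genes, non-normal expression,
population structure, batch effects, or a gold standard that is itself a
biased sample of true positives — all present in real data.

Defaults were chosen once from the emulated study's scale (30 strains, gene
spacing 3 Mb so 1 Mb windows do not overlap neighbouring genes' blocks) and
are not tuned against test outcomes.

# Numerical choices

* P-values are floored at `1e-300` before any log or quantile transform.
* $\hat\tau^2$ is floored at `1e-12` so the posterior stays proper when the
  second-stage fit is near-perfect.
* A perfectly constant response returns slope 0 with P = 1 (guarded
  division); a monomorphic genotype or fewer than `min_n` informative
  strains is a *skip*, counted and logged, never a zero.
* Gene-level collapse ties are broken by smaller SNP position, then
  lexicographic probeset id — declared, since any rule is defensible.
* Tied ranking scores contribute half-concordance to the AUC (average-rank
  handling), equivalent to the trapezoid rule over the tie block's diagonal
  segment; each method's ROC uses its own threshold grid.
* The overlap enrichment test is a one-sided binomial with success
  probability $(n_1/n)(n_2/n)$ — a declared choice where several tests would
  serve.
* Sub-sampling draws strains without replacement, replicates independent,
  with each replicate's seed derived deterministically from (master seed,
  size, replicate index), all below $2^{31}$.
* Genes absent from the secondary tissue bypass the Bayesian update and keep
  their conventional P-value, flagged `has_prior = FALSE`. A zero-valued
  prior covariate would actively shrink such genes toward the null on the
  basis of absent evidence, which is why pass-through is the default and
  only behaviour.

# Design decisions that were genuinely open

* **What stands in for $\sigma^2$.** The posterior formula combines
  $\hat\tau^2$ with "the" first-stage variance. Reading it as the residual
  variance (SSE/(n−2)) follows the stated estimation procedure literally and
  is the default; statistically, the sampling variance of $\hat\beta$
  (`sigma_mode = "beta_se2"`) is the quantity for which conjugacy of
  $\hat\beta \sim N(\beta, \cdot)$ holds exactly. Both are exposed; results
  in this package's own evaluation are qualitatively unchanged.
* **Stouffer conversion.** The two-sided per-tissue P-values are pushed
  through the one-tailed inverse-normal transform unchanged — direction is
  deliberately discarded, consistent with the prior construction. The
  textbook signed variant (halve P, reattach the effect sign) is available
  as `conversion = "half_p_signed"`.
* **TSS anchoring.** Strand-aware when strand is annotated (start for `+`,
  end for `-`), else the annotation start.
* **Per-method threshold grids** for ROC curves (rather than one shared
  grid): AUC and DeLong comparisons are rank-based and unaffected.

# Known limitations

* **The contour probability is a ranking score, not a calibrated P-value.**
  Under a global null, $\tilde\beta/\sqrt{S}$ is under-dispersed relative to
  $N(0,1)$ — the posterior shrinks toward the prior mean while $S$ counts
  both variance components — so its distribution is conservative (piled
  toward 1), with either `sigma_mode`. Ranking, AUC and all comparative
  results are unaffected; treating the score as an error-rate-controlling
  P-value would be anti-conservative nowhere but would lose power against a
  nominal threshold. The acceptance suite documents this measured deviation
  from uniformity rather than hiding it.
* One covariate only: the prior design is a single signed $-\log P$ column,
  though the second-stage regression extends naturally to more.
* Gene-level inference only: one SNP represents each gene; multi-SNP
  architectures and SNP-level claims are out of scope.
* The empirical prior ignores estimation error in $\hat\beta$ when fitting
  $\hat\tau^2$ across genes, so $\hat\tau^2$ absorbs sampling noise; this is
  inherent to the two-stage design.
* Distal (trans) eQTL, covariate adjustment, and multiple-testing correction
  inside the scan are deliberately excluded; all downstream consumers rank
  raw scores.
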