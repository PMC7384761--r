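# TA-eQTL core: cross-tissue prior covariate, second-stage prior regression,
# weighted conjugate-normal posterior and contour probability.

#' Build the cross-tissue prior covariate
#'
#' For every gene present in both tissues' gene-level records, the covariate is
#' the negative logarithm of the secondary tissue's P-value multiplied by the
#' sign of the chosen tissue's slope estimate:
#' `z = sign(beta_hat) * (-log(p_secondary))`. Directionality is not assumed to
#' transfer across tissues (the two tissues need not even select the same SNP),
#' so the sign source defaults to the primary tissue's slope, keeping prior
#' mean and data estimate on a common sign convention. P-values are floored at
#' 1e-300 before the log.
#'
#' @param primary Gene-level records for the primary tissue
#'   (see [collapse_to_gene()]).
#' @param secondary Gene-level records for the secondary tissue.
#' @param log_base Base of the logarithm (default 10).
#' @param sign_source `"primary"` (default) or `"secondary"`: which tissue's
#'   slope supplies the sign.
#' @return A tibble with columns `gene_id`, `z`; genes missing from the
#'   secondary tissue are excluded and reported in the `dropped_genes`
#'   attribute (they are never imputed a zero prior).
#' @export
build_prior_covariate <- function(primary, secondary,
                                  log_base = 10,
                                  sign_source = c("primary", "secondary")) {
  sign_source <- match.arg(sign_source)
  joined <- inner_join(
    select(primary, "gene_id", beta_primary = "beta_hat"),
    select(secondary, "gene_id", beta_secondary = "beta_hat", p_secondary = "p_value"),
    by = "gene_id"
  )
  dropped <- setdiff(primary$gene_id, joined$gene_id)
  if (length(dropped) > 0) {
    inform(sprintf(
      "build_prior_covariate: %d gene(s) absent from the secondary tissue excluded.",
      length(dropped)
    ))
  }
  s <- if (sign_source == "primary") joined$beta_primary else joined$beta_secondary
  z <- sign(s) * (-log(floor_p(joined$p_secondary)) / log(log_base))
  if (any(!is.finite(z))) abort("Non-finite prior covariate produced.")
  out <- tibble(gene_id = joined$gene_id, z = z)
  attr(out, "dropped_genes") <- dropped
  attr(out, "log_base") <- log_base
  attr(out, "sign_source") <- sign_source
  out
}

#' Fit the second-stage prior model across genes
#'
#' Regresses the primary-tissue slope estimates on the prior covariate across
#' genes: `beta_hat = gamma1 + gamma2 * z + U`, `U ~ N(0, tau2)`, by ordinary
#' least squares. `tau2` is the residual variance SSE/(G-2), floored at 1e-12
#' so the posterior stays proper when the fit is near-perfect. The rescaling
#' weight `c = max|beta_hat| / max|fitted prior mean|` corrects the prior
#' means' systematically smaller scale (`c_mode = "raw"` preserves the
#' signed-maximum reading).
#'
#' @param primary Gene-level records for the primary tissue, or a numeric
#'   vector of slope estimates aligned with `design`.
#' @param design Prior covariate tibble from [build_prior_covariate()].
#' @param c_mode `"abs"` (default) or `"raw"`.
#' @return An object of class `ta_prior_fit` with elements `gamma` (length-2
#'   named vector), `tau2`, `c`, `prior_mean` (tibble `gene_id`, `z`,
#'   `prior_mean`), `n_genes`, and the underlying `lm` fit.
#' @export
fit_prior_model <- function(primary, design, c_mode = c("abs", "raw")) {
  c_mode <- match.arg(c_mode)
  if (is.data.frame(primary)) {
    joined <- inner_join(select(primary, "gene_id", "beta_hat"), design, by = "gene_id")
    beta <- joined$beta_hat
    z <- joined$z
    gene_id <- joined$gene_id
  } else {
    if (length(primary) != nrow(design)) {
      abort("Slope vector and prior design are not aligned.")
    }
    beta <- primary
    z <- design$z
    gene_id <- design$gene_id
  }
  if (length(beta) < 3) abort("At least 3 genes are needed to fit the prior model.")
  if (sd(z) == 0) abort("Uninformative prior design: covariate has zero variance.")
  fit <- lm(beta ~ z)
  gamma <- setNames(coef(fit), c("gamma1", "gamma2"))
  tau2 <- max(sum(resid(fit)^2) / (length(beta) - 2), 1e-12)
  pm <- unname(fitted(fit))
  denom <- if (c_mode == "abs") max(abs(pm)) else max(pm)
  if (denom <= 1e-10 * max(abs(beta), 1)) {
    abort("Degenerate prior model: all fitted prior means are zero.")
  }
  numer <- if (c_mode == "abs") max(abs(beta)) else max(beta)
  structure(
    list(
      gamma = gamma,
      tau2 = tau2,
      c = numer / denom,
      prior_mean = tibble(gene_id = gene_id, z = z, prior_mean = pm),
      n_genes = length(beta),
      c_mode = c_mode,
      lm_fit = fit
    ),
    class = "ta_prior_fit"
  )
}

#' @export
print.ta_prior_fit <- function(x, ...) {
  cat(sprintf(
    "<ta_prior_fit> %d genes | gamma = (%.4g, %.4g) | tau2 = %.4g | c = %.4g\n",
    x$n_genes, x$gamma[1], x$gamma[2], x$tau2, x$c
  ))
  invisible(x)
}

#' Tidy the second-stage prior regression
#'
#' @param x A `ta_prior_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.ta_prior_fit <- function(x, ...) {
  sm <- summary(x$lm_fit)$coefficients
  tibble(
    term = c("gamma1", "gamma2"),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' One-row summary of a prior model fit
#'
#' @param x A `ta_prior_fit`.
#' @param ... Unused.
#' @return A tibble with columns `n_genes`, `tau2`, `c`, `r.squared`.
#' @exportS3Method generics::glance
glance.ta_prior_fit <- function(x, ...) {
  tibble(
    n_genes = x$n_genes,
    tau2 = x$tau2,
    c = x$c,
    r.squared = summary(x$lm_fit)$r.squared
  )
}

#' Compute the weighted conjugate-normal posterior per gene
#'
#' With prior `beta ~ N(ZGamma, tau2)` and first-stage estimate
#' `beta_hat ~ N(beta, sigma2)`, conjugacy gives the closed-form posterior
#' `N(beta_tilde, S)` with `S^-1 = tau2^-1 + sigma2^-1`, shrinkage weight
#' `lambda = tau2 / (tau2 + sigma2)` and weighted posterior mean
#' `beta_tilde = c (1 - lambda) ZGamma + lambda beta_hat` (the rescaling
#' weight `c` is fixed at 1 when `weighted = FALSE`). `lambda -> 1` as the
#' prior becomes uninformative (large `tau2`), recovering the data-only
#' estimate; `lambda -> 0` defers to the prior mean.
#'
#' `sigma_mode` selects what stands in for `sigma2`: the first-stage residual
#' variance (`"residual"`, the default and the literal model) or the squared
#' standard error of the slope (`"beta_se2"`, the sampling-variance reading).
#'
#' @param records Gene-level records for the primary tissue.
#' @param prior A `ta_prior_fit` from [fit_prior_model()].
#' @param weighted Apply the rescaling weight `c` (default TRUE).
#' @param sigma_mode `"residual"` (default) or `"beta_se2"`.
#' @return A tibble with one row per gene present in the prior design:
#'   `gene_id`, `beta_hat`, `sigma2`, `prior_mean`, `lambda`, `beta_tilde`,
#'   `S`, `contour_p`.
#' @export
compute_posterior <- function(records, prior, weighted = TRUE,
                              sigma_mode = c("residual", "beta_se2")) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(inherits(prior, "ta_prior_fit"))
  df <- inner_join(records, prior$prior_mean, by = "gene_id")
  sigma2 <- if (sigma_mode == "residual") df$sigma2_hat else df$se_beta^2
  if (any(sigma2 <= 0) || prior$tau2 <= 0) {
    abort("Non-positive variance: posterior undefined.")
  }
  tau2 <- prior$tau2
  c_eff <- if (weighted) prior$c else 1
  lambda <- tau2 / (tau2 + sigma2)
  S <- 1 / (1 / tau2 + 1 / sigma2)
  beta_tilde <- c_eff * (1 - lambda) * df$prior_mean + lambda * df$beta_hat
  tibble(
    gene_id = df$gene_id,
    beta_hat = df$beta_hat,
    sigma2 = sigma2,
    prior_mean = df$prior_mean,
    lambda = lambda,
    beta_tilde = beta_tilde,
    S = S,
    contour_p = contour_probability(beta_tilde, S)
  )
}

#' Two-sided posterior contour probability
#'
#' Twice the posterior probability mass on the far side of zero from the
#' posterior mean: `2 * pnorm(-|beta_tilde| / sqrt(S))`, capped at 1 — the
#' Bayesian analogue of a two-sided test, used as the ranking score (smaller =
#' stronger local eQTL).
#'
#' @param beta_tilde Posterior mean(s).
#' @param S Posterior variance(s), positive.
#' @return Numeric vector of probabilities in (0, 1].
#' @export
contour_probability <- function(beta_tilde, S) {
  stopifnot(all(S > 0))
  floor_p(pmin(2 * pnorm(-abs(beta_tilde) / sqrt(S)), 1))
}

#' Run the full TA-eQTL stage on two tissues' gene-level records
#'
#' Builds the signed -log P prior covariate from the secondary tissue, fits
#' the second-stage prior regression across genes, and computes the weighted
#' posterior and contour probability per gene. Genes present only in the
#' primary tissue bypass the Bayesian update (no zero-prior imputation): they
#' are passed through with their conventional P-value as score and flagged
#' `has_prior = FALSE`.
#'
#' @param primary,secondary Gene-level record tibbles from
#'   [collapse_to_gene()].
#' @param log_base,sign_source Passed to [build_prior_covariate()].
#' @param c_mode Passed to [fit_prior_model()].
#' @param weighted,sigma_mode Passed to [compute_posterior()].
#' @return A tibble with one row per primary-tissue gene: the posterior
#'   columns of [compute_posterior()] plus `p_value` (conventional), `score`
#'   (contour probability, or conventional P for pass-through genes) and
#'   `has_prior`. The fitted prior model is attached as attribute
#'   `prior_fit`.
#' @export
run_ta_eqtl <- function(primary, secondary,
                        log_base = 10,
                        sign_source = c("primary", "secondary"),
                        c_mode = c("abs", "raw"),
                        weighted = TRUE,
                        sigma_mode = c("residual", "beta_se2")) {
  design <- build_prior_covariate(primary, secondary,
                                  log_base = log_base,
                                  sign_source = match.arg(sign_source))
  prior <- fit_prior_model(primary, design, c_mode = match.arg(c_mode))
  post <- compute_posterior(primary, prior, weighted = weighted,
                            sigma_mode = match.arg(sigma_mode))
  post <- post |>
    left_join(select(primary, "gene_id", "p_value"), by = "gene_id") |>
    mutate(has_prior = TRUE, score = .data$contour_p)
  passthrough <- primary |>
    filter(!(.data$gene_id %in% post$gene_id)) |>
    mutate(has_prior = FALSE, score = .data$p_value) |>
    select("gene_id", "beta_hat", "p_value", "has_prior", "score")
  out <- bind_rows(post, passthrough)
  attr(out, "prior_fit") <- prior
  out
}
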