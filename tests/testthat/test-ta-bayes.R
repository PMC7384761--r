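# Prior covariate, second-stage prior regression, conjugate posterior,
# contour probability, orchestration.

test_that("build_prior_covariate forms the signed -log P covariate", {
  prim <- make_records(c("g1", "g2", "g3"), beta_hat = c(-1, 2, 0.5),
                       p_value = c(0.5, 0.5, 0.5))
  sec <- make_records(c("g1", "g2", "g3"), beta_hat = c(1, 1, 1),
                      p_value = c(0.01, 1, 0.001), tissue = "secondary")
  d <- build_prior_covariate(prim, sec)
  expect_equal(d$z, c(-2, 0, 3))               # sign from primary beta, -log10 p

  d_ln <- build_prior_covariate(prim, sec, log_base = exp(1))
  expect_equal(d_ln$z[3], 6.9078, tolerance = 1e-4)

  d_sec <- build_prior_covariate(prim, sec, sign_source = "secondary")
  expect_equal(d_sec$z, c(2, 0, 3))
})

test_that("genes absent from the secondary tissue are excluded, not zeroed", {
  prim <- make_records(c("g1", "g2"), beta_hat = c(1, 1), p_value = c(0.5, 0.5))
  sec <- make_records("g1", beta_hat = 1, p_value = 0.1, tissue = "secondary")
  expect_message(d <- build_prior_covariate(prim, sec), "1 gene")
  expect_equal(d$gene_id, "g1")
  expect_equal(attr(d, "dropped_genes"), "g2")
})

test_that("fit_prior_model: identity regression, floors, and failure modes", {
  z <- c(-2, -1, 0, 1, 2, 3)
  d <- tibble::tibble(gene_id = paste0("g", 1:6), z = z)
  fit <- fit_prior_model(z, d)       # beta == z exactly
  expect_equal(unname(fit$gamma), c(0, 1), tolerance = 1e-10)
  expect_equal(fit$tau2, 1e-12)      # near-perfect fit hits the floor
  expect_equal(fit$c, 1, tolerance = 1e-10)

  expect_error(fit_prior_model(z, dplyr::mutate(d, z = 1)), "Uninformative")
  # beta orthogonal to z with zero mean -> all fitted prior means zero
  d2 <- tibble::tibble(gene_id = paste0("g", 1:4), z = c(1, 1, -1, -1))
  expect_error(fit_prior_model(c(-1, 1, -1, 1), d2), "Degenerate")
  expect_error(fit_prior_model(c(1, 2), d[1:2, ]), "At least 3")
})

test_that("c rescales by the absolute-maximum ratio; raw mode preserves signs", {
  withr::with_seed(4, {
    z <- rnorm(50)
    beta <- -0.5 * z + rnorm(50, sd = 0.1)
  })
  d <- tibble::tibble(gene_id = paste0("g", 1:50), z = z)
  fit <- fit_prior_model(beta, d)
  expect_equal(fit$c, max(abs(beta)) / max(abs(fitted(fit$lm_fit))), tolerance = 1e-12)
  fit_raw <- fit_prior_model(beta, d, c_mode = "raw")
  expect_equal(fit_raw$c, max(beta) / max(fitted(fit_raw$lm_fit)), tolerance = 1e-12)
})

test_that("tidy() and glance() summarise the prior regression", {
  withr::with_seed(8, {
    z <- rnorm(100)
    beta <- 1 + 2 * z + rnorm(100, sd = 0.5)
  })
  d <- tibble::tibble(gene_id = paste0("g", 1:100), z = z)
  fit <- fit_prior_model(beta, d)
  td <- tidy(fit)
  expect_equal(td$term, c("gamma1", "gamma2"))
  expect_equal(td$estimate, unname(coef(fit$lm_fit)))
  gl <- glance(fit)
  expect_named(gl, c("n_genes", "tau2", "c", "r.squared"))
  expect_equal(gl$n_genes, 100)
})

test_that("compute_posterior matches the worked conjugate example", {
  recs <- make_records("g1", beta_hat = 2, p_value = 0.05, sigma2_hat = 0.5)
  prior <- manual_prior("g1", prior_mean = 1, tau2 = 0.5, c = 1)
  post <- compute_posterior(recs, prior)
  expect_equal(post$lambda, 0.5)
  expect_equal(post$beta_tilde, 1.5)
  expect_equal(post$S, 0.25)
  expect_equal(post$contour_p, 2 * pnorm(-1.5 / 0.5), tolerance = 1e-12)
})

test_that("shrinkage limits recover the data-only and prior-only estimates", {
  recs <- make_records("g1", beta_hat = 2, p_value = 0.05, sigma2_hat = 0.5)
  flat <- compute_posterior(recs, manual_prior("g1", 1, tau2 = 1e12, c = 3))
  expect_equal(flat$beta_tilde, 2, tolerance = 1e-6)
  expect_equal(flat$lambda, 1, tolerance = 1e-6)

  tight <- compute_posterior(recs, manual_prior("g1", 1, tau2 = 1e-12, c = 3))
  expect_equal(tight$beta_tilde, 3 * 1, tolerance = 1e-6)   # c * prior mean
  expect_equal(tight$lambda, 0, tolerance = 1e-6)
})

test_that("posterior identities and monotonicities hold on grids", {
  tau2_grid <- 10^seq(-3, 3, length.out = 13)
  sigma2_grid <- 10^seq(-2, 2, length.out = 9)
  for (s2 in sigma2_grid) {
    lam <- tau2_grid / (tau2_grid + s2)
    recs <- make_records("g1", beta_hat = 1.7, p_value = 0.1, sigma2_hat = s2)
    post <- purrr::map_dfr(tau2_grid, function(t2) {
      compute_posterior(recs, manual_prior("g1", 0.4, tau2 = t2, c = 1.2))
    })
    expect_equal(1 / post$S, 1 / tau2_grid + 1 / s2, tolerance = 1e-10)
    expect_true(all(diff(post$lambda) > 0))      # increasing in tau2
    expect_true(all(post$lambda >= 0 & post$lambda <= 1))
    lo <- pmin(1.2 * 0.4, 1.7); hi <- pmax(1.2 * 0.4, 1.7)
    expect_true(all(post$beta_tilde >= lo - 1e-12 & post$beta_tilde <= hi + 1e-12))
  }
  # lambda decreasing in sigma2 at fixed tau2
  recs <- make_records(sprintf("g%02d", seq_along(sigma2_grid)),
                       beta_hat = 1, p_value = 0.1, sigma2_hat = sigma2_grid)
  post <- compute_posterior(recs, manual_prior(recs$gene_id, 0, tau2 = 0.5))
  expect_true(all(diff(post$lambda[order(sigma2_grid)]) < 0))
})

test_that("contour_probability is the two-sided posterior tail", {
  expect_equal(contour_probability(0, 1), 1)
  expect_equal(contour_probability(3 * sqrt(0.5), 0.5), 0.0027, tolerance = 1e-4)
  expect_equal(contour_probability(1.5, 0.25), 0.0027, tolerance = 1e-4)
  # monotone decreasing in |beta_tilde|/sqrt(S)
  b <- seq(0, 5, by = 0.25)
  expect_true(all(diff(contour_probability(b, 1)) < 0))
  expect_equal(contour_probability(-2, 1), contour_probability(2, 1))
})

test_that("run_ta_eqtl produces one valid record per gene with pass-through", {
  sim <- simulate_panel(sim_config(n_strains = 15, n_genes = 50,
                                   fraction_platform_specific = 0.2, seed = 31))
  out <- run_pipeline(sim)
  ta <- out$ta
  expect_equal(nrow(ta), nrow(out$primary))
  with_prior <- ta[ta$has_prior, ]
  expect_true(all(with_prior$lambda >= 0 & with_prior$lambda <= 1))
  expect_true(all(with_prior$contour_p > 0 & with_prior$contour_p <= 1))
  prior <- attr(ta, "prior_fit")
  expect_equal(1 / with_prior$S, 1 / prior$tau2 + 1 / with_prior$sigma2,
               tolerance = 1e-10)
  # platform-specific genes bypass the update and keep their conventional P
  pass <- ta[!ta$has_prior, ]
  expect_gt(nrow(pass), 0)
  expect_equal(pass$score,
               out$primary$p_value[match(pass$gene_id, out$primary$gene_id)])
})

test_that("unweighted mode reproduces the c = 1 posterior exactly", {
  sim <- simulate_panel(sim_config(n_strains = 15, n_genes = 40, seed = 33))
  out <- run_pipeline(sim, weighted = FALSE)
  prior <- attr(out$ta, "prior_fit")
  manual <- compute_posterior(out$primary, prior, weighted = FALSE)
  ref <- (1 - manual$lambda) * manual$prior_mean + manual$lambda * manual$beta_hat
  expect_equal(manual$beta_tilde, ref, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(prior$c, 1)))   # c ignored, not equal to 1
})

test_that("an uninformative prior leaves the conventional ranking intact", {
  withr::with_seed(41, {
    G <- 300
    beta <- rnorm(G); se <- runif(G, 0.2, 0.5)
    recs <- make_records(sprintf("g%03d", 1:G), beta_hat = beta,
                         p_value = runif(G), sigma2_hat = se^2 * 25,
                         se_beta = se)
  })
  # tau2 huge relative to sigma2: posterior ranking ~ data-only ranking
  prior <- manual_prior(recs$gene_id, prior_mean = rnorm(300),
                        tau2 = max(recs$sigma2_hat) * 1e6, c = 2)
  post <- compute_posterior(recs, prior)
  conv_rank <- rank(-abs(recs$beta_hat / sqrt(recs$sigma2_hat)))
  expect_gt(cor(rank(post$contour_p), conv_rank, method = "spearman"), 0.99)
})

test_that("a secondary tissue duplicating the primary concentrates the ranking", {
  sim <- simulate_panel(sim_config(n_strains = 20, n_genes = 150, seed = 37))
  out <- run_pipeline(sim)
  suppressMessages({
    a1 <- align_strains(sim$genotypes, sim$primary)
    r1 <- collapse_to_gene(scan_tissue(a1$expr, a1$genotypes))
    copy <- r1; copy$tissue <- "copy"
    ta_copy <- run_ta_eqtl(r1, copy)
  })
  cor_copy <- cor(rank(ta_copy$score), rank(r1$p_value), method = "spearman")
  cor_indep <- cor(rank(out$ta$score[match(r1$gene_id, out$ta$gene_id)]),
                   rank(r1$p_value), method = "spearman")
  expect_gte(cor_copy, cor_indep)
})
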