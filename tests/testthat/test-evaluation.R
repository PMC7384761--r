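# ROC/AUC, bootstrap, DeLong, overlap enrichment, geometric mean, sub-sampling.

test_that("roc_auc handles the canonical cases", {
  perfect <- roc_auc(c(0.01, 0.02, 0.9, 0.95), c(TRUE, TRUE, FALSE, FALSE),
                     n_boot = 0)
  expect_equal(perfect$auc, 1)

  flat <- roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5), n_boot = 0)
  expect_equal(flat$auc, 0.5)

  mixed <- roc_auc(c(0.01, 0.40, 0.20, 0.80), c(TRUE, TRUE, FALSE, FALSE),
                   n_boot = 0)
  expect_equal(mixed$auc, 0.75)    # 3 of 4 concordant positive-negative pairs

  expect_error(roc_auc(1:4 / 10, rep(TRUE, 4), n_boot = 0), "at least one")
})

test_that("the ROC curve is monotone and the bootstrap CI brackets the AUC", {
  withr::with_seed(19, {
    lab <- rep(c(TRUE, FALSE), c(60, 140))
    sc <- ifelse(lab, rbeta(200, 1, 6), runif(200))
  })
  roc <- roc_auc(sc, lab, n_boot = 300, seed = 5)
  expect_true(all(diff(roc$curve$sensitivity) >= 0))
  expect_true(all(diff(1 - roc$curve$specificity) >= 0))
  expect_lte(roc$ci_low, roc$auc)
  expect_gte(roc$ci_high, roc$auc)
  # deterministic under a fixed seed
  roc2 <- roc_auc(sc, lab, n_boot = 300, seed = 5)
  expect_equal(roc2$ci_low, roc$ci_low)
  expect_equal(glance(roc)$auc, roc$auc)
})

test_that("widening the bootstrap barely moves the interval on a 500-gene fixture", {
  withr::with_seed(23, {
    lab <- rep(c(TRUE, FALSE), c(100, 400))
    sc <- ifelse(lab, rbeta(500, 1, 4), runif(500))
  })
  small <- roc_auc(sc, lab, n_boot = 200, seed = 7)
  big <- roc_auc(sc, lab, n_boot = 2000, seed = 7)
  expect_lt(abs(small$ci_low - big$ci_low), 0.02)
  expect_lt(abs(small$ci_high - big$ci_high), 0.02)
})

test_that("roc_auc reports gold-standard overlap for tibble input", {
  scores <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                           score = c(0.01, 0.02, 0.5, 0.6, 0.7, 0.8))
  expect_message(
    roc <- roc_auc(scores, c("g1", "g2", "g99"), n_boot = 0),
    "2 of 3 gold-standard"
  )
  expect_equal(roc$n_pos, 2)
})

test_that("delong_test identity, symmetry, and a decisive separation", {
  withr::with_seed(27, {
    lab <- rep(c(TRUE, FALSE), each = 40)
    a <- ifelse(lab, runif(80, 0, 0.4), runif(80, 0.6, 1))  # perfect
    b <- runif(80)                                          # useless
  })
  expect_warning(same <- delong_test(a, a, lab), "zero-variance")
  expect_equal(same$p.value, 1)

  dt <- delong_test(a, b, lab)
  expect_equal(unname(dt$estimate["auc_a"]), 1)
  expect_lt(dt$p.value, 0.01)
  dt_swap <- delong_test(b, a, lab)
  expect_equal(dt_swap$p.value, dt$p.value, tolerance = 1e-12)
})

test_that("overlap_analysis applies the independence product rule", {
  withr::with_seed(3, {
    p1 <- runif(100); p2 <- runif(100)
  })
  # engineer: 20 significant in t1, 30 in t2, 12 shared, at threshold 0.05
  p1[] <- 0.5; p2[] <- 0.5
  p1[1:20] <- 0.01
  p2[c(1:12, 21:38)] <- 0.01
  t1 <- make_records(sprintf("g%03d", 1:100), beta_hat = 1, p_value = p1)
  t2 <- make_records(sprintf("g%03d", 1:100), beta_hat = 1, p_value = p2,
                     tissue = "secondary")
  out <- overlap_analysis(t1, t2, thresholds = 0.05)
  expect_equal(out$n_sig_t1, 20)
  expect_equal(out$n_sig_t2, 30)
  expect_equal(out$expected_shared, 6)
  expect_equal(out$observed_shared, 12)
  expect_equal(out$ratio, 2)
  expect_lt(out$p_enrichment, 0.05)

  # empty significant set in one tissue: ratio undefined, reported missing
  t2_null <- make_records(sprintf("g%03d", 1:100), beta_hat = 1, p_value = 0.9,
                          tissue = "secondary")
  out2 <- overlap_analysis(t1, t2_null, thresholds = 0.05)
  expect_true(is.na(out2$ratio))
  expect_equal(out2$expected_shared, 0)

  expect_error(overlap_analysis(t1[0, ], t2[0, ]), "Empty shared")
})

test_that("geometric_mean is exact, order-invariant, and guards degenerate input", {
  expect_equal(geometric_mean(c(0.2, 0.2, 0.2)), 0.2, tolerance = 1e-12)
  expect_equal(geometric_mean(c(0.01, 1)), 0.1, tolerance = 1e-12)
  expect_equal(geometric_mean(c(0.3, 0.01, 0.9)),
               geometric_mean(c(0.9, 0.3, 0.01)), tolerance = 1e-15)
  expect_equal(geometric_mean(c(0, 1)), 1e-150, tolerance = 1e-10)
  expect_error(geometric_mean(numeric(0)), "empty")
})

test_that("subsample_protocol: identity cases and determinism", {
  sim <- simulate_panel(sim_config(n_strains = 12, n_genes = 40, seed = 43))
  suppressMessages({
    a2 <- align_strains(sim$genotypes, sim$secondary)
    sec <- collapse_to_gene(scan_tissue(a2$expr, a2$genotypes))
  })
  # full-size "subsample" with one replicate reproduces the full-data run
  full <- suppressMessages(
    subsample_protocol(sim$primary, sim$genotypes, sec, sizes = 12, n_reps = 1,
                       seed = 9)
  )
  out <- run_pipeline(sim)
  conv <- dplyr::filter(full, method == "conventional")
  expect_equal(conv$score[match(out$primary$gene_id, conv$gene_id)],
               out$primary$p_value, tolerance = 1e-12)
  ta <- dplyr::filter(full, method == "ta_eqtl")
  expect_equal(ta$score[match(out$ta$gene_id, ta$gene_id)], out$ta$score,
               tolerance = 1e-12)

  # reruns with the same master seed are identical; different seeds differ
  s1 <- suppressMessages(subsample_protocol(sim$primary, sim$genotypes, sec,
                                            sizes = 8, n_reps = 2, seed = 5))
  s2 <- suppressMessages(subsample_protocol(sim$primary, sim$genotypes, sec,
                                            sizes = 8, n_reps = 2, seed = 5))
  s3 <- suppressMessages(subsample_protocol(sim$primary, sim$genotypes, sec,
                                            sizes = 8, n_reps = 2, seed = 6))
  expect_equal(s1, s2, ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(s1$score, s3$score)))

  expect_error(
    suppressMessages(subsample_protocol(sim$primary, sim$genotypes, sec,
                                        sizes = 3, n_reps = 1)),
    "minimum informative"
  )
  expect_error(
    suppressMessages(subsample_protocol(sim$primary, sim$genotypes, sec,
                                        sizes = 50, n_reps = 1)),
    "exceeds"
  )
})

test_that("replicate scores aggregate by geometric mean per gene and method", {
  sim <- simulate_panel(sim_config(n_strains = 14, n_genes = 30, seed = 47))
  suppressMessages({
    a2 <- align_strains(sim$genotypes, sim$secondary)
    sec <- collapse_to_gene(scan_tissue(a2$expr, a2$genotypes))
  })
  agg <- suppressMessages(
    subsample_protocol(sim$primary, sim$genotypes, sec, sizes = 10, n_reps = 3,
                       seed = 11)
  )
  reps <- attr(agg, "replicates")
  one <- dplyr::filter(reps, method == "meta", gene_id == reps$gene_id[1])
  ref <- geometric_mean(one$score)
  got <- dplyr::filter(agg, method == "meta", gene_id == reps$gene_id[1])$score
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("autoplot and the summary plots return ggplot objects", {
  roc <- roc_auc(c(0.1, 0.2, 0.6, 0.9), c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)
  expect_s3_class(autoplot(roc), "ggplot")
  ov <- tibble::tibble(threshold = c(0.05, 0.01), ratio = c(1.7, 3.2))
  expect_s3_class(plot_overlap_ratio(ov), "ggplot")
  au <- tibble::tibble(method = c("a", "b"), size = 10, auc = c(0.7, 0.8))
  expect_s3_class(plot_auc_by_size(au), "ggplot")
})
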