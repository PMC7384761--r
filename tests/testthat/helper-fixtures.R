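# Shared fixture builders: all panels are constructed in code, no stored data.

# Small genotype panel: n strains x SNPs at given positions on one chromosome.
make_geno <- function(calls, pos_bp, chrom = "chr1", strains = NULL,
                      snp_ids = NULL) {
  calls <- as.matrix(calls)
  strains <- strains %||% sprintf("S%02d", seq_len(nrow(calls)))
  snp_ids <- snp_ids %||% sprintf("snp%02d", seq_len(ncol(calls)))
  rownames(calls) <- strains
  colnames(calls) <- snp_ids
  genotype_panel(calls, tibble::tibble(
    snp_id = snp_ids,
    chrom = rep_len(chrom, ncol(calls)),
    pos_bp = pos_bp
  ))
}

# Expression panel with one probeset per gene unless probeset ids repeat genes.
make_expr <- function(values, gene_ids, tss_bp, chrom = "chr1",
                      strand = "+", tissue = "primary",
                      probeset_ids = NULL, strains = NULL) {
  values <- as.matrix(values)
  strains <- strains %||% sprintf("S%02d", seq_len(ncol(values)))
  probeset_ids <- probeset_ids %||% paste0(gene_ids, "_at")
  rownames(values) <- probeset_ids
  colnames(values) <- strains
  expression_panel(values, tibble::tibble(
    probeset_id = probeset_ids,
    gene_id = gene_ids,
    chrom = rep_len(chrom, length(gene_ids)),
    start_bp = tss_bp,
    end_bp = tss_bp + 5e4,
    strand = rep_len(strand, length(gene_ids))
  ), tissue)
}

# Gene-level eQTL record tibble with sensible defaults.
make_records <- function(gene_id, beta_hat, p_value,
                         sigma2_hat = 1, se_beta = sqrt(sigma2_hat) / 2,
                         tissue = "primary") {
  n <- length(gene_id)
  tibble::tibble(
    gene_id = gene_id,
    tissue = tissue,
    snp_id = paste0(gene_id, "_snp"),
    probeset_id = paste0(gene_id, "_at"),
    chrom = "chr1",
    pos_bp = seq_len(n) * 1e6,
    beta_hat = beta_hat,
    alpha_hat = 0,
    sigma2_hat = rep_len(sigma2_hat, n),
    se_beta = rep_len(se_beta, n),
    p_value = p_value,
    n_used = 30
  )
}

# Hand-assembled prior fit for posterior unit tests.
manual_prior <- function(gene_id, prior_mean, tau2, c = 1) {
  structure(
    list(
      gamma = c(gamma1 = NA_real_, gamma2 = NA_real_),
      tau2 = tau2, c = c,
      prior_mean = tibble::tibble(gene_id = gene_id, z = NA_real_,
                                  prior_mean = prior_mean),
      n_genes = length(gene_id), c_mode = "abs", lm_fit = NULL
    ),
    class = "ta_prior_fit"
  )
}

# Conventional gene-level records for a simulated panel, plus TA and meta runs.
run_pipeline <- function(sim, window_bp = 1e6, ...) {
  suppressMessages({
    a1 <- align_strains(sim$genotypes, sim$primary)
    a2 <- align_strains(sim$genotypes, sim$secondary)
    r1 <- collapse_to_gene(scan_tissue(a1$expr, a1$genotypes, window_bp = window_bp))
    r2 <- collapse_to_gene(scan_tissue(a2$expr, a2$genotypes, window_bp = window_bp))
    ta <- run_ta_eqtl(r1, r2, ...)
    list(primary = r1, secondary = r2, ta = ta)
  })
}

auc_of <- function(gene_id, score, gold) {
  suppressMessages(
    roc_auc(tibble::tibble(gene_id = gene_id, score = score), gold, n_boot = 0)$auc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
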