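# Recombinant-inbred-style two-tissue simulator with known truth, emulating a
# BXD-like panel: binary strain genotypes with local LD blocks, strain-mean
# log2 expression normalized to mean 8 / SD 2 per gene, and a positive gene
# set standing in for the ASE gold standard.

#' Configuration for the two-tissue RI panel simulator
#'
#' Defaults describe the emulated study: a 30-strain panel (the size of the
#' primary liver data set), 2000 genes with a 5-SNP local LD block each,
#' 30% of genes carrying a real primary-tissue cis effect of which 70% are
#' shared with the secondary tissue, unit effect-size and residual SDs on the
#' raw scale. Genes are spaced 3 Mb apart along the chromosomes so 1 Mb cis
#' windows do not bleed into neighbouring genes.
#'
#' @param n_strains Number of strains (>= 10).
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param snps_per_gene_region SNPs in each gene's local LD block.
#' @param fraction_true_primary Share of genes with a real primary-tissue
#'   cis effect.
#' @param fraction_shared Share of true effects also present in the secondary
#'   tissue (same magnitude, independent sign — directionality does not
#'   transfer across tissues).
#' @param effect_size_sd SD of true raw-scale effect sizes.
#' @param noise_sd Residual SD on the raw scale.
#' @param maf_range Admissible per-SNP minor-allele-frequency band.
#' @param fraction_platform_specific Share of genes present only on the
#'   primary tissue's platform (absent from the secondary panel).
#' @param seed Simulation seed; all randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 30, n_genes = 2000, n_chromosomes = 19,
                       snps_per_gene_region = 5,
                       fraction_true_primary = 0.3, fraction_shared = 0.7,
                       effect_size_sd = 1, noise_sd = 1,
                       maf_range = c(0.1, 0.9),
                       fraction_platform_specific = 0,
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains), n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_gene_region = as.integer(snps_per_gene_region),
    fraction_true_primary = fraction_true_primary,
    fraction_shared = fraction_shared,
    effect_size_sd = effect_size_sd, noise_sd = noise_sd,
    maf_range = maf_range,
    fraction_platform_specific = fraction_platform_specific,
    seed = as.integer(seed)
  )
  if (cfg$n_strains < 10) abort("n_strains must be at least 10.")
  if (cfg$n_genes < 1 || cfg$n_chromosomes < 1 || cfg$snps_per_gene_region < 1) {
    abort("Gene, chromosome and SNP counts must be positive.")
  }
  fr <- c(cfg$fraction_true_primary, cfg$fraction_shared,
          cfg$fraction_platform_specific)
  if (any(fr < 0 | fr > 1)) abort("Fractions must lie in [0, 1].")
  if (cfg$effect_size_sd <= 0 || cfg$noise_sd <= 0) abort("SDs must be positive.")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] >= cfg$maf_range[2]) {
    abort("maf_range must be an increasing pair.")
  }
  structure(cfg, class = "sim_config")
}

# Two-state Markov chain along each chromosome per strain: small switch
# probability inside a gene's LD block, near-independence between blocks.
# A declared simplification of RI descent sufficient for cis-window structure.
simulate_genotypes <- function(cfg, gene_map) {
  n <- cfg$n_strains
  strains <- sprintf("BXD%03d", seq_len(n))
  blocks <- split(seq_len(nrow(gene_map$snps)), gene_map$snps$chrom)
  calls <- matrix(NA_real_, n, nrow(gene_map$snps),
                  dimnames = list(strains, gene_map$snps$snp_id))
  for (chr in names(blocks)) {
    ix <- blocks[[chr]]
    new_block <- c(TRUE, diff(gene_map$snps$block[ix]) != 0)
    state <- rbinom(n, 1, 0.5)
    for (j in seq_along(ix)) {
      r <- if (new_block[j] && j > 1) 0.45 else if (j > 1) 0.02 else 0
      if (r > 0) state <- abs(state - rbinom(n, 1, r))
      calls[, ix[j]] <- state
    }
  }
  # keep every SNP's allele frequency inside the admissible band by flipping
  # the minimum number of randomly chosen strains on violating SNPs
  af <- colMeans(calls)
  for (j in which(af < cfg$maf_range[1] | af > cfg$maf_range[2])) {
    major <- as.numeric(af[j] > 0.5)
    need <- ceiling((abs(af[j] - 0.5) - (0.5 - cfg$maf_range[1])) * n)
    flip <- sample(which(calls[, j] == major), max(need, 1))
    calls[flip, j] <- 1 - major
  }
  genotype_panel(calls, select(gene_map$snps, "snp_id", "chrom", "pos_bp"))
}

simulate_tissue <- function(cfg, geno, gene_map, beta_raw, tissue) {
  n <- cfg$n_strains
  genes <- gene_map$genes
  vals <- matrix(NA_real_, nrow(genes), n,
                 dimnames = list(genes$probeset_id, rownames(geno$calls)))
  beta_emit <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    x <- geno$calls[, genes$causal_snp[i]]
    y <- beta_raw[i] * x + rnorm(n, sd = cfg$noise_sd)
    s <- sd(y)
    scale <- 2 / s
    vals[i, ] <- 8 + (y - mean(y)) * scale
    beta_emit[i] <- beta_raw[i] * scale
  }
  ann <- tibble(
    probeset_id = genes$probeset_id, gene_id = genes$gene_id,
    chrom = genes$chrom, start_bp = genes$tss_bp,
    end_bp = genes$tss_bp + 5e4, strand = "+"
  )
  list(panel = expression_panel(vals, ann, tissue), beta_emit = beta_emit)
}

#' Simulate a two-tissue recombinant-inbred panel with known truth
#'
#' Generates a genotype panel (binary RI-style calls with local LD blocks per
#' gene region), two expression panels whose per-gene cis effects are
#' partially shared, and the truth table. For each gene, expression is
#' `y = beta * x_causal + noise` on the raw scale, then affine-rescaled per
#' gene to mean 8 / SD 2 (the strain-mean log2 convention); the truth records
#' effect sizes on the emitted (rescaled) scale. Shared genes reuse the
#' primary effect magnitude in the secondary tissue with an independently
#' random sign. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `ta_sim`: `genotypes` ([genotype_panel()]),
#'   `primary` and `secondary` ([expression_panel()]s), and `truth`, a tibble
#'   with `gene_id`, `causal_snp`, `beta_primary`, `beta_secondary`,
#'   `is_positive` (nonzero true primary effect), plus the `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    cfg <- config
    G <- cfg$n_genes
    m <- cfg$snps_per_gene_region
    chrom_of <- rep(seq_len(cfg$n_chromosomes), length.out = G)
    genes <- tibble(
      gene_id = sprintf("gene%05d", seq_len(G)),
      probeset_id = sprintf("gene%05d_at", seq_len(G)),
      chrom = sprintf("chr%d", chrom_of)
    ) |>
      group_by(.data$chrom) |>
      mutate(tss_bp = 3e6 * dplyr::row_number()) |>
      ungroup()
    offsets <- (seq_len(m) - (m + 1) / 2) * 5e4
    snps <- genes |>
      select("gene_id", "chrom", "tss_bp") |>
      mutate(block = dplyr::row_number()) |>
      tidyr::crossing(offset = offsets) |>
      mutate(
        pos_bp = .data$tss_bp + .data$offset,
        snp_id = sprintf("%s_snp%d", .data$gene_id,
                         match(.data$offset, offsets))
      ) |>
      arrange(.data$chrom, .data$pos_bp)
    gene_map <- list(genes = genes, snps = snps)
    geno <- simulate_genotypes(cfg, gene_map)

    causal_idx <- ceiling(m / 2)
    genes$causal_snp <- sprintf("%s_snp%d", genes$gene_id, causal_idx)
    gene_map$genes <- genes

    n_true <- round(cfg$fraction_true_primary * G)
    true_genes <- sample(seq_len(G), n_true)
    beta_primary_raw <- numeric(G)
    beta_primary_raw[true_genes] <- rnorm(n_true, sd = cfg$effect_size_sd)
    n_shared <- round(cfg$fraction_shared * n_true)
    shared_genes <- if (n_shared > 0) sample(true_genes, n_shared) else integer(0)
    beta_secondary_raw <- numeric(G)
    beta_secondary_raw[shared_genes] <-
      abs(beta_primary_raw[shared_genes]) * sample(c(-1, 1), n_shared, replace = TRUE)

    prim <- simulate_tissue(cfg, geno, gene_map, beta_primary_raw, "primary")
    sec <- simulate_tissue(cfg, geno, gene_map, beta_secondary_raw, "secondary")

    sec_panel <- sec$panel
    n_drop <- round(cfg$fraction_platform_specific * G)
    if (n_drop > 0) {
      drop <- sample(seq_len(G), n_drop)
      keep <- setdiff(seq_len(G), drop)
      sec_panel <- expression_panel(
        sec_panel$values[keep, , drop = FALSE],
        sec_panel$annotation[keep, ], "secondary"
      )
    }

    truth <- tibble(
      gene_id = genes$gene_id,
      causal_snp = ifelse(beta_primary_raw != 0 | beta_secondary_raw != 0,
                          genes$causal_snp, NA_character_),
      beta_primary = ifelse(beta_primary_raw != 0, prim$beta_emit, 0),
      beta_secondary = ifelse(beta_secondary_raw != 0, sec$beta_emit, 0),
      is_positive = beta_primary_raw != 0
    )
    structure(
      list(genotypes = geno, primary = prim$panel, secondary = sec_panel,
           truth = truth, config = cfg),
      class = "ta_sim"
    )
  })
}

#' @export
print.ta_sim <- function(x, ...) {
  cat(sprintf(
    "<ta_sim> %d strains, %d genes (%d positive), %d SNPs; seed %d\n",
    x$config$n_strains, x$config$n_genes, sum(x$truth$is_positive),
    ncol(x$genotypes$calls), x$config$seed
  ))
  invisible(x)
}

#' Write a simulated panel set as on-disk fixtures
#'
#' Emits the genotype (.geno dialect), expression, annotation, gold-standard
#' and truth files in exactly the formats the readers consume, so a write /
#' read round trip is lossless.
#'
#' @param sim A `ta_sim` from [simulate_panel()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ta_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create directory '%s'.", out_dir))
  paths <- c(
    geno = file.path(out_dir, "panel.geno"),
    primary_expr = file.path(out_dir, "primary_expression.tsv"),
    primary_annot = file.path(out_dir, "primary_annotation.tsv"),
    secondary_expr = file.path(out_dir, "secondary_expression.tsv"),
    secondary_annot = file.path(out_dir, "secondary_annotation.tsv"),
    gold = file.path(out_dir, "gold_standard.txt"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_geno_file(sim$genotypes, paths["geno"])
  write_expression_table(sim$primary, paths["primary_expr"], paths["primary_annot"])
  write_expression_table(sim$secondary, paths["secondary_expr"], paths["secondary_annot"])
  writeLines(sim$truth$gene_id[sim$truth$is_positive], paths["gold"])
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
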