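# Conventional per-tissue local-eQTL scan: cis-SNP enumeration, marginal OLS
# per probeset-SNP pair, gene-level minimum-P collapse.

# Closed-form single-regressor least squares. Returns NULL as the "skip"
# signal (monomorphic genotype after pairwise-complete filtering, or fewer
# than `min_n` informative strains). A perfectly constant response is NOT a
# skip: it yields slope 0, P = 1 (guarded division).
ols_pair <- function(y, x, min_n = 5L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) return(NULL)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NULL)                       # monomorphic
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  beta <- sxy / sxx
  alpha <- my - beta * mx
  sse <- max(syy - beta * sxy, 0)
  sigma2 <- sse / (n - 2)
  if (sigma2 > 0) {
    se <- sqrt(sigma2 / sxx)
    t_stat <- beta / se
    p <- floor_p(2 * pt(-abs(t_stat), df = n - 2))
  } else if (beta == 0) {                          # constant y
    se <- 0; t_stat <- 0; p <- 1
  } else {                                         # perfect non-trivial fit
    se <- 0; t_stat <- sign(beta) * Inf; p <- P_FLOOR
  }
  list(beta_hat = beta, alpha_hat = alpha, sigma2_hat = sigma2,
       se_beta = se, t_stat = t_stat, p_value = p, n_used = n)
}

#' Fit the marginal single-SNP linear model for one probeset-SNP pair
#'
#' Ordinary least squares of strain-mean expression on the 0/1 genotype, the
#' basic per-tissue local-eQTL model. Strains missing either value are dropped
#' pairwise; the slope is tested two-sided against zero with a t distribution
#' on `n_used - 2` degrees of freedom. The residual variance estimate is
#' SSE/(n-2).
#'
#' @param y Numeric expression vector.
#' @param x Numeric 0/1 genotype vector, same length.
#' @param min_n Minimum informative strain count (default 5); below this, or
#'   when the genotype is monomorphic after filtering, the pair is skipped.
#' @return A one-row tibble with columns `beta_hat`, `alpha_hat`,
#'   `sigma2_hat`, `se_beta`, `t_stat`, `p_value`, `n_used`, or `NULL` (with a
#'   message) when the pair is skipped.
#' @export
fit_marginal <- function(y, x, min_n = 5L) {
  stopifnot(length(x) == length(y))
  fit <- ols_pair(y, x, min_n = min_n)
  if (is.null(fit)) {
    inform("fit_marginal: pair skipped (monomorphic genotype or too few strains).")
    return(NULL)
  }
  as_tibble(fit)
}

#' Enumerate the cis SNPs of a gene
#'
#' SNPs on the gene's chromosome whose position falls in the closed interval
#' `[TSS - window_bp, TSS + window_bp]`. The TSS is strand-aware when strand
#' annotation is available: gene start for `+`, gene end for `-`.
#'
#' @param gene_id Gene id to look up in the panel's annotation.
#' @param expr An [expression_panel()] carrying the gene's annotation.
#' @param genotypes A [genotype_panel()].
#' @param window_bp Half-width of the cis window in base pairs (default 1 Mb).
#' @return Character vector of SNP ids (possibly empty).
#' @export
find_local_snps <- function(gene_id, expr, genotypes, window_bp = 1e6) {
  stopifnot(window_bp > 0)
  tss <- gene_tss(expr$annotation)
  row <- tss[tss$gene_id == gene_id, ]
  if (nrow(row) == 0) abort(sprintf("Gene '%s' is not annotated in this panel.", gene_id))
  si <- genotypes$snp_info
  hit <- si$chrom == row$chrom &
    si$pos_bp >= row$tss_bp - window_bp &
    si$pos_bp <= row$tss_bp + window_bp
  si$snp_id[hit]
}

#' Scan one tissue for local eQTL
#'
#' Fits the marginal model for every probeset x cis-SNP pair and returns the
#' per-pair statistics. Pairs skipped (monomorphic genotype, too few
#' informative strains) are counted in the `n_skipped` attribute and a
#' message. Panels must be strain-aligned (see [align_strains()]).
#'
#' @param expr An [expression_panel()].
#' @param genotypes A [genotype_panel()] with rows matching `expr` columns.
#' @param window_bp Half-width of the cis window in base pairs.
#' @param min_n Minimum informative strain count per pair.
#' @return A tibble with one row per tested pair: `gene_id`, `probeset_id`,
#'   `snp_id`, `chrom`, `pos_bp`, `beta_hat`, `alpha_hat`, `sigma2_hat`,
#'   `se_beta`, `t_stat`, `p_value`, `n_used`; attribute `n_skipped`.
#' @export
scan_tissue <- function(expr, genotypes, window_bp = 1e6, min_n = 5L) {
  stopifnot(inherits(expr, "expression_panel"), inherits(genotypes, "genotype_panel"))
  if (!identical(colnames(expr$values), rownames(genotypes$calls))) {
    abort("Panels are not strain-aligned; call align_strains() first.")
  }
  tss <- gene_tss(expr$annotation)
  ann <- left_join(expr$annotation, tss, by = "gene_id", suffix = c("", ".tss"))
  si <- genotypes$snp_info
  # per-chromosome sorted position index for fast interval lookup
  chr_index <- split(seq_len(nrow(si)), si$chrom)
  chr_index <- lapply(chr_index, function(ix) ix[order(si$pos_bp[ix])])

  out <- vector("list", nrow(expr$values))
  n_skipped <- 0L
  for (i in seq_len(nrow(expr$values))) {
    ps <- rownames(expr$values)[i]
    g_chr <- ann$chrom.tss[i] %||% ann$chrom[i]
    g_tss <- ann$tss_bp[i]
    ix <- chr_index[[g_chr]]
    if (is.null(ix)) next
    pos <- si$pos_bp[ix]
    lo <- findInterval(g_tss - window_bp - 0.5, pos) + 1L
    hi <- findInterval(g_tss + window_bp + 0.5, pos)
    if (lo > hi) next
    snp_ix <- ix[lo:hi]
    y <- expr$values[i, ]
    fits <- vector("list", length(snp_ix))
    for (k in seq_along(snp_ix)) {
      f <- ols_pair(y, genotypes$calls[, snp_ix[k]], min_n = min_n)
      if (is.null(f)) { n_skipped <- n_skipped + 1L; next }
      fits[[k]] <- c(list(snp = snp_ix[k]), f)
    }
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits) == 0) next
    ids <- vapply(fits, function(f) f$snp, integer(1))
    out[[i]] <- tibble(
      gene_id = ann$gene_id[i],
      probeset_id = ps,
      snp_id = si$snp_id[ids],
      chrom = si$chrom[ids],
      pos_bp = si$pos_bp[ids],
      beta_hat = vapply(fits, `[[`, numeric(1), "beta_hat"),
      alpha_hat = vapply(fits, `[[`, numeric(1), "alpha_hat"),
      sigma2_hat = vapply(fits, `[[`, numeric(1), "sigma2_hat"),
      se_beta = vapply(fits, `[[`, numeric(1), "se_beta"),
      t_stat = vapply(fits, `[[`, numeric(1), "t_stat"),
      p_value = vapply(fits, `[[`, numeric(1), "p_value"),
      n_used = vapply(fits, `[[`, numeric(1), "n_used")
    )
  }
  res <- bind_rows(out)
  if (n_skipped > 0) {
    inform(sprintf("scan_tissue [%s]: %d pair(s) skipped.", expr$tissue, n_skipped))
  }
  attr(res, "n_skipped") <- n_skipped
  attr(res, "tissue") <- expr$tissue
  res
}

#' Collapse a scan table to one record per gene
#'
#' For each gene, selects the (probeset, SNP) pair with the minimum P-value
#' across all of the gene's probesets and their cis SNPs — the gene-level (not
#' probeset-level) minimum-P rule, which lets tissues measured on different
#' platforms be matched by gene id downstream. Ties are broken by smaller SNP
#' position, then lexicographic probeset id.
#'
#' @param scan_table Output of [scan_tissue()].
#' @param tissue Optional tissue label; defaults to the scan table's tissue
#'   attribute.
#' @return A tibble of gene-level eQTL records, one row per gene: `gene_id`,
#'   `tissue`, `snp_id`, `probeset_id`, `beta_hat`, `alpha_hat`, `sigma2_hat`,
#'   `se_beta`, `p_value`, `n_used`.
#' @export
collapse_to_gene <- function(scan_table, tissue = NULL) {
  if (nrow(scan_table) == 0) abort("Empty scan table.")
  tissue <- tissue %||% attr(scan_table, "tissue") %||% NA_character_
  scan_table |>
    arrange(.data$gene_id, .data$p_value, .data$pos_bp, .data$probeset_id) |>
    group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(tissue = tissue) |>
    select("gene_id", "tissue", "snp_id", "probeset_id", "chrom", "pos_bp",
           "beta_hat", "alpha_hat", "sigma2_hat", "se_beta", "p_value", "n_used")
}
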