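# Benchmarking of gene rankings against a gold-standard positive set: ROC,
# trapezoid AUC, stratified bootstrap CI, DeLong paired-AUC test, cross-tissue
# overlap enrichment, and the strain sub-sampling protocol.

# Rank-based AUC: probability that a random positive scores lower (more
# significant) than a random negative, ties counting one half — identical to
# the trapezoid area of the tie-aware ROC curve.
auc_rank <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  r <- rank(score)
  u_gt <- sum(r[label]) - n1 * (n1 + 1) / 2
  1 - u_gt / (n1 * n0)
}

roc_curve_points <- function(score, label) {
  ord <- order(score)
  s <- score[ord]; l <- label[ord]
  n1 <- sum(l); n0 <- sum(!l)
  keep <- !duplicated(s, fromLast = TRUE)      # one point per tie block
  tibble(
    threshold = s[keep],
    sensitivity = cumsum(l)[keep] / n1,
    specificity = 1 - cumsum(!l)[keep] / n0
  )
}

#' ROC curve and trapezoid AUC against a gold standard
#'
#' Scores are ranking values where smaller means a more confident positive
#' call (P-values or posterior contour probabilities). The curve sweeps every
#' distinct score as a threshold; tied scores form a single diagonal segment
#' (average-rank handling), so the trapezoid area equals the Mann-Whitney
#' U-based AUC. The 95% confidence interval comes from percentile bootstrap
#' with resampling stratified by label.
#'
#' @param scores Either a numeric vector of scores, or a tibble with columns
#'   `gene_id` and `score`.
#' @param labels If `scores` is numeric: a logical vector (TRUE = positive).
#'   If `scores` is a tibble: a character vector of positive gene ids (the
#'   gold standard); the overlap with the scored genes is reported, not
#'   assumed.
#' @param n_boot Number of stratified bootstrap replicates (default 2000);
#'   0 skips the interval.
#' @param seed Seed for the bootstrap.
#' @return An object of class `ta_roc`: `curve` (tibble of threshold,
#'   sensitivity, specificity), `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`,
#'   `n_boot`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1L) {
  if (is.data.frame(scores)) {
    label <- scores$gene_id %in% labels
    n_hit <- sum(label)
    inform(sprintf("roc_auc: %d of %d gold-standard gene(s) among %d scored genes.",
                   n_hit, length(unique(labels)), nrow(scores)))
    score <- scores$score
  } else {
    score <- scores
    label <- as.logical(labels)
  }
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) {
    abort("ROC needs at least one positive and one negative label.")
  }
  curve <- roc_curve_points(score, label)
  fpr <- c(0, 1 - curve$specificity)
  sens <- c(0, curve$sensitivity)
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    pos <- which(label); neg <- which(!label)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ip <- sample(pos, n1, replace = TRUE)
        ineg <- sample(neg, n0, replace = TRUE)
        idx <- c(ip, ineg)
        auc_rank(score[idx], label[idx])
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  structure(
    list(curve = curve, auc = auc, ci_low = ci[1], ci_high = ci[2],
         n_pos = n1, n_neg = n0, n_boot = n_boot),
    class = "ta_roc"
  )
}

#' @export
print.ta_roc <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (95%% CI %.3f-%.3f, %d boot)",
                                             x$ci_low, x$ci_high, x$n_boot)
  cat(sprintf("<ta_roc> AUC = %.4f%s | %d positives / %d negatives\n",
              x$auc, ci, x$n_pos, x$n_neg))
  invisible(x)
}

#' One-row summary of a ROC result
#'
#' @param x A `ta_roc` object.
#' @param ... Unused.
#' @return A tibble with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @exportS3Method generics::glance
glance.ta_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

# DeLong placement values for one score vector. `score`: smaller = more
# positive-leaning; internally flipped so larger = positive-leaning.
delong_placements <- function(score, label) {
  u <- -score
  x <- u[label]; y <- u[!label]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(theta = (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equal AUC for two score vectors over the same genes and
#' labels, using the DeLong variance estimator of the paired AUC difference
#' computed from placement values.
#'
#' @param scores_a,scores_b Numeric score vectors (smaller = more significant)
#'   over the same genes.
#' @param labels Logical vector, TRUE = gold-standard positive.
#' @return An object of class `htest` with the AUC estimates, the z statistic
#'   and the two-sided p-value. Identical score vectors give p = 1 with a
#'   warning.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- var(pa$v10 - pb$v10)
  s01 <- var(pa$v01 - pb$v01)
  v <- s10 / m + s01 / n
  d <- pa$theta - pb$theta
  if (v <= .Machine$double.eps) {
    warn("DeLong: zero-variance AUC difference; returning p = 1.")
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(
      statistic = c(z = z),
      p.value = p,
      estimate = c(auc_a = pa$theta, auc_b = pb$theta),
      method = "DeLong test for two correlated ROC curves",
      data.name = "scores_a, scores_b",
      alternative = "two.sided"
    ),
    class = "htest"
  )
}

#' Observed vs expected cross-tissue overlap of significant local eQTL
#'
#' At each threshold, counts genes significant in each tissue, the observed
#' shared set, and the expected shared count under independence
#' (`n_sig_t1 * n_sig_t2 / n_total`), plus a one-sided binomial enrichment
#' P-value for the observed count with success probability
#' `(n_sig_t1/n) * (n_sig_t2/n)`.
#'
#' @param records_t1,records_t2 Gene-level record tibbles with `gene_id` and
#'   `p_value`; the analysis runs over their shared gene universe.
#' @param thresholds Numeric vector of significance thresholds.
#' @return A tibble with one row per threshold: `threshold`, `n_sig_t1`,
#'   `n_sig_t2`, `n_total`, `observed_shared`, `expected_shared`, `ratio`
#'   (NA when the expected count is zero), `p_enrichment`.
#' @export
overlap_analysis <- function(records_t1, records_t2,
                             thresholds = c(0.05, 0.01, 1e-3, 1e-4, 1e-5)) {
  joined <- inner_join(
    select(records_t1, "gene_id", p1 = "p_value"),
    select(records_t2, "gene_id", p2 = "p_value"),
    by = "gene_id"
  )
  n <- nrow(joined)
  if (n == 0) abort("Empty shared gene universe.")
  purrr::map_dfr(thresholds, function(t) {
    s1 <- joined$p1 <= t
    s2 <- joined$p2 <= t
    n1 <- sum(s1); n2 <- sum(s2)
    obs <- sum(s1 & s2)
    expd <- n1 * n2 / n
    tibble(
      threshold = t,
      n_sig_t1 = n1,
      n_sig_t2 = n2,
      n_total = n,
      observed_shared = obs,
      expected_shared = expd,
      ratio = if (expd > 0) obs / expd else NA_real_,
      p_enrichment = pbinom(obs - 1, n, (n1 / n) * (n2 / n), lower.tail = FALSE)
    )
  })
}

#' Geometric mean of probabilities
#'
#' `exp(mean(log(v)))` with zeros clamped to 1e-300; the aggregation used to
#' fold sub-sampling replicates into one score per gene and method.
#'
#' @param values Numeric vector in (0, 1] (zeros clamped).
#' @return The geometric mean.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0) abort("geometric_mean: empty input.")
  exp(mean(log(pmax(values, 1e-300))))
}

#' Strain sub-sampling protocol with geometric-mean aggregation
#'
#' For each subsample size and replicate, draws strains without replacement
#' from the primary tissue, re-runs the conventional scan, TA-eQTL and the
#' Stouffer meta-analysis on the subsample — holding the secondary tissue's
#' gene-level records fixed at their full-data values — and aggregates each
#' method's per-gene scores across replicates by geometric mean, yielding one
#' score table per (method, size) ready for [roc_auc()]. Replicate seeds are
#' derived deterministically from the master seed, size and replicate index.
#'
#' @param expr_primary Primary-tissue [expression_panel()].
#' @param genotypes A [genotype_panel()] (will be strain-aligned internally).
#' @param secondary_records Full-data gene-level records for the secondary
#'   tissue.
#' @param sizes Integer vector of subsample sizes (default `c(10, 15, 20, 25)`).
#' @param n_reps Replicates per size (default 6).
#' @param seed Master seed.
#' @param window_bp Cis window half-width.
#' @param min_n Minimum informative strain count per tested pair.
#' @param ... Further arguments passed to [run_ta_eqtl()].
#' @return A tibble with columns `method`, `size`, `gene_id`, `score`
#'   (geometric mean over replicates); the per-replicate table is attached as
#'   attribute `replicates`.
#' @export
subsample_protocol <- function(expr_primary, genotypes, secondary_records,
                               sizes = c(10, 15, 20, 25), n_reps = 6,
                               seed = 1L, window_bp = 1e6, min_n = 5L, ...) {
  aligned <- align_strains(genotypes, expr_primary)
  strains <- colnames(aligned$expr$values)
  if (any(sizes < min_n)) abort("Subsample size below the minimum informative strain count.")
  if (any(sizes > length(strains))) abort("Subsample size exceeds available strains.")
  per_rep <- list()
  for (size in sizes) {
    for (rep_i in seq_len(n_reps)) {
      rep_seed <- derive_seed(seed, size, rep_i)
      sub <- withr::with_seed(rep_seed, sample(strains, size, replace = FALSE))
      sub <- sort(sub)
      expr_s <- aligned$expr
      expr_s$values <- expr_s$values[, sub, drop = FALSE]
      geno_s <- aligned$genotypes
      geno_s$calls <- geno_s$calls[sub, , drop = FALSE]
      recs <- suppressMessages(
        collapse_to_gene(scan_tissue(expr_s, geno_s, window_bp = window_bp,
                                     min_n = min_n))
      )
      ta <- suppressMessages(run_ta_eqtl(recs, secondary_records, ...))
      meta <- run_meta(recs, secondary_records)
      per_rep[[length(per_rep) + 1]] <- bind_rows(
        tibble(method = "conventional", size = size, rep = rep_i,
               gene_id = recs$gene_id, score = recs$p_value),
        tibble(method = "ta_eqtl", size = size, rep = rep_i,
               gene_id = ta$gene_id, score = ta$score),
        tibble(method = "meta", size = size, rep = rep_i,
               gene_id = meta$gene_id, score = meta$score)
      )
    }
  }
  reps <- bind_rows(per_rep)
  out <- reps |>
    group_by(.data$method, .data$size, .data$gene_id) |>
    summarise(score = geometric_mean(.data$score), .groups = "drop")
  attr(out, "replicates") <- reps
  out
}
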