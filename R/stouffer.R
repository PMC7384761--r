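# Stouffer inverse-normal meta-analysis of per-tissue gene-level P-values.

#' Combine per-tissue P-values by Stouffer's inverse-normal method
#'
#' Each P-value is converted to a standard normal deviate
#' `Z_i = qnorm(1 - p_i)` and the combined score is `Z_S = sum(Z_i) / sqrt(k)`
#' with combined P `1 - pnorm(Z_S)`. The two-sided per-tissue P-values are fed
#' into the transform directly (direction is deliberately discarded: effect
#' signs are not comparable across tissues that may select different SNPs).
#' `conversion = "half_p_signed"` exposes the textbook directional variant,
#' which halves each P and reattaches the sign of the supplied effect.
#'
#' @param p_values Numeric vector of per-tissue P-values in (0, 1], length k.
#' @param conversion `"twosided_direct"` (default) or `"half_p_signed"`.
#' @param signs Effect signs per tissue, required for `"half_p_signed"`.
#' @return A one-row tibble with `k`, `z_combined`, `p_combined` and a
#'   list-column `z_scores` of the per-tissue deviates.
#' @export
stouffer_combine <- function(p_values,
                             conversion = c("twosided_direct", "half_p_signed"),
                             signs = NULL) {
  conversion <- match.arg(conversion)
  if (length(p_values) == 0) abort("stouffer_combine: empty P-value list.")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  p <- pmin(pmax(p_values, 1e-300), 1 - 1e-16)
  if (conversion == "twosided_direct") {
    z <- qnorm(p, lower.tail = FALSE)
  } else {
    if (is.null(signs)) abort("`signs` required for half_p_signed conversion.")
    z <- sign(signs) * qnorm(pmax(p / 2, 1e-300), lower.tail = FALSE)
  }
  k <- length(z)
  zs <- sum(z) / sqrt(k)
  tibble(
    k = k,
    z_combined = zs,
    p_combined = min(max(pnorm(zs, lower.tail = FALSE), 1e-300), 1 - 1e-16),
    z_scores = list(z)
  )
}

#' Meta-analyse two tissues' gene-level records
#'
#' Applies [stouffer_combine()] per gene over the two tissues' conventional
#' gene-level P-values. Genes present in only one tissue carry their
#' single-tissue P through with `k = 1` (at k = 1 the transform is the
#' identity).
#'
#' @param primary,secondary Gene-level record tibbles from
#'   [collapse_to_gene()].
#' @param conversion Passed to [stouffer_combine()].
#' @return A tibble with one row per gene in either tissue: `gene_id`, `k`,
#'   `z_combined`, `p_combined`, `score` (= `p_combined`).
#' @export
run_meta <- function(primary, secondary,
                     conversion = c("twosided_direct", "half_p_signed")) {
  conversion <- match.arg(conversion)
  joined <- full_join(
    select(primary, "gene_id", p1 = "p_value", b1 = "beta_hat"),
    select(secondary, "gene_id", p2 = "p_value", b2 = "beta_hat"),
    by = "gene_id"
  )
  res <- purrr::pmap(
    list(joined$p1, joined$p2, joined$b1, joined$b2),
    function(p1, p2, b1, b2) {
      p <- c(p1, p2)
      s <- c(b1, b2)
      keep <- !is.na(p)
      stouffer_combine(p[keep], conversion = conversion, signs = s[keep])
    }
  )
  bind_rows(res) |>
    mutate(gene_id = joined$gene_id, score = .data$p_combined) |>
    select("gene_id", "k", "z_combined", "p_combined", "score")
}
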