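# Domain containers: genotype and expression panels.
#
# Panels are lightweight S3 containers pairing a numeric matrix with a tibble
# of annotation; all downstream analysis results are plain tibbles.

#' Construct a genotype panel
#'
#' A genotype panel holds binary recombinant-inbred genotype calls for a set of
#' strains at a set of SNPs, together with genomic coordinates for every SNP.
#' Calls are coded 0 (first parental allele), 1 (second parental allele) or
#' `NA` (heterozygous or unknown, excluded from analysis). Coordinates are
#' 1-based; cis windows downstream are closed intervals.
#'
#' @param calls Numeric matrix, strains x SNPs, values in \{0, 1, NA\}, with
#'   strain ids as rownames and SNP ids as colnames.
#' @param snp_info Data frame with columns `snp_id`, `chrom`, `pos_bp`
#'   (1-based), one row per column of `calls`, same order.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(calls, snp_info) {
  calls <- as.matrix(calls)
  snp_info <- as_tibble(snp_info)
  if (is.null(rownames(calls))) abort("`calls` must have strain ids as rownames.")
  if (ncol(calls) != nrow(snp_info)) {
    abort("`snp_info` must have one row per SNP column of `calls`.")
  }
  if (is.null(colnames(calls))) colnames(calls) <- as.character(snp_info$snp_id)
  if (ncol(calls) > 0 &&
      !identical(colnames(calls), as.character(snp_info$snp_id))) {
    abort("SNP ids in `calls` colnames and `snp_info$snp_id` must match in order.")
  }
  if (anyDuplicated(snp_info$snp_id)) abort("Duplicate SNP ids in genotype panel.")
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad)) abort("Genotype calls must be 0, 1 or NA.")
  if (anyNA(snp_info$chrom) || anyNA(snp_info$pos_bp)) {
    abort("Every SNP needs a chromosome and position.")
  }
  structure(
    list(calls = calls, snp_info = snp_info),
    class = "genotype_panel"
  )
}

#' Construct an expression panel for one tissue
#'
#' Holds strain-mean log2 expression (probesets x strains) for one tissue plus
#' a probeset-to-gene annotation. Values are assumed already normalized
#' upstream (the BXD-style convention is mean 8, SD 2 per data set); no
#' re-normalization is applied. A gene may own several probesets; every
#' probeset maps to exactly one gene.
#'
#' @param values Numeric matrix, probesets x strains, probeset ids as rownames,
#'   strain ids as colnames.
#' @param annotation Data frame with columns `probeset_id`, `gene_id`, `chrom`,
#'   `start_bp`, `end_bp`, `strand` (one row per probeset of `values`).
#' @param tissue Single string labelling the tissue.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, annotation, tissue) {
  values <- as.matrix(values)
  annotation <- as_tibble(annotation)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs probeset rownames and strain colnames.")
  }
  if (anyDuplicated(colnames(values))) abort("Duplicate strain ids in expression panel.")
  if (anyDuplicated(annotation$probeset_id)) {
    abort("A probeset must map to exactly one gene (duplicate probeset_id in annotation).")
  }
  missing_ann <- setdiff(rownames(values), annotation$probeset_id)
  if (length(missing_ann) > 0) {
    abort(c("Every probeset in `values` needs annotation.",
            "x" = paste("Missing:", paste(head(missing_ann, 5), collapse = ", "))))
  }
  annotation <- annotation[match(rownames(values), annotation$probeset_id), ]
  structure(
    list(values = values, annotation = annotation, tissue = tissue),
    class = "expression_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d strains x %d SNPs on %d chromosome(s); %d missing call(s)\n",
    nrow(x$calls), ncol(x$calls), length(unique(x$snp_info$chrom)), sum(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf(
    "<expression_panel> tissue '%s': %d probesets (%d genes) x %d strains\n",
    x$tissue, nrow(x$values), length(unique(x$annotation$gene_id)), ncol(x$values)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Tidy a genotype panel into long form
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return A tibble with columns `strain_id`, `snp_id`, `chrom`, `pos_bp`, `call`.
#' @exportS3Method tibble::as_tibble
as_tibble.genotype_panel <- function(x, ...) {
  long <- tibble(
    strain_id = rep(rownames(x$calls), times = ncol(x$calls)),
    snp_id = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.vector(x$calls)
  )
  left_join(long, x$snp_info, by = "snp_id")
}

#' Tidy an expression panel into long form
#'
#' @param x An `expression_panel`.
#' @param ... Unused.
#' @return A tibble with columns `tissue`, `probeset_id`, `gene_id`,
#'   `strain_id`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.expression_panel <- function(x, ...) {
  tibble(
    tissue = x$tissue,
    probeset_id = rep(rownames(x$values), times = ncol(x$values)),
    strain_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  ) |>
    left_join(select(x$annotation, "probeset_id", "gene_id"), by = "probeset_id") |>
    select("tissue", "probeset_id", "gene_id", "strain_id", "value")
}

# Strand-aware transcription start site per gene. `start` anchors '+' (and
# unknown-strand) genes, `end` anchors '-' genes.
gene_tss <- function(annotation) {
  annotation |>
    mutate(
      tss_bp = ifelse(!is.na(.data$strand) & .data$strand == "-",
                      .data$end_bp, .data$start_bp)
    ) |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      tss_bp = first(.data$tss_bp),
      .groups = "drop"
    )
}

#' Restrict genotype and expression panels to their shared strains
#'
#' Both panels are subset to the intersection of strain ids and reordered into
#' a single canonical (sorted) order, so genotype and expression columns align
#' row-for-row in downstream scans.
#'
#' @param genotypes A `genotype_panel`.
#' @param expr An `expression_panel`.
#' @return A list with elements `genotypes` and `expr`, both restricted to the
#'   shared strains.
#' @export
align_strains <- function(genotypes, expr) {
  stopifnot(inherits(genotypes, "genotype_panel"), inherits(expr, "expression_panel"))
  shared <- sort(intersect(rownames(genotypes$calls), colnames(expr$values)))
  if (length(shared) == 0) abort("No shared strains between genotype and expression panels.")
  inform(sprintf("align_strains: %d shared strain(s).", length(shared)))
  genotypes$calls <- genotypes$calls[shared, , drop = FALSE]
  expr$values <- expr$values[, shared, drop = FALSE]
  list(genotypes = genotypes, expr = expr)
}
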