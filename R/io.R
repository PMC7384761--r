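# Readers and writers for the GeneNetwork-style .geno dialect, expression /
# annotation / gold-standard tables, and provenance-stamped result tables.

GENO_CODE <- c(B = 0, D = 1, H = NA_real_, U = NA_real_)

#' Read a GeneNetwork-style .geno genotype file
#'
#' The .geno dialect is tab-delimited: lines beginning with `@` or `#` are
#' metadata/comments; a header row names the columns `Chr`, `Locus`, `cM`,
#' `Mb`, then one column per strain; data rows carry one allele code per strain
#' from \{B, D, H, U\}. Codes are recoded B -> 0, D -> 1, H/U -> missing (no
#' imputation anywhere downstream). Positions are taken from the `Mb` column
#' and converted to base pairs (x 1e6, rounded to the nearest integer).
#'
#' @param path Path to the .geno file.
#' @return A [genotype_panel()].
#' @export
read_geno_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[@#]", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) abort("No header row found in .geno file.")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 || header[1] != "Chr" || header[2] != "Locus") {
    abort("Malformed .geno header: expected columns Chr, Locus, cM, Mb, <strains...>.")
  }
  if (header[4] != "Mb") {
    abort("Missing Mb position column in .geno file; positions are required.")
  }
  strains <- header[-(1:4)]
  if (length(strains) == 0) abort(".geno header names no strains.")
  if (anyDuplicated(strains)) abort("Duplicate strain ids in .geno header.")

  rows <- lines[-1]
  n_snp <- length(rows)
  calls <- matrix(NA_real_, nrow = length(strains), ncol = n_snp,
                  dimnames = list(strains, NULL))
  snp_id <- character(n_snp); chrom <- character(n_snp); pos <- numeric(n_snp)
  for (i in seq_len(n_snp)) {
    f <- strsplit(rows[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4 + length(strains)) {
      abort(sprintf(".geno data row %d has %d fields, expected %d.",
                    i, length(f), 4 + length(strains)))
    }
    snp_id[i] <- f[2]
    chrom[i] <- f[1]
    mb <- suppressWarnings(as.numeric(f[4]))
    if (is.na(mb)) abort(sprintf("Non-numeric Mb position for SNP '%s' (row %d).", f[2], i))
    pos[i] <- round(mb * 1e6)
    codes <- f[-(1:4)]
    bad <- !(codes %in% names(GENO_CODE))
    if (any(bad)) {
      j <- which(bad)[1]
      abort(sprintf("Unknown allele code '%s' at SNP '%s' (row %d), strain '%s'.",
                    codes[j], f[2], i, strains[j]))
    }
    calls[, i] <- unname(GENO_CODE[codes])
  }
  if (anyDuplicated(snp_id)) {
    abort(sprintf("Duplicate SNP id '%s' in .geno file.", snp_id[anyDuplicated(snp_id)]))
  }
  colnames(calls) <- snp_id
  genotype_panel(calls, tibble(snp_id = snp_id, chrom = chrom, pos_bp = pos))
}

#' Write a genotype panel in the .geno dialect
#'
#' Inverse of [read_geno_file()]: 0 -> B, 1 -> D, missing -> U; positions are
#' written in Mb with six decimals so base-pair coordinates round-trip exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno_file <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  strains <- rownames(panel$calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@type:riset", con)
  writeLines(paste(c("Chr", "Locus", "cM", "Mb", strains), collapse = "\t"), con)
  code <- function(v) ifelse(is.na(v), "U", ifelse(v == 1, "D", "B"))
  for (i in seq_len(ncol(panel$calls))) {
    row <- c(
      panel$snp_info$chrom[i],
      panel$snp_info$snp_id[i],
      "0",
      sprintf("%.6f", panel$snp_info$pos_bp[i] / 1e6),
      code(panel$calls[, i])
    )
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a strain-mean expression table plus probeset annotation
#'
#' The expression table is tab-delimited, probesets x strains, with probeset
#' ids in the first column and strain ids in the header. The annotation table
#' is tab-delimited with columns `probeset_id`, `gene_id`, `chrom`, `tss_bp`
#' (gene start), `end_bp`, `strand`. Probesets lacking annotation are dropped
#' with a message (mirroring upstream retention of annotated probesets only).
#'
#' @param path Expression table path.
#' @param annotation_path Annotation table path.
#' @param tissue Tissue label for the resulting panel.
#' @return An [expression_panel()].
#' @export
read_expression_table <- function(path, annotation_path, tissue) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2) abort("Expression table needs a probeset column plus strain columns.")
  strains <- names(raw)[-1]
  if (anyDuplicated(strains)) {
    abort(sprintf("Duplicate strain id '%s' in expression header.",
                  strains[duplicated(strains)][1]))
  }
  probesets <- raw[[1]]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(strains),
                 dimnames = list(probesets, strains))
  for (j in seq_along(strains)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num) & !is.na(col) & col != "NA"
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("Non-numeric expression value '%s' at probeset '%s', strain '%s'.",
                    col[i], probesets[i], strains[j]))
    }
    vals[, j] <- num
  }

  ann <- readr::read_tsv(annotation_path, col_types = readr::cols(
    probeset_id = readr::col_character(), gene_id = readr::col_character(),
    chrom = readr::col_character(), tss_bp = readr::col_double(),
    end_bp = readr::col_double(), strand = readr::col_character()
  ), progress = FALSE)
  ann <- dplyr::rename(ann, start_bp = "tss_bp")

  keep <- rownames(vals) %in% ann$probeset_id
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("read_expression_table: dropped %d unannotated probeset(s).", n_drop))
  }
  if (!any(keep)) abort("No probeset in the expression table has annotation.")
  vals <- vals[keep, , drop = FALSE]
  ann <- ann[ann$probeset_id %in% rownames(vals), ]
  expression_panel(vals, ann, tissue)
}

#' Write an expression panel and its annotation as tab-delimited tables
#'
#' @param panel An [expression_panel()].
#' @param path Expression table output path.
#' @param annotation_path Annotation table output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(panel, path, annotation_path) {
  stopifnot(inherits(panel, "expression_panel"))
  df <- as.data.frame(panel$values)
  df <- cbind(probeset_id = rownames(panel$values), df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  ann_out <- panel$annotation |>
    select("probeset_id", "gene_id", "chrom",
           tss_bp = "start_bp", "end_bp", "strand")
  readr::write_tsv(ann_out, annotation_path, progress = FALSE)
  invisible(path)
}

#' Read a gold-standard positive gene list
#'
#' One gene id per line; blank lines and `#` comments ignored. The overlap with
#' the analysis gene universe is reported by the evaluation functions, never
#' assumed.
#'
#' @param path Path to the gene list.
#' @return Character vector of positive gene ids.
#' @export
read_gold_standard <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) warn("Gold-standard file contains no gene ids.")
  unique(x)
}

#' Write a result table with a provenance header
#'
#' Writes a tab-delimited table preceded by a single `#`-commented header line
#' recording the package version and a hash of the resolved configuration. The
#' write is atomic (temp file + rename).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config List of resolved configuration values recorded in the hash.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, config = list()) {
  tmp <- tempfile(tmpdir = dirname(path))
  header <- sprintf("# taeqtl %s | config_hash=%s",
                    as.character(packageVersion("taeqtl")), config_hash(config))
  writeLines(header, tmp)
  suppressWarnings(
    readr::write_tsv(df, tmp, append = TRUE, col_names = TRUE, progress = FALSE)
  )
  file.rename(tmp, path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path Path to the table.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  show_col_types = FALSE)
}
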