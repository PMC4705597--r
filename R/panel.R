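#' Construct a SNP panel
#'
#' A SNP panel is the ordered set of assays anchoring every analysis to a
#' single reference coordinate system (by default GenBank AB268588, the
#' 231,382-bp MHC-B reference spanning 9,551-240,933 bp). Haplotypes are
#' defined over the *core* SNPs only; the 5' non-core SNPs are excluded from
#' haplotype identity because copy-number variation there produces
#' dual-allele and failed calls.
#'
#' @param snps A data frame with columns `snp`, `position_bp`, `gene`,
#'   `allele_x`, `allele_y`, `in_core`. Positions are 1-based on the
#'   reference; rows are re-sorted by position.
#' @param reference_name Name of the reference sequence.
#' @param reference_length Length of the reference in bp.
#'
#' @return A tibble of class `snp_panel`, sorted by position, with the
#'   reference name and length stored as attributes.
#' @export
snp_panel <- function(snps, reference_name = "AB268588",
                      reference_length = 240933L) {
  required <- c("snp", "position_bp", "gene", "allele_x", "allele_y", "in_core")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "bsnphap_format_error")
  }
  snps <- tibble::as_tibble(snps)[required]
  snps$position_bp <- as.integer(snps$position_bp)
  snps$in_core <- as.logical(snps$in_core)
  snps$gene <- as.character(snps$gene)
  snps$gene[is.na(snps$gene)] <- ""
  snps <- dplyr::arrange(snps, .data$position_bp)
  if (anyDuplicated(snps$snp)) {
    abort("duplicate SNP names in panel", class = "bsnphap_format_error")
  }
  if (anyDuplicated(snps$position_bp)) {
    abort("panel positions must be strictly increasing (duplicate position)",
          class = "bsnphap_format_error")
  }
  bad <- snps$allele_x == snps$allele_y
  if (any(bad)) {
    abort(paste0("allele_x == allele_y for SNP ", snps$snp[which(bad)[1]]),
          class = "bsnphap_format_error")
  }
  structure(snps,
            reference_name = reference_name,
            reference_length = as.integer(reference_length),
            class = c("snp_panel", class(tibble::tibble())))
}

#' Read a SNP panel from a tab-delimited file
#'
#' Expects a header with columns `snp`, `position_bp`, `gene`, `allele_x`,
#' `allele_y`, `in_core`; lines starting with `#` are ignored. Rows may be in
#' any order; the panel is returned sorted by position.
#'
#' @param path Path to the panel TSV.
#' @inheritParams snp_panel
#' @return A [snp_panel].
#' @export
read_snp_panel <- function(path, reference_name = "AB268588",
                           reference_length = 240933L) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"in_core" %in% names(df)) {
    abort("panel file is missing column 'in_core'",
          class = "bsnphap_format_error")
  }
  df$in_core <- df$in_core %in% c("TRUE", "true", "1", "yes")
  snp_panel(df, reference_name = reference_name,
            reference_length = reference_length)
}

#' Write a SNP panel to a tab-delimited file
#'
#' @param panel A [snp_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  readr::write_tsv(tibble::as_tibble(panel), path)
  invisible(path)
}

#' Core SNPs of a panel
#'
#' @param panel A [snp_panel].
#' @return The rows of `panel` with `in_core = TRUE` (haplotype-defining SNPs).
#' @export
core_snps <- function(panel) {
  tibble::as_tibble(panel)[panel$in_core, , drop = FALSE]
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d SNPs (%d core) on %s (%s bp), %s-%s bp\n",
              nrow(x), sum(x$in_core), attr(x, "reference_name"),
              format(attr(x, "reference_length"), big.mark = ","),
              format(min(x$position_bp), big.mark = ","),
              format(max(x$position_bp), big.mark = ",")))
  NextMethod()
}
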