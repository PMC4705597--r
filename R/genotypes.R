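#' Construct a genotype matrix
#'
#' Birds by SNPs diploid calls in canonical codes. Optional per-bird metadata
#' carries the population (line) label, pedigree (sire/dam ids) and the two
#' LEI0258 VNTR allele sizes in bp.
#'
#' @param birds A data frame with at least `bird_id` and `line_id`; optional
#'   `sire_id`, `dam_id`, `lei_1`, `lei_2`.
#' @param calls A character matrix (birds x SNPs) of canonical codes among
#'   `XX`, `YY`, `XY`, `DUP_XXY`, `DUP_XYY`, `AMBIG_BOTH`, `FAIL`, with
#'   column names equal to panel SNP names.
#' @param panel The [snp_panel] the calls refer to.
#' @return A tibble of class `genotype_matrix`: metadata columns followed by
#'   one call column per SNP, with the panel stored as an attribute.
#' @export
genotype_matrix <- function(birds, calls, panel) {
  birds <- tibble::as_tibble(birds)
  if (!all(c("bird_id", "line_id") %in% names(birds))) {
    abort("birds needs columns bird_id and line_id",
          class = "bsnphap_format_error")
  }
  if (nrow(calls) != nrow(birds)) {
    abort("calls and birds disagree on the number of birds",
          class = "bsnphap_format_error")
  }
  if (!identical(colnames(calls), panel$snp)) {
    abort("calls columns must match panel SNPs in panel order",
          class = "bsnphap_format_error")
  }
  bad <- !(calls %in% .call_codes)
  if (any(bad)) {
    abort(paste0("illegal call code: ", calls[which(bad)[1]]),
          class = "bsnphap_format_error")
  }
  if (all(c("sire_id", "dam_id") %in% names(birds))) {
    parents <- c(birds$sire_id, birds$dam_id)
    parents <- parents[!is.na(parents)]
    if (!all(parents %in% birds$bird_id)) {
      abort("pedigree references unknown bird ids",
            class = "bsnphap_format_error")
    }
  }
  out <- dplyr::bind_cols(birds, tibble::as_tibble(calls))
  structure(out, panel = panel,
            meta_cols = names(birds),
            class = c("genotype_matrix", class(tibble::tibble())))
}

#' Panel attached to a genotype matrix or haplotype set
#' @param x A `genotype_matrix` or `haplotype_set`.
#' @return The [snp_panel] attribute.
#' @export
panel_of <- function(x) attr(x, "panel")

#' Call columns of a genotype matrix as a character matrix
#' @param m A `genotype_matrix`.
#' @return Character matrix birds x SNPs of canonical codes.
#' @export
call_matrix <- function(m) {
  panel <- panel_of(m)
  out <- as.matrix(tibble::as_tibble(m)[, panel$snp, drop = FALSE])
  rownames(out) <- m$bird_id
  out
}

# --- cell token dialect ------------------------------------------------------

# Parse one written genotype token for a SNP with alleles (x, y) into a
# canonical code. Accepted tokens: two-nucleotide strings ("AC"), a single
# IUPAC ambiguity letter for the allele pair, "-" (fail), "DUP:XXY"/"DUP:XYY".
parse_call_token <- function(token, x, y, snp = "?") {
  if (is.na(token) || token == "-" || token == "") return("FAIL")
  if (token == "DUP:XXY") return("DUP_XXY")
  if (token == "DUP:XYY") return("DUP_XYY")
  if (nchar(token) == 1) {
    if (identical(unname(.iupac[paste0(x, y)]), token)) return("AMBIG_BOTH")
    if (token == x) return("XX")   # single-letter homozygote shorthand
    if (token == y) return("YY")
    abort(paste0("illegal cell token '", token, "' at SNP ", snp),
          class = "bsnphap_format_error")
  }
  if (nchar(token) == 2) {
    a <- substr(token, 1, 1); b <- substr(token, 2, 2)
    if (!all(c(a, b) %in% c(x, y))) {
      abort(paste0("cell '", token, "' at SNP ", snp,
                   " does not match alleles ", x, "/", y),
            class = "bsnphap_format_error")
    }
    n_x <- (a == x) + (b == x)
    return(c("YY", "XY", "XX")[n_x + 1])
  }
  abort(paste0("illegal cell token '", token, "' at SNP ", snp),
        class = "bsnphap_format_error")
}

render_call_token <- function(code, x, y) {
  switch(code,
         XX = paste0(x, x),
         YY = paste0(y, y),
         XY = paste0(x, y),
         AMBIG_BOTH = unname(.iupac[paste0(x, y)]),
         DUP_XXY = "DUP:XXY",
         DUP_XYY = "DUP:XYY",
         FAIL = "-")
}

#' Read a genotype matrix from a tab-delimited file
#'
#' One row per bird. Metadata columns `bird_id`, `line_id` (and optionally
#' `sire_id`, `dam_id`, `lei_1`, `lei_2`) are followed by one column per panel
#' SNP. Per-SNP cells are two-nucleotide strings ("AC"), a single IUPAC
#' ambiguity letter (K/M/R/Y, the dual-allele duplication signal), `-` for a
#' failed assay, or explicit `DUP:XXY` / `DUP:XYY` tokens.
#'
#' @param path Path to the genotype TSV.
#' @param panel The [snp_panel] defining SNP columns and allele pairs.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, panel) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  meta_cols <- intersect(c("bird_id", "line_id", "sire_id", "dam_id",
                           "lei_1", "lei_2"), names(df))
  snp_cols <- setdiff(names(df), meta_cols)
  unknown <- setdiff(snp_cols, panel$snp)
  if (length(unknown) > 0) {
    abort(paste0("unknown SNP column(s): ", paste(unknown, collapse = ", ")),
          class = "bsnphap_format_error")
  }
  missing_snp <- setdiff(panel$snp, snp_cols)
  if (length(missing_snp) > 0) {
    abort(paste0("genotype file lacks panel SNP(s): ",
                 paste(head(missing_snp, 5), collapse = ", ")),
          class = "bsnphap_format_error")
  }
  birds <- df[meta_cols]
  for (col in intersect(c("lei_1", "lei_2"), names(birds))) {
    birds[[col]] <- suppressWarnings(as.integer(birds[[col]]))
  }
  calls <- matrix("", nrow(df), nrow(panel), dimnames = list(NULL, panel$snp))
  for (j in seq_len(nrow(panel))) {
    s <- panel$snp[j]
    calls[, j] <- vapply(df[[s]], parse_call_token,
                         x = panel$allele_x[j], y = panel$allele_y[j],
                         snp = s, FUN.VALUE = character(1), USE.NAMES = FALSE)
  }
  genotype_matrix(birds, calls, panel)
}

#' Write a genotype matrix to a tab-delimited file
#'
#' Inverse of [read_genotypes()]; round-trips exactly.
#'
#' @param m A [genotype_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(m, path) {
  panel <- panel_of(m)
  calls <- call_matrix(m)
  out <- tibble::as_tibble(m)[, attr(m, "meta_cols"), drop = FALSE]
  for (j in seq_len(nrow(panel))) {
    out[[panel$snp[j]]] <- vapply(calls[, j], render_call_token,
                                  x = panel$allele_x[j], y = panel$allele_y[j],
                                  FUN.VALUE = character(1), USE.NAMES = FALSE)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d birds x %d SNPs, %d line(s)\n",
              nrow(x), nrow(panel_of(x)), length(unique(x$line_id))))
  NextMethod()
}
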