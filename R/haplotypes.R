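#' Construct a haplotype set
#'
#' A haplotype is the ordered vector of allele states over the panel's core
#' SNPs, one of `X` (reference-panel allele x), `Y` (allele y), `B` (both
#' alleles, the dual-allele duplication signal) or `F` (failed assay /
#' missing). A haplotype set records, per haplotype, how often and in which
#' lines/birds it was observed, plus naming annotations (family letter,
#' index, LEI0258 allele sizes, serology labels).
#'
#' @param alleles List of character vectors (or a character matrix with one
#'   row per haplotype) over the panel's core SNPs, states in X/Y/B/F.
#' @param panel The [snp_panel].
#' @param count Integer observation counts (default 1 each).
#' @param lines List of character vectors of line ids per haplotype.
#' @param birds List of character vectors of bird ids per haplotype.
#' @param family,index,suffix Optional naming components.
#' @param lei List of integer vectors of LEI0258 allele sizes (bp).
#' @param serology List of character vectors of serology labels.
#' @param name Optional full names; if `NA`, built by [bsnp_name()] when the
#'   components are present.
#' @return A tibble of class `haplotype_set` with a list-column `alleles` and
#'   the panel attached as an attribute.
#' @export
haplotype_set <- function(alleles, panel, count = NULL, lines = NULL,
                          birds = NULL, family = NA_character_,
                          index = NA_integer_, suffix = NA_character_,
                          lei = NULL, serology = NULL, name = NA_character_) {
  if (is.matrix(alleles)) {
    alleles <- lapply(seq_len(nrow(alleles)), function(i) unname(alleles[i, ]))
  }
  n <- length(alleles)
  n_core <- sum(panel$in_core)
  ok_len <- vapply(alleles, length, integer(1)) == n_core
  if (!all(ok_len)) {
    abort(sprintf("haplotype allele vectors must have length %d (core SNPs)",
                  n_core), class = "bsnphap_format_error")
  }
  ok_states <- vapply(alleles, function(a) all(a %in% .hap_states), logical(1))
  if (!all(ok_states)) {
    abort("haplotype states must be in {X, Y, B, F}",
          class = "bsnphap_format_error")
  }
  out <- tibble::tibble(
    hap_id = paste0("H", seq_len(n)),
    alleles = alleles,
    count = if (is.null(count)) rep(1L, n) else as.integer(count),
    lines = lines %||% rep(list(character(0)), n),
    birds = birds %||% rep(list(character(0)), n),
    family = rep_len(family, n),
    index = rep_len(as.integer(index), n),
    suffix = rep_len(suffix, n),
    lei = lei %||% rep(list(integer(0)), n),
    serology = serology %||% rep(list(character(0)), n),
    name = rep_len(name, n)
  )
  structure(out, panel = panel,
            class = c("haplotype_set", class(tibble::tibble())))
}

new_haplotype_set <- function(df, panel) {
  structure(tibble::as_tibble(df), panel = panel,
            class = c("haplotype_set", class(tibble::tibble())))
}

#' Compact string keys for haplotype allele vectors
#' @param haps A `haplotype_set` or list of allele vectors.
#' @return Character vector, one string (e.g. "XYXB...") per haplotype.
#' @export
hap_key <- function(haps) {
  alleles <- if (is.data.frame(haps)) haps$alleles else haps
  vapply(alleles, paste, collapse = "", FUN.VALUE = character(1),
         USE.NAMES = FALSE)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("Haplotype set: %d haplotypes over %d core SNPs\n",
              nrow(x), sum(panel_of(x)$in_core)))
  NextMethod()
}

#' Compose a BSNP haplotype name
#'
#' Names follow the `BSNP-<letter><two-digit index>` convention, with an
#' optional variant suffix letter (used when haplotypes identical over the
#' core SNPs differ in the 5' copy-number region), followed in parentheses by
#' the LEI0258 allele sizes and, after a semicolon, any serology labels:
#' e.g. `BSNP-A02(357;B75)`, `BSNP-A09A(357,369;BQ)`.
#'
#' @param family Cluster (family) letter.
#' @param index Integer 1..99, printed with two digits.
#' @param suffix Optional variant suffix letter.
#' @param lei Integer LEI0258 allele sizes in bp.
#' @param serology Character serology labels.
#' @return The composed name, a string.
#' @export
bsnp_name <- function(family, index, suffix = NULL, lei = integer(0),
                      serology = character(0)) {
  if (is.na(index) || index < 1 || index > 99) {
    abort("haplotype index must be in 1..99", class = "bsnphap_value_error")
  }
  base <- sprintf("BSNP-%s%02d%s", family, index,
                  if (is.null(suffix) || is.na(suffix)) "" else suffix)
  lei <- lei[!is.na(lei)]
  serology <- serology[!is.na(serology) & serology != ""]
  if (length(lei) == 0 && length(serology) == 0) return(base)
  ann <- paste(lei, collapse = ",")
  if (length(serology) > 0) {
    sero <- paste(serology, collapse = ",")
    ann <- if (length(lei) > 0) paste0(ann, ";", sero) else sero
  }
  paste0(base, "(", ann, ")")
}

#' Name of a recombinant haplotype
#'
#' Recombinants are numbered in order of identification: `BSNP-Rec01`,
#' `BSNP-Rec02`, ...
#'
#' @param n Integer order of identification.
#' @param lei Optional LEI0258 allele sizes.
#' @param labels Optional previously-accepted recombinant names.
#' @return The composed name.
#' @export
bsnp_rec_name <- function(n, lei = integer(0), labels = character(0)) {
  base <- sprintf("BSNP-Rec%02d", n)
  if (length(lei) == 0 && length(labels) == 0) return(base)
  ann <- paste(lei, collapse = ",")
  if (length(labels) > 0) {
    lab <- paste(labels, collapse = ",")
    ann <- if (length(lei) > 0) paste0(ann, "; ", lab) else lab
  }
  paste0(base, "(", ann, ")")
}

# render one haplotype state as a table cell (nucleotides; B as the IUPAC
# letter of the allele pair; F literal)
render_hap_cell <- function(state, x, y) {
  switch(state, X = x, Y = y, B = unname(.iupac[paste0(x, y)]), F = "F")
}

parse_hap_cell <- function(cell, x, y, snp = "?") {
  if (cell == "F") return("F")
  if (cell == x) return("X")
  if (cell == y) return("Y")
  if (identical(unname(.iupac[paste0(x, y)]), cell)) return("B")
  abort(paste0("illegal haplotype cell '", cell, "' at SNP ", snp),
        class = "bsnphap_format_error")
}

#' Write a haplotype table
#'
#' Rows are haplotypes, columns the core SNPs (cells are nucleotides, IUPAC
#' letters for dual-allele states, `F` for fail), preceded by the name and
#' annotation columns. Round-trips exactly through [read_haplotypes()].
#'
#' @param haps A [haplotype_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haps, path) {
  panel <- panel_of(haps)
  core <- core_snps(panel)
  out <- tibble::tibble(
    hap_id = haps$hap_id,
    name = haps$name,
    family = haps$family,
    index = haps$index,
    suffix = haps$suffix,
    lei = vapply(haps$lei, paste, collapse = ",", FUN.VALUE = character(1)),
    serology = vapply(haps$serology, paste, collapse = ",",
                      FUN.VALUE = character(1)),
    count = haps$count,
    lines = vapply(haps$lines, paste, collapse = ",", FUN.VALUE = character(1))
  )
  states <- do.call(rbind, haps$alleles)
  for (j in seq_len(nrow(core))) {
    out[[core$snp[j]]] <-
      if (nrow(haps) == 0) character(0) else
        vapply(states[, j], render_hap_cell, x = core$allele_x[j],
               y = core$allele_y[j], FUN.VALUE = character(1),
               USE.NAMES = FALSE)
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a haplotype table written by [write_haplotypes()]
#'
#' @param path Path to the haplotype TSV.
#' @param panel The [snp_panel].
#' @return A [haplotype_set].
#' @export
read_haplotypes <- function(path, panel) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, na = character(),
                        col_types = readr::cols(.default = readr::col_character()))
  core <- core_snps(panel)
  missing_snp <- setdiff(core$snp, names(df))
  if (length(missing_snp) > 0) {
    abort(paste0("haplotype table lacks core SNP(s): ",
                 paste(head(missing_snp, 5), collapse = ", ")),
          class = "bsnphap_format_error")
  }
  split_int <- function(s) if (s == "") integer(0) else as.integer(strsplit(s, ",")[[1]])
  split_chr <- function(s) if (s == "") character(0) else strsplit(s, ",")[[1]]
  n <- nrow(df)
  alleles <- lapply(seq_len(n), function(i) {
    vapply(seq_len(nrow(core)), function(j) {
      parse_hap_cell(df[[core$snp[j]]][i], core$allele_x[j], core$allele_y[j],
                     core$snp[j])
    }, character(1))
  })
  out <- haplotype_set(
    alleles, panel,
    count = if ("count" %in% names(df)) as.integer(df$count) else NULL,
    lines = if ("lines" %in% names(df)) lapply(df$lines, split_chr) else NULL,
    lei = if ("lei" %in% names(df)) lapply(df$lei, split_int) else NULL,
    serology = if ("serology" %in% names(df)) lapply(df$serology, split_chr) else NULL
  )
  for (col in c("name", "family", "suffix", "hap_id")) {
    if (col %in% names(df)) out[[col]] <- ifelse(df[[col]] == "", NA, df[[col]])
  }
  if ("index" %in% names(df)) {
    out$index <- suppressWarnings(as.integer(df$index))
  }
  new_haplotype_set(out, panel)
}
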