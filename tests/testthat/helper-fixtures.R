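# shared fixture builders; everything is generated in code

# minimal panel: n core SNPs at the given positions, alleles A/C throughout
tiny_panel <- function(positions, in_core = TRUE, names = NULL,
                       ref_len = max(positions) + 1000L) {
  n <- length(positions)
  snp_panel(tibble::tibble(
    snp = names %||% sprintf("S%02d", seq_len(n)),
    position_bp = positions,
    gene = "",
    allele_x = "A", allele_y = "C",
    in_core = rep_len(in_core, n)),
    reference_length = ref_len)
}

# haplotype set from state strings like "XXYYX"
hs_from_keys <- function(keys, panel, count = NULL, ...) {
  haplotype_set(lapply(keys, function(k) strsplit(k, "")[[1]]), panel,
                count = count, ...)
}

# genotype matrix for one line from a matrix of canonical codes
gm_from_codes <- function(codes, panel, line = "L1", birds = NULL,
                          extra = NULL) {
  birds <- birds %||% sprintf("b%02d", seq_len(nrow(codes)))
  colnames(codes) <- panel$snp
  meta <- tibble::tibble(bird_id = birds, line_id = line)
  if (!is.null(extra)) meta <- dplyr::bind_cols(meta, extra)
  genotype_matrix(meta, codes, panel)
}

# diploid code matrix from two haplotype key strings per bird
codes_from_pairs <- function(pairs) {
  t(vapply(pairs, function(p) {
    a <- strsplit(p[1], "")[[1]]; b <- strsplit(p[2], "")[[1]]
    ifelse(a == b, ifelse(a == "X", "XX", "YY"), "XY")
  }, character(nchar(pairs[[1]][1]))))
}

# random tiny line drawn from a small haplotype pool (codes only)
random_tiny_line <- function(n_snp = NULL, n_hap = NULL, n_bird = NULL) {
  n_snp <- n_snp %||% sample(4:8, 1)
  n_hap <- n_hap %||% sample(2:4, 1)
  n_bird <- n_bird %||% sample(2:6, 1)
  pool <- unique(replicate(n_hap, sample(c("X", "Y"), n_snp, TRUE),
                           simplify = FALSE))
  g <- t(sapply(seq_len(n_bird), function(i) {
    pr <- sample(length(pool), 2, replace = TRUE)
    a <- pool[[pr[1]]]; b <- pool[[pr[2]]]
    ifelse(a == b, ifelse(a == "X", "XX", "YY"), "XY")
  }))
  colnames(g) <- paste0("S", seq_len(n_snp))
  rownames(g) <- paste0("b", seq_len(n_bird))
  g
}

tiny_line_gm <- function(g) {
  panel <- tiny_panel(seq_len(ncol(g)) * 1000L, names = colnames(g))
  gm_from_codes(g, panel, birds = rownames(g))
}
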