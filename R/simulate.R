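#' Simulation configuration
#'
#' Defaults emulate the study system this package targets: a 101-SNP panel
#' (90 core SNPs spanning 30,189-240,933 bp plus 11 5' SNPs subject to
#' copy-number variation), a multiple-line cross of 15 sires x 142 dams
#' producing 1189 offspring, a recombination rate of 0.006 observable
#' crossovers per offspring (7/1189 = 0.6 per 100), LEI0258 VNTR alleles
#' mutating in 12/13-bp repeat steps at about 1.1 per 1000 birds, and a 5'
#' segment (12,062-13,992 bp) deleted on some haplotypes and duplicated on
#' others.
#'
#' @param n_core_snps,n_flank_snps Panel sizes (haplotype-defining core and
#'   5' flank).
#' @param n_families,haps_per_family Founder haplotype family structure.
#' @param within_family_diff Maximum core-SNP differences within a family.
#' @param between_family_diff Minimum core-SNP differences between families.
#' @param n_lines,haps_per_line Population structure: founder haplotypes are
#'   dealt to lines, `haps_per_line` each.
#' @param n_sires,n_dams,n_offspring Pedigree sizes.
#' @param recomb_rate_per_meiosis Probability that an offspring carries an
#'   observable recombinant haplotype (crossover of a heterozygous parent's
#'   two haplotypes inside their informative span).
#' @param hotspot_bins Data frame (`start_bp`, `end_bp`, `weight`) from which
#'   crossover positions are drawn; `NULL` means uniform over the core span.
#' @param lei_mutation_rate Probability of a LEI0258 allele-size mutation per
#'   offspring.
#' @param lei_step_sizes Repeat-unit sizes (bp) for LEI0258 mutations.
#' @param lei_up_prob Probability a mutation increases the allele size
#'   (the bias observed in pedigreed data is entirely upward).
#' @param cnv_haplotype_profile Optional named integer vector mapping founder
#'   haplotype id to copy number (0, 1 or 2) for the 5' CNV segment; `NULL`
#'   draws copies with `cnv_copy_probs`.
#' @param cnv_copy_probs Probabilities of 0/1/2 copies per founder haplotype.
#' @param cnv_segment Integer `c(start, end)` bp of the CNV segment.
#' @param fluor_noise_sd Gaussian noise sd for simulated endpoint
#'   fluorescence (normalized scale).
#' @param parent_het If `TRUE`, sires and dams receive two distinct founder
#'   haplotypes whenever their line segregates more than one, so crossovers
#'   are observable.
#' @param seed Integer seed; all simulator output is a deterministic
#'   function of the config including the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_core_snps = 90L, n_flank_snps = 11L,
                       n_families = 5L, haps_per_family = 3L,
                       within_family_diff = 3L, between_family_diff = 30L,
                       n_lines = 4L, haps_per_line = 4L,
                       n_sires = 15L, n_dams = 142L, n_offspring = 1189L,
                       recomb_rate_per_meiosis = 0.006,
                       hotspot_bins = NULL,
                       lei_mutation_rate = 0.0011,
                       lei_step_sizes = c(12L, 13L),
                       lei_up_prob = 1,
                       cnv_haplotype_profile = NULL,
                       cnv_copy_probs = c(`0` = 0.15, `1` = 0.70, `2` = 0.15),
                       cnv_segment = c(12062L, 13992L),
                       fluor_noise_sd = 0.02,
                       parent_het = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(recomb_rate_per_meiosis, lei_mutation_rate, lei_up_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "bsnphap_value_error")
  }
  if (!is.null(hotspot_bins)) {
    hb <- tibble::as_tibble(hotspot_bins)
    if (any(hb$weight < 0) || all(hb$weight == 0)) {
      abort("hotspot bin weights must be nonnegative with at least one positive",
            class = "bsnphap_value_error")
    }
    cfg$hotspot_bins <- hb
  }
  if (haps_per_family > 1 && between_family_diff <= within_family_diff) {
    abort("between_family_diff must exceed within_family_diff",
          class = "bsnphap_value_error")
  }
  structure(cfg, class = "sim_config")
}

#' Deterministic synthetic SNP panel
#'
#' Core SNPs are spread over 30,189-240,933 bp; with the default 11 flank
#' SNPs the 5' layout mirrors the real panel (six SNPs inside the
#' 12,062-13,992 bp CNV segment, the rest between 9,551 and 27,791 bp).
#'
#' @param n_core,n_flank Numbers of core and flank SNPs.
#' @return A [snp_panel].
#' @export
simulate_panel <- function(n_core = 90L, n_flank = 11L) {
  core_pos <- round(seq(30189, 240933, length.out = n_core))
  flank_pos <- if (n_flank == 11L) {
    c(9551L, 12062L, 12448L, 12834L, 13220L, 13606L, 13992L,
      17607L, 21784L, 24788L, 27791L)
  } else if (n_flank > 0) {
    round(seq(9551, 27791, length.out = n_flank))
  } else integer(0)
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"), ncol = 2,
                  byrow = TRUE)
  n <- n_core + n_flank
  idx <- rep_len(seq_len(nrow(pairs)), n)
  snp_panel(tibble::tibble(
    snp = c(sprintf("NEW%03d", seq_len(n_flank)),
            sprintf("MHC%03d", seq_len(n_core))),
    position_bp = c(flank_pos, core_pos),
    gene = "",
    allele_x = pairs[idx, 1],
    allele_y = pairs[idx, 2],
    in_core = c(rep(FALSE, n_flank), rep(TRUE, n_core))
  ))
}

#' Generate founder haplotypes organised into separated families
#'
#' Families are built around random core-allele centres whose pairwise
#' Hamming distances respect the between-family bound; members differ from
#' their centre at `floor(within_family_diff / 2)` positions so any
#' within-family pair differs at no more than `within_family_diff` SNPs.
#' Each founder also receives a flank allele vector, a CNV copy number for
#' the 5' segment and a family-linked LEI0258 allele size.
#'
#' @param cfg A [sim_config()].
#' @param panel Optional [snp_panel]; defaults to
#'   `simulate_panel(cfg$n_core_snps, cfg$n_flank_snps)`.
#' @return A [haplotype_set] with extra columns `cnv_copies`, `lei_size` and
#'   `flank_alleles`; the family letter is in `family`.
#' @export
simulate_founders <- function(cfg, panel = NULL) {
  panel <- panel %||% simulate_panel(cfg$n_core_snps, cfg$n_flank_snps)
  n_core <- sum(panel$in_core)
  r <- floor(cfg$within_family_diff / 2)
  need <- cfg$between_family_diff + 2L * r
  if (cfg$n_families > 1 && need > n_core) {
    abort(sprintf(
      "infeasible separation: need centre distance %d > %d core SNPs",
      need, n_core), class = "bsnphap_value_error")
  }
  if (cfg$haps_per_family > 1 && r < 1) {
    abort("within_family_diff < 2 cannot produce distinct family members",
          class = "bsnphap_value_error")
  }
  set.seed(cfg$seed)
  centres <- NULL
  for (try in seq_len(2000)) {
    cand <- matrix(sample(c("X", "Y"), cfg$n_families * n_core, replace = TRUE),
                   nrow = cfg$n_families)
    if (cfg$n_families == 1) { centres <- cand; break }
    dmin <- min(stats::dist(ifelse(cand == "X", 0L, 1L), method = "manhattan"))
    if (dmin >= need) { centres <- cand; break }
  }
  if (is.null(centres)) {
    abort("could not place family centres at the requested separation",
          class = "bsnphap_value_error")
  }
  alleles <- list(); family <- character(0)
  for (f in seq_len(cfg$n_families)) {
    flip_pool <- sample.int(n_core)  # distinct flip positions across members
    for (k in seq_len(cfg$haps_per_family)) {
      h <- centres[f, ]
      if (k > 1 && r > 0) {
        pos <- flip_pool[((k - 2) * r + 1):((k - 1) * r)]
        h[pos] <- ifelse(h[pos] == "X", "Y", "X")
      }
      alleles <- c(alleles, list(h))
      family <- c(family, LETTERS[f])
    }
  }
  n <- length(alleles)
  lei_pool <- c(193L, 205L, 249L, 261L, 295L, 309L, 345L, 357L, 369L,
                405L, 443L, 461L, 539L)
  fam_lei <- sample(lei_pool, cfg$n_families,
                    replace = cfg$n_families > length(lei_pool))
  n_flank <- sum(!panel$in_core)
  flank <- lapply(seq_len(n), function(i)
    sample(c("X", "Y"), n_flank, replace = TRUE))
  copies <- if (!is.null(cfg$cnv_haplotype_profile)) {
    as.integer(cfg$cnv_haplotype_profile[seq_len(n)])
  } else {
    sample(0:2, n, replace = TRUE, prob = cfg$cnv_copy_probs)
  }
  out <- haplotype_set(alleles, panel, family = NA_character_)
  out$hap_id <- sprintf("F%02d", seq_len(n))
  out$family <- family
  out$cnv_copies <- copies
  out$lei_size <- fam_lei[match(family, LETTERS)]
  out$lei <- as.list(out$lei_size)
  out$flank_alleles <- flank
  new_haplotype_set(out, panel)
}

#' Draw crossover positions from weighted hotspot bins
#'
#' @param bins Data frame with `start_bp`, `end_bp`, `weight`.
#' @param n Number of positions to draw.
#' @return Integer positions, bin chosen proportionally to weight, uniform
#'   within the bin.
#' @export
sample_breakpoints <- function(bins, n) {
  bins <- tibble::as_tibble(bins)
  idx <- sample.int(nrow(bins), n, replace = TRUE, prob = bins$weight)
  floor(runif(n, bins$start_bp[idx], bins$end_bp[idx]))
}

# Draw one crossover position for a heterozygous parent: restricted to the
# informative span [first differing core SNP, last differing core SNP), so
# the product differs from both parental haplotypes.
draw_crossover <- function(h_a, h_b, core_pos, bins) {
  diff_pos <- core_pos[h_a != h_b]
  lo <- min(diff_pos); hi <- max(diff_pos) - 1L
  if (!is.null(bins)) {
    ov <- dplyr::mutate(bins,
                        start_bp = pmax(.data$start_bp, lo),
                        end_bp = pmin(.data$end_bp, hi))
    ov <- ov[ov$start_bp < ov$end_bp & ov$weight > 0, ]
    if (nrow(ov) > 0) return(sample_breakpoints(ov, 1L))
  }
  floor(runif(1, lo, hi + 1))
}

# genotype code at a CNV-segment SNP given per-haplotype copy numbers and
# alleles; a 2-copy haplotype carries both alleles (one per paralog)
cnv_call <- function(a1, c1, a2, c2) {
  n_x <- (c1 == 1) * (a1 == "X") + (c2 == 1) * (a2 == "X") +
    (c1 == 2) + (c2 == 2)
  n_y <- (c1 == 1) * (a1 == "Y") + (c2 == 1) * (a2 == "Y") +
    (c1 == 2) + (c2 == 2)
  tot <- n_x + n_y
  if (tot == 0) return("FAIL")
  if (n_y == 0) return("XX")
  if (n_x == 0) return("YY")
  if (n_x == n_y) return(if (tot == 2) "XY" else "AMBIG_BOTH")
  if (n_x > n_y) "DUP_XXY" else "DUP_XYY"
}

#' Simulate a pedigreed multi-line population
#'
#' Founder haplotypes are dealt to lines; sires and dams receive haplotype
#' pairs from their line's pool; each offspring draws one haplotype from its
#' sire and one from its dam. With probability `recomb_rate_per_meiosis` a
#' transmitted haplotype is an observable crossover of a heterozygous
#' parent's two haplotypes at a position drawn from the hotspot bins within
#' the parental informative span. Genotypes are derived from the haplotype
#' pairs; 5' CNV-segment SNPs follow the copy-number logic (0+0 copies fail,
#' duplicated haplotypes produce dual-allele and 2:1 cluster codes).
#' LEI0258 alleles are transmitted with the haplotype and mutate in repeat
#' steps.
#'
#' @param founders Output of [simulate_founders()].
#' @param cfg The same [sim_config()].
#' @return A list of class `sim_population`: `genotypes` (a
#'   [genotype_matrix] containing sires, dams and offspring), `truth` (a
#'   list of tibbles: `transmissions`, `recombinants`, `lei_mutations`,
#'   `founders`), and `line_pools` (founder ids per line).
#' @export
simulate_population <- function(founders, cfg) {
  panel <- panel_of(founders)
  set.seed(cfg$seed + 1L)
  n_f <- nrow(founders)
  if (cfg$haps_per_line < 1 || cfg$n_lines < 1) {
    abort("each line needs at least one founder haplotype",
          class = "bsnphap_value_error")
  }
  line_ids <- sprintf("L%02d", seq_len(cfg$n_lines))
  # deal founders to lines interleaved across families, so each line
  # segregates distinct haplotypes (as in a multi-line cross)
  member_rank <- stats::ave(seq_len(n_f), founders$family, FUN = seq_along)
  deal_order <- order(member_rank, founders$family)
  pool_idx <- lapply(seq_len(cfg$n_lines), function(l) {
    deal_order[((seq_len(cfg$haps_per_line) - 1 +
                   (l - 1) * cfg$haps_per_line) %% n_f) + 1]
  })
  core <- core_snps(panel)
  flank <- tibble::as_tibble(panel)[!panel$in_core, , drop = FALSE]
  in_cnv <- flank$position_bp >= cfg$cnv_segment[1] &
    flank$position_bp <= cfg$cnv_segment[2]

  n_off <- cfg$n_offspring
  max_haps <- n_f + n_off
  hap_id_v <- character(max_haps); hap_core <- vector("list", max_haps)
  hap_flank <- vector("list", max_haps); hap_copies <- integer(max_haps)
  hap_lei <- integer(max_haps); hap_founder <- logical(max_haps)
  hap_id_v[1:n_f] <- founders$hap_id
  hap_core[1:n_f] <- founders$alleles
  hap_flank[1:n_f] <- founders$flank_alleles
  hap_copies[1:n_f] <- founders$cnv_copies
  hap_lei[1:n_f] <- founders$lei_size
  hap_founder[1:n_f] <- TRUE
  n_hap <- n_f
  founder_keys <- hap_key(founders$alleles)

  # parents: two founder haplotype indices each
  mk_parent <- function(line_l) {
    pool <- pool_idx[[line_l]]
    if (cfg$parent_het && length(unique(pool)) >= 2) {
      sample(unique(pool), 2L)
    } else sample(pool, 2L, replace = TRUE)
  }
  sire_line <- ((seq_len(cfg$n_sires) - 1) %% cfg$n_lines) + 1
  dam_line <- ((seq_len(cfg$n_dams) - 1) %% cfg$n_lines) + 1
  sire_haps <- lapply(sire_line, mk_parent)
  dam_haps <- lapply(dam_line, mk_parent)
  sire_ids <- sprintf("S%03d", seq_len(cfg$n_sires))
  dam_ids <- sprintf("D%03d", seq_len(cfg$n_dams))

  n_b <- cfg$n_sires + cfg$n_dams + n_off
  bird_id <- c(sire_ids, dam_ids, sprintf("O%04d", seq_len(n_off)))
  line_id <- c(line_ids[sire_line], line_ids[dam_line], character(n_off))
  sire_of <- rep(NA_character_, n_b); dam_of <- rep(NA_character_, n_b)
  lei_1 <- integer(n_b); lei_2 <- integer(n_b)
  hap1_i <- integer(n_b); hap2_i <- integer(n_b)
  np <- cfg$n_sires + cfg$n_dams
  hap1_i[1:np] <- vapply(c(sire_haps, dam_haps), `[`, integer(1), 1)
  hap2_i[1:np] <- vapply(c(sire_haps, dam_haps), `[`, integer(1), 2)
  lei_1[1:np] <- hap_lei[hap1_i[1:np]]
  lei_2[1:np] <- hap_lei[hap2_i[1:np]]

  t_bird <- character(2 * n_off); t_role <- character(2 * n_off)
  t_parent <- character(2 * n_off); t_hap <- character(2 * n_off)
  t_rec <- logical(2 * n_off)
  recombinants <- vector("list", n_off); n_recs <- 0L
  lei_mut <- vector("list", n_off); n_mut <- 0L

  off_line <- rep_len(seq_len(cfg$n_lines), n_off)
  for (o in seq_len(n_off)) {
    l <- off_line[o]
    b <- np + o
    oid <- bird_id[b]
    line_id[b] <- line_ids[l]
    si <- sample(which(sire_line == l), 1)
    di <- sample(which(dam_line == l), 1)
    sire_of[b] <- sire_ids[si]; dam_of[b] <- dam_ids[di]
    par_haps <- list(sire_haps[[si]], dam_haps[[di]])
    par_ids <- c(sire_ids[si], dam_ids[di])
    recomb <- runif(1) < cfg$recomb_rate_per_meiosis
    rec_role <- if (recomb) {
      het <- vapply(par_haps, function(h) h[1] != h[2], logical(1))
      if (any(het)) sample(c(1, 2)[het], 1) else NA_integer_
    } else NA_integer_
    pair <- integer(2)
    for (ri in 1:2) {
      ph <- par_haps[[ri]]
      if (!is.na(rec_role) && ri == rec_role) {
        ord <- sample(1:2)
        ha_i <- ph[ord[1]]; hb_i <- ph[ord[2]]
        ha <- hap_core[[ha_i]]; hb <- hap_core[[hb_i]]
        x <- draw_crossover(ha, hb, core$position_bp, cfg$hotspot_bins)
        new_core <- ifelse(core$position_bp <= x, ha, hb)
        n_hap <- n_hap + 1L; hi <- n_hap
        n_recs <- n_recs + 1L
        rid <- sprintf("R%03d", n_recs)
        hap_id_v[hi] <- rid; hap_core[[hi]] <- new_core
        hap_flank[[hi]] <- hap_flank[[ha_i]]
        hap_copies[hi] <- hap_copies[ha_i]; hap_lei[hi] <- hap_lei[ha_i]
        key <- paste(new_core, collapse = "")
        recombinants[[n_recs]] <- tibble::tibble(
          bird_id = oid, line_id = line_ids[l], rec_id = rid,
          p5_hap = hap_id_v[ha_i], p3_hap = hap_id_v[hb_i],
          crossover_bp = x, key = key,
          novel = !(key %in% founder_keys))
      } else {
        hi <- ph[sample(1:2, 1)]
      }
      pair[ri] <- hi
      ti <- 2L * (o - 1L) + ri
      t_bird[ti] <- oid; t_role[ti] <- c("sire", "dam")[ri]
      t_parent[ti] <- par_ids[ri]; t_hap[ti] <- hap_id_v[hi]
      t_rec[ti] <- !is.na(rec_role) && ri == rec_role
    }
    lei_pair <- hap_lei[pair]
    if (runif(1) < cfg$lei_mutation_rate) {
      slot <- sample(1:2, 1)
      step <- sample(cfg$lei_step_sizes, 1)
      sgn <- if (runif(1) < cfg$lei_up_prob) 1L else -1L
      n_mut <- n_mut + 1L
      lei_mut[[n_mut]] <- tibble::tibble(
        bird_id = oid, allele_slot = slot, from = lei_pair[slot],
        to = lei_pair[slot] + sgn * step, delta = sgn * step)
      lei_pair[slot] <- lei_pair[slot] + sgn * step
    }
    lei_1[b] <- lei_pair[1]; lei_2[b] <- lei_pair[2]
    hap1_i[b] <- pair[1]; hap2_i[b] <- pair[2]
  }

  birds_df <- tibble::tibble(bird_id = bird_id, line_id = line_id,
                             sire_id = sire_of, dam_id = dam_of,
                             lei_1 = lei_1, lei_2 = lei_2)
  # genotypes from haplotype pairs, vectorized over birds
  H <- do.call(rbind, hap_core[1:n_hap])
  A1 <- H[hap1_i, , drop = FALSE]; A2 <- H[hap2_i, , drop = FALSE]
  core_calls <- ifelse(A1 == A2, ifelse(A1 == "X", "XX", "YY"), "XY")
  FL <- do.call(rbind, hap_flank[1:n_hap])
  F1 <- FL[hap1_i, , drop = FALSE]; F2 <- FL[hap2_i, , drop = FALSE]
  flank_calls <- ifelse(F1 == F2, ifelse(F1 == "X", "XX", "YY"), "XY")
  c1 <- hap_copies[hap1_i]; c2 <- hap_copies[hap2_i]
  for (j in which(in_cnv)) {
    a1 <- F1[, j]; a2 <- F2[, j]
    nx <- (c1 == 1) * (a1 == "X") + (c2 == 1) * (a2 == "X") +
      (c1 == 2) + (c2 == 2)
    ny <- (c1 == 1) * (a1 == "Y") + (c2 == 1) * (a2 == "Y") +
      (c1 == 2) + (c2 == 2)
    tot <- nx + ny
    flank_calls[, j] <- ifelse(tot == 0, "FAIL",
      ifelse(ny == 0, "XX", ifelse(nx == 0, "YY",
        ifelse(nx == ny, ifelse(tot == 2, "XY", "AMBIG_BOTH"),
          ifelse(nx > ny, "DUP_XXY", "DUP_XYY")))))
  }
  calls <- matrix("FAIL", n_b, nrow(panel), dimnames = list(NULL, panel$snp))
  calls[, which(panel$in_core)] <- core_calls
  calls[, which(!panel$in_core)] <- flank_calls
  geno <- genotype_matrix(birds_df, calls, panel)
  hap_tbl <- tibble::tibble(hap_id = hap_id_v[1:n_hap],
                            core = hap_core[1:n_hap],
                            flank = hap_flank[1:n_hap],
                            copies = hap_copies[1:n_hap],
                            lei = hap_lei[1:n_hap],
                            founder = hap_founder[1:n_hap])
  transmissions <- list(tibble::tibble(
    bird_id = t_bird, parent_role = t_role, parent_id = t_parent,
    hap_id = t_hap, recombinant = t_rec))
  t_i <- 1L
  recombinants <- recombinants[seq_len(n_recs)]
  lei_mut <- lei_mut[seq_len(n_mut)]
  truth <- list(
    transmissions = dplyr::bind_rows(transmissions[seq_len(t_i)]),
    recombinants = if (length(recombinants)) dplyr::bind_rows(recombinants)
      else tibble::tibble(bird_id = character(0), line_id = character(0),
                          rec_id = character(0), p5_hap = character(0),
                          p3_hap = character(0), crossover_bp = integer(0),
                          key = character(0), novel = logical(0)),
    lei_mutations = if (length(lei_mut)) dplyr::bind_rows(lei_mut)
      else tibble::tibble(bird_id = character(0), allele_slot = integer(0),
                          from = integer(0), to = integer(0),
                          delta = integer(0)),
    founders = tibble::tibble(hap_id = founders$hap_id,
                              family = founders$family,
                              cnv_copies = founders$cnv_copies,
                              lei_size = founders$lei_size),
    haplotypes = hap_tbl
  )
  structure(list(genotypes = geno, truth = truth,
                 line_pools = setNames(
                   lapply(pool_idx, function(ix) founders$hap_id[ix]),
                   line_ids)),
            class = "sim_population")
}

#' Simulate endpoint-fluorescence signal for genotype calls
#'
#' Noiseless centroids on the normalized (total = 1) plane are
#' XX (1, 0), YY (0, 1), XY (0.5, 0.5), DUP_XXY (2/3, 1/3),
#' DUP_XYY (1/3, 2/3), AMBIG_BOTH (0.5, 0.5) and FAIL (0, 0); Gaussian noise
#' of sd `noise_sd` is added per axis and truncated at 0.
#'
#' @param calls Character vector of canonical genotype codes.
#' @param noise_sd Noise standard deviation.
#' @return A tibble with columns `vic` (allele-x fluorophore) and `fam`.
#' @export
simulate_kasp_fluorescence <- function(calls, noise_sd = 0) {
  cent <- kasp_centroids()
  cent <- rbind(cent, AMBIG_BOTH = cent["XY", ])
  bad <- setdiff(unique(calls), rownames(cent))
  if (length(bad)) {
    abort(paste0("unknown call code: ", bad[1]), class = "bsnphap_value_error")
  }
  n <- length(calls)
  vic <- unname(cent[calls, "vic"]) + rnorm(n, 0, noise_sd)
  fam <- unname(cent[calls, "fam"]) + rnorm(n, 0, noise_sd)
  tibble::tibble(vic = pmax(vic, 0), fam = pmax(fam, 0))
}

#' Simulate qPCR Cq replicates for a copy-number assay
#'
#' The target amplicon lies in the CNV segment; the control is a single-copy
#' gene. The expected Cq difference is `-log_eff(copies / 2)`; zero copies
#' give no target amplification (missing Cq).
#'
#' @param copies Copies per diploid genome (0..4).
#' @param efficiency PCR efficiency in (1, 2]; 2 means perfect doubling.
#' @param noise_sd Replicate Cq noise sd.
#' @param n_reps Number of replicates (the assay design uses six).
#' @param base_cq Mean control Cq.
#' @return A tibble with columns `replicate`, `target_cq` (NA when
#'   `copies = 0`) and `control_cq`.
#' @export
simulate_qpcr <- function(copies, efficiency = 2, noise_sd = 0, n_reps = 6L,
                          base_cq = 25) {
  if (efficiency <= 1 || efficiency > 2) {
    abort("efficiency must be in (1, 2]", class = "bsnphap_value_error")
  }
  control <- rnorm(n_reps, base_cq, noise_sd)
  target <- if (copies == 0) rep(NA_real_, n_reps) else
    rnorm(n_reps, base_cq - log(copies / 2) / log(efficiency), noise_sd)
  tibble::tibble(replicate = seq_len(n_reps), target_cq = target,
                 control_cq = control)
}
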