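test_that("breakpoint localization brackets the crossover with informative SNPs",
{
  panel <- tiny_panel(seq_len(6) * 10000L)   # 10k..60k
  p5 <- rep("X", 6); p3 <- rep("Y", 6)
  rec <- c("X", "X", "X", "Y", "Y", "Y")
  iv <- localize_breakpoint(rec, p5, p3, panel)
  expect_equal(unname(iv), c(30000, 40000))

  # parents identical over an internal block: the interval spans it
  p3b <- c("Y", "Y", "X", "X", "Y", "Y")    # identical at 30-40k
  recb <- c("X", "X", "X", "X", "Y", "Y")
  ivb <- localize_breakpoint(recb, p5, p3b, panel)
  expect_equal(unname(ivb), c(20000, 50000))

  expect_error(localize_breakpoint(p5, p5, p3, panel),
               class = "bsnphap_breakpoint_error")
  expect_error(localize_breakpoint(c("X", "Y", "X", "Y", "X", "Y"), p5, p3,
                                   panel),
               class = "bsnphap_breakpoint_error")
})

test_that("breakpoint localization handles a synthetic standard-recombinant case",
{
  # synthetic stand-in for a known class-II-upstream recombinant: informative
  # SNPs flank the crossover at 64,656 and 85,359 bp
  panel <- tiny_panel(c(30189L, 45000L, 64656L, 85359L, 120000L, 240933L),
                      names = c("MHCJ06", "MHC010", "MHC018", "MHC033",
                                "MHC087", "MHC178"))
  p5 <- c("X", "X", "X", "Y", "Y", "Y")   # 5' parent
  p3 <- c("Y", "Y", "Y", "X", "X", "X")   # 3' parent
  rec <- c("X", "X", "X", "X", "X", "X")  # switches inside MHC018..MHC033
  iv <- localize_breakpoint(rec, p5, p3, panel)
  expect_equal(unname(iv), c(64656, 85359))
})

test_that("recombinants are called only when both parents are present", {
  panel <- tiny_panel(seq_len(10) * 10000L)
  H1 <- paste(rep("X", 10), collapse = "")
  H2 <- paste(rep("Y", 10), collapse = "")
  H3 <- "XYXYXYXYXY"
  mosaic <- "XXXXXYYYYY"
  pop <- hs_from_keys(c(H1, H2, H3), panel, count = c(5L, 5L, 5L))
  cand <- hs_from_keys(mosaic, panel)
  sc <- detect_recombinants(cand, pop)
  expect_equal(nrow(sc$calls), 1)
  expect_equal(sc$calls$name, "BSNP-Rec01")
  got_parents <- c(sc$calls$p5_id, sc$calls$p3_id)
  expect_setequal(hap_key(pop)[match(got_parents, pop$hap_id)], c(H1, H2))
  expect_equal(sc$calls$interval_start_bp, 50000)
  expect_equal(sc$calls$interval_end_bp, 60000)

  # drop one parent from the population: no call, reported as apparent
  pop2 <- hs_from_keys(c(H1, H3), panel, count = c(5L, 5L))
  sc2 <- detect_recombinants(cand, pop2)
  expect_equal(nrow(sc2$calls), 0)
  expect_equal(nrow(sc2$apparent), 1)
})

test_that("one exception SNP is tolerated and annotated", {
  panel <- tiny_panel(seq_len(10) * 10000L)
  H1 <- paste(rep("X", 10), collapse = "")
  H2 <- paste(rep("Y", 10), collapse = "")
  pop <- hs_from_keys(c(H1, H2), panel, count = c(5L, 5L))
  # position 3 carries an allele found in neither parent's state there
  mosaic_mut <- "XXBXXYYYYY"
  sc <- detect_recombinants(hs_from_keys(mosaic_mut, panel), pop,
                            max_mismatches = 1)
  expect_equal(nrow(sc$calls), 1)
  expect_equal(sc$calls$n_mismatches, 1)
  expect_equal(sc$calls$mismatch_snps[[1]], "S03")
  expect_equal(sc$calls$mismatch_type[[1]], "mutation")
  # a failed SNP is pairwise-deleted, matching how an inherited deletion
  # (failed in recombinant and parent alike) is no exception at all
  mosaic_del <- "XXFXXYYYYY"
  sc_d <- detect_recombinants(hs_from_keys(mosaic_del, panel), pop,
                              max_mismatches = 1)
  expect_equal(nrow(sc_d$calls), 1)
  expect_equal(sc_d$calls$n_mismatches, 0)
  # with zero tolerance the mutated mosaic is rejected
  sc0 <- detect_recombinants(hs_from_keys(mosaic_mut, panel), pop,
                             max_mismatches = 0)
  expect_equal(nrow(sc0$calls), 0)
})

test_that("hotspot bins count unique recombinants, contained by default", {
  panel <- tiny_panel(c(1000L, 250000L), ref_len = 250000L)
  calls <- tibble::tibble(key = "k1",
                          interval_start_bp = 10000L,
                          interval_end_bp = 12500L)
  prof <- hotspot_profile(calls, panel, bin_size = 1000, threshold = 4)
  hit <- prof$count[prof$bin_start %in% c(10000, 11000, 12000)]
  expect_equal(hit, c(1L, 1L, 0L))   # [12k,13k) is not contained in 12.5k
  expect_equal(sum(prof$count), 2)
  prof_ov <- hotspot_profile(calls, panel, bin_size = 1000, threshold = 4,
                             mode = "overlap")
  expect_equal(prof_ov$count[prof_ov$bin_start %in% c(10000, 11000, 12000)],
               c(1L, 1L, 1L))

  # duplicated keys (the same recombinant seen twice) count once
  calls2 <- dplyr::bind_rows(calls, calls)
  expect_equal(sum(hotspot_profile(calls2, panel)$count), 2)

  # four unique identical-interval recombinants reach the threshold
  calls4 <- tibble::tibble(key = paste0("k", 1:4),
                           interval_start_bp = 10000L,
                           interval_end_bp = 12500L)
  prof4 <- hotspot_profile(calls4, panel, threshold = 4)
  hs <- hotspots(prof4)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$letter, "A")
  expect_equal(c(hs$start_bp, hs$end_bp), c(10000, 12000))

  # no calls: an all-zero profile without hotspots
  prof0 <- hotspot_profile(calls[0, ], panel)
  expect_true(all(prof0$count == 0))
  expect_equal(nrow(hotspots(prof0)), 0)
  expect_error(hotspot_profile(calls, panel, bin_size = 0),
               class = "bsnphap_value_error")
})

test_that("hotspot BED export is 0-based half-open with letter names", {
  panel <- tiny_panel(c(1000L, 250000L), ref_len = 250000L)
  calls4 <- tibble::tibble(key = paste0("k", 1:4),
                           interval_start_bp = 10000L,
                           interval_end_bp = 13000L)
  prof <- hotspot_profile(calls4, panel, threshold = 4)
  path <- withr::local_tempfile(fileext = ".bed")
  write_hotspots_bed(prof, path)
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE)
  expect_equal(bed$start, 10000)
  expect_equal(bed$end, 13000)
  expect_equal(bed$name, "A")
})

test_that("rate estimates follow the events-per-unit convention", {
  r <- recombination_rate(7, 1189)
  expect_equal(round(r$rate, 1), 0.6)
  expect_equal(r$per_unit, 100L)
  expect_equal(tidy(r)$rate_1dp, 0.6)
  ci <- stats::binom.test(7, 1189)$conf.int
  expect_equal(unname(r$ci95), unname(100 * ci))
  expect_equal(recombination_rate(0, 1000)$rate, 0)
  expect_equal(recombination_rate(1, 100)$rate, 1)
  expect_error(recombination_rate(5, 0), class = "bsnphap_value_error")

  l <- lei_mutation_rate(3, 2667)
  expect_equal(round(l$rate, 1), 1.1)
  expect_equal(l$per_unit, 1000L)
  expect_equal(lei_mutation_rate(0, 1000)$rate, 0)
  expect_equal(lei_mutation_rate(6, 1000)$rate, 6)
  ev <- tibble::tibble(delta = c(12, 24, 5))
  expect_warning(l2 <- lei_mutation_rate(ev, 1000), "12/13")
  expect_equal(l2$events, 3L)
})

test_that("pedigree screening finds VNTR allele-size mutations", {
  panel <- tiny_panel(c(1000L, 2000L))
  codes <- rbind(c("XX", "XX"), c("XX", "XX"), c("XX", "XX"),
                 c("XX", "XX"), c("XX", "XX"))
  m <- gm_from_codes(codes, panel,
                     birds = c("sire", "dam", "kid1", "kid2", "kid3"),
                     extra = tibble::tibble(
                       sire_id = c(NA, NA, "sire", "sire", "sire"),
                       dam_id = c(NA, NA, "dam", "dam", "dam"),
                       lei_1 = c(261L, 261L, 261L, 261L, NA),
                       lei_2 = c(261L, 309L, 321L, 309L, 309L)))
  ev <- detect_lei_mutations(m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$bird_id, "kid1")
  expect_equal(ev$allele, 321L)
  expect_equal(ev$nearest_parent_allele, 309L)
  expect_equal(ev$delta, 12L)
  expect_true(ev$step_multiple)
  expect_equal(attr(ev, "n_checked"), 2L)    # kid3 skipped (missing allele)
  expect_equal(attr(ev, "skipped"), "kid3")
  m2 <- gm_from_codes(codes[1:2, ], panel, birds = c("a", "b"))
  expect_error(detect_lei_mutations(m2), class = "bsnphap_value_error")
})

test_that("pedigree-aware line scan resolves ambiguous recombinant carriers", {
  # crossovers near the core boundary make one true parent spuriously
  # compatible with the carrier's genotype; pedigree attribution must
  # recover the event anyway
  found <- 0; total <- 0
  for (s in c(4, 11)) {
    cfg <- sim_config(seed = s)
    f <- simulate_founders(cfg)
    pop <- simulate_population(f, cfg)
    tr <- pop$truth$recombinants
    for (l in unique(tr$line_id)) {
      sc <- scan_line_recombinants(pop$genotypes, l)
      tl <- tr[tr$line_id == l & tr$novel, ]
      total <- total + nrow(tl)
      found <- found + sum(tl$key %in% sc$calls$key)
    }
  }
  expect_gt(total, 0)
  expect_equal(found, total)
})
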