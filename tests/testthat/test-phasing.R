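test_that("subtracting a known haplotype leaves the complement", {
  # heterozygous first SNP, homozygous second: AC/GG style input
  expect_equal(subtract_phase(c("XY", "XX"), c("X", "X")), c("Y", "X"))
  # a fully homozygous bird minus its own haplotype returns it unchanged
  expect_equal(subtract_phase(c("XX", "YY", "XX"), c("X", "Y", "X")),
               c("X", "Y", "X"))
  # fail and dual-allele genotypes propagate as missing / both
  expect_equal(subtract_phase(c("FAIL", "AMBIG_BOTH", "XY"), c("X", "B", "Y")),
               c("F", "B", "X"))
  err <- expect_error(subtract_phase(c("YY", "XX"), c("X", "X"),
                                     snp_names = c("MHC001", "MHC002")),
                      class = "bsnphap_subtraction_error")
  expect_match(conditionMessage(err), "MHC001")
  expect_error(subtract_phase(c("XX"), c("X", "Y")),
               class = "bsnphap_value_error")
})

test_that("homozygous birds define haplotypes with counts", {
  panel <- tiny_panel(c(1000L, 2000L, 3000L))
  codes <- rbind(c("XX", "YY", "XX"),
                 c("XX", "YY", "XX"),
                 c("XX", "YY", "XX"),
                 c("XX", "XY", "XX"),     # heterozygous: excluded here
                 c("XX", "YY", "FAIL"))   # homozygous with a failed SNP
  m <- gm_from_codes(codes, panel)
  hs <- haplotypes_from_homozygotes(m, "L1")
  expect_equal(sort(hap_key(hs)), c("XYF", "XYX"))
  expect_equal(hs$count[hap_key(hs) == "XYX"], 3L)
  expect_error(haplotypes_from_homozygotes(m, "nope"),
               class = "bsnphap_value_error")
  # a line with no homozygote yields an empty set, not an error
  m2 <- gm_from_codes(rbind(c("XY", "XY", "XY")), panel)
  expect_equal(nrow(haplotypes_from_homozygotes(m2, "L1")), 0)
})

test_that("chained subtraction recovers haplotypes seen only in heterozygotes", {
  panel <- tiny_panel(seq_len(6) * 1000L)
  H1 <- "XXXXXX"; H2 <- "YYYYYY"; H3 <- "XXYYXX"
  g <- codes_from_pairs(list(c(H1, H1), c(H2, H2), c(H1, H3)))
  m <- gm_from_codes(g, panel)
  res <- infer_haplotypes(m, "L1")
  expect_setequal(hap_key(res$haplotypes), c(H1, H2, H3))
  expect_equal(nrow(res$unresolved), 0)
})

test_that("a line fixed for one haplotype resolves trivially", {
  panel <- tiny_panel(seq_len(5) * 1000L)
  g <- codes_from_pairs(list(c("XYXYX", "XYXYX"), c("XYXYX", "XYXYX")))
  res <- infer_haplotypes(gm_from_codes(g, panel), "L1")
  expect_equal(hap_key(res$haplotypes), "XYXYX")
  expect_equal(res$haplotypes$count, 2L)
})

test_that("identical multi-SNP heterozygotes stay unresolved", {
  panel <- tiny_panel(seq_len(6) * 1000L)
  g <- codes_from_pairs(list(c("XXXXXX", "YYYYYY"), c("XXXXXX", "YYYYYY")))
  res <- infer_haplotypes(gm_from_codes(g, panel), "L1")
  expect_equal(nrow(res$haplotypes), 0)
  expect_equal(nrow(res$unresolved), 2)
})

test_that("a single-SNP heterozygote phases itself", {
  panel <- tiny_panel(seq_len(4) * 1000L)
  g <- codes_from_pairs(list(c("XXXX", "XXXY")))
  res <- infer_haplotypes(gm_from_codes(g, panel), "L1")
  expect_setequal(hap_key(res$haplotypes), c("XXXX", "XXXY"))
})

test_that("inferred pairs reproduce every bird's genotype (soundness)", {
  set.seed(31)
  for (i in 1:20) {
    g <- random_tiny_line()
    m <- tiny_line_gm(g)
    res <- infer_haplotypes(m, "L1")
    asn <- res$assignments
    for (r in which(!is.na(asn$method))) {
      a <- strsplit(asn$hap1[r], "")[[1]]
      b <- strsplit(asn$hap2[r], "")[[1]]
      expected <- ifelse(a == b, ifelse(a == "X", "XX", "YY"), "XY")
      expect_equal(unname(g[asn$bird_id[r], ]), expected)
    }
  }
})

test_that("iterative inference equals the exhaustive parsimony reference", {
  set.seed(32)
  for (i in 1:60) {
    g <- random_tiny_line()
    oracle <- enumerate_parsimony_phasings(g)
    res <- infer_haplotypes(tiny_line_gm(g), "L1")
    expect_identical(sort(hap_key(res$haplotypes)), sort(oracle$forced))
  }
})

test_that("haplotypes occurring homozygous in a simulated line are always recovered,
           and all resolutions are sound", {
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_offspring = 200, n_sires = 4, n_dams = 10,
                      recomb_rate_per_meiosis = 0)
    f <- simulate_founders(cfg)
    pop <- simulate_population(f, cfg)
    key_of <- setNames(hap_key(f), f$hap_id)
    tr <- pop$truth$transmissions
    for (l in names(pop$line_pools)) {
      res <- infer_haplotypes(pop$genotypes, l)
      line_birds <- pop$genotypes$bird_id[pop$genotypes$line_id == l]
      tl <- tr[tr$bird_id %in% line_birds, ]
      # haplotypes with at least one homozygous carrier must be recovered
      hom_haps <- unique(unlist(tapply(tl$hap_id, tl$bird_id, function(h)
        if (length(unique(h)) == 1) h[1] else NULL)))
      expect_true(all(key_of[hom_haps] %in% hap_key(res$haplotypes)))
      # and everything recovered is a haplotype truly carried in the line
      carried_keys <- unique(unname(key_of[unique(tl$hap_id)]))
      parent_rows <- which(pop$genotypes$line_id == l &
                             is.na(pop$genotypes$sire_id))
      # parents also carry pool haplotypes
      pool_keys <- unname(key_of[pop$line_pools[[l]]])
      expect_true(all(hap_key(res$haplotypes) %in%
                        union(carried_keys, pool_keys)))
    }
  }
})

test_that("reconciliation merges identical haplotypes and fills missing calls",
{
  panel <- tiny_panel(seq_len(4) * 1000L)
  s1 <- hs_from_keys(c("XYXY", "XXXX"), panel, count = c(3L, 1L),
                     lines = list("L1", "L1"))
  s2 <- hs_from_keys(c("XYXY", "XYXF", "YYYY"), panel, count = c(2L, 1L, 1L),
                     lines = list("L2", "L2", "L2"))
  merged <- reconcile_haplotypes(list(s1, s2))
  # identical vector across lines: one haplotype, union provenance
  k <- hap_key(merged)
  expect_equal(sum(k == "XYXY"), 1)
  expect_setequal(merged$lines[[which(k == "XYXY")]], c("L1", "L2"))
  expect_equal(merged$count[k == "XYXY"], 6)   # 3 + 2 + the F-filled singleton
  # one non-missing disagreement keeps haplotypes distinct
  expect_true(all(c("XXXX", "YYYY") %in% k))
  expect_equal(nrow(merged), 3)
})

test_that("haplotype names compose per the naming scheme", {
  expect_equal(bsnp_name("A", 2, lei = 357L, serology = "B75"),
               "BSNP-A02(357;B75)")
  expect_equal(bsnp_name("A", 9, suffix = "A", lei = c(357L, 369L),
                         serology = "BQ"),
               "BSNP-A09A(357,369;BQ)")
  expect_equal(bsnp_name("B", 3, lei = 249L,
                         serology = c("B15.2", "B22")),
               "BSNP-B03(249;B15.2,B22)")
  expect_equal(bsnp_name("A", 1, lei = 345L), "BSNP-A01(345)")
  expect_equal(bsnp_name("S", 1), "BSNP-S01")
  expect_error(bsnp_name("A", 0), class = "bsnphap_value_error")
  expect_error(bsnp_name("A", 100), class = "bsnphap_value_error")
  expect_equal(bsnp_rec_name(1, lei = 309L, labels = c("B2R1", "B2R3")),
               "BSNP-Rec01(309; B2R1,B2R3)")
  expect_equal(bsnp_rec_name(20), "BSNP-Rec20")
})
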