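test_that("fractional dissimilarity counts differing comparable sites", {
  a <- rep("X", 90)
  expect_equal(fractional_dissimilarity(a, a), 0)
  # two standard haplotypes differing at 31 of 90 SNPs
  b <- a; b[1:31] <- "Y"
  expect_equal(fractional_dissimilarity(a, b), 31 / 90, tolerance = 1e-12)
  # one missing call at a differing site: pairwise deletion leaves 89 sites
  b2 <- b; b2[1] <- "F"
  expect_equal(fractional_dissimilarity(a, b2), 30 / 89, tolerance = 1e-12)
  # the dual-allele signal is a state of its own
  b3 <- a; b3[1] <- "B"
  expect_equal(fractional_dissimilarity(a, b3), 1 / 90, tolerance = 1e-12)
  expect_error(fractional_dissimilarity(a, a[1:10]),
               class = "bsnphap_value_error")
  expect_error(fractional_dissimilarity(rep("F", 5),
                                        c("X", "X", "F", "F", "F")),
               class = "bsnphap_value_error")
})

test_that("fractional dissimilarity agrees with the ape pairwise-deletion oracle",
{
  set.seed(8)
  panel <- tiny_panel(seq_len(40) * 1000L)
  for (i in 1:5) {
    keys <- replicate(5, paste(sample(c("X", "Y"), 40, TRUE), collapse = ""))
    haps <- hs_from_keys(keys, panel)
    D <- dissimilarity_matrix(haps)
    M <- do.call(rbind, haps$alleles)
    D_ape <- as.matrix(ape::dist.gene(M, method = "percentage",
                                      pairwise.deletion = TRUE))
    expect_equal(unname(D), unname(D_ape), tolerance = 1e-12)
  }
})

test_that("FAIL-heavy haplotype pairs are refused", {
  panel <- tiny_panel(seq_len(6) * 1000L)
  haps <- hs_from_keys(c("XXXXXX", "FFFFXX"), panel)
  expect_error(dissimilarity_matrix(haps), class = "bsnphap_value_error")
})

test_that("neighbor joining handles 2 and 3 taxa in closed form", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- nj_tree(D2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  # three-point formulas: d(a,v) = (dab + dac - dbc) / 2 etc.
  D3 <- matrix(c(0, .3, .5,
                 .3, 0, .4,
                 .5, .4, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(D3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(0.2, 0.1, 0.3),
               tolerance = 1e-12)
  expect_error(nj_tree(D2[1, 1, drop = FALSE]), class = "bsnphap_value_error")
})

test_that("NJ recovers 4-taxon topologies chosen by the four-point condition", {
  set.seed(13)
  tips <- c("t1", "t2", "t3", "t4")
  for (i in 1:20) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.5))
    D <- ape::cophenetic.phylo(tr)[tips, tips]
    # independent oracle: the four-point condition picks the split whose
    # pairwise distance sum is smallest
    sums <- c(`((t1,t2),(t3,t4));` = D[1, 2] + D[3, 4],
              `((t1,t3),(t2,t4));` = D[1, 3] + D[2, 4],
              `((t1,t4),(t2,t3));` = D[1, 4] + D[2, 3])
    if (sum(sums == min(sums)) > 1) next   # degenerate: skip this draw
    want <- ape::unroot(ape::read.tree(text = names(which.min(sums))))
    expect_equal(phangorn::RF.dist(nj_tree(D), want), 0)
  }
})

test_that("NJ on additive distances recovers the generating topology", {
  set.seed(14)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    tr <- ape::unroot(tr)
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    expect_equal(phangorn::RF.dist(got, tr), 0)
  }
})

test_that("patristic distances cover all nodes and match a graph oracle", {
  skip_if_not_installed("igraph")
  t2 <- ape::read.tree(text = "(a:0.1,b:0.2);")
  expect_equal(patristic_matrix(t2)[1, 2], 0.3)
  tz <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  expect_true(all(patristic_matrix(tz) == 0))

  set.seed(15)
  tr <- ape::rtree(8)
  dn <- patristic_matrix(tr)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$edge[, 1], to = tr$edge[, 2],
               weight = tr$edge.length), directed = FALSE)
  sp <- igraph::distances(g)
  ord <- as.character(seq_len(nrow(dn)))
  expect_equal(unname(dn[ord, ord]), unname(sp[ord, ord]), tolerance = 1e-10)
  tr0 <- tr; tr0$edge.length <- NULL
  expect_error(patristic_matrix(tr0), class = "bsnphap_value_error")
})

test_that("bootstrap support is deterministic and saturates for a clean split",
{
  # half the columns split {A,B} from {C,D}, the rest are constant: the
  # probability a resample carries no informative column is (1/2)^80
  panel <- tiny_panel(seq_len(80) * 1000L)
  keyA <- paste(c(rep("X", 40), rep("X", 40)), collapse = "")
  keyB <- keyA
  keyC <- paste(c(rep("Y", 40), rep("X", 40)), collapse = "")
  keyD <- keyC
  # perturb one haplotype per pair so all four are distinct
  keyB <- sub("X", "Y", keyA)          # differs at one constant column
  keyD <- sub("XX", "XY", keyC)
  haps <- hs_from_keys(c(keyA, keyB, keyC, keyD), panel)
  haps$hap_id <- c("A", "B", "C", "D")
  tr <- bootstrap_support(haps, n_reps = 100, seed = 1)
  supports <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(supports, na.rm = TRUE), 99)
  tr2 <- bootstrap_support(haps, n_reps = 100, seed = 1)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrap_support(haps, n_reps = 1, seed = 2)
  expect_true(all(suppressWarnings(as.numeric(tr3$node.label)) %in%
                    c(0, 100, NA)))
})

test_that("MPPD clustering separates tight clades and leaves stars unclustered",
{
  # two tight clades joined by a long internal branch; with only two
  # clusters the within-clade pairs make up over a third of the whole
  # distance distribution, so the matching percentile is 40, not 10 (the
  # 10% convention presumes many clusters, as in the family-recovery test)
  tr <- ape::read.tree(text = paste0(
    "((a:0.01,(b:0.01,c:0.011):0.002):0.5,",
    "(d:0.01,(e:0.013,f:0.012):0.003):0.5);"))
  tr <- ape::unroot(tr)
  cl <- mppd_clusters(tr, percentile = 40, bootstrap_min = 0)
  fam <- setNames(cl$family, cl$haplotype)
  expect_equal(length(unique(fam)), 2)
  expect_equal(length(unique(fam[c("a", "b", "c")])), 1)
  expect_equal(length(unique(fam[c("d", "e", "f")])), 1)
  expect_true(all(!cl$singleton))

  # equidistant taxa: no clade is tighter than the whole, all singletons
  n <- 8
  D <- matrix(0.5, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(D) <- 0
  star <- nj_tree(D)
  cl_star <- mppd_clusters(star, percentile = 10, bootstrap_min = 0)
  expect_true(all(cl_star$singleton))
  expect_equal(length(unique(cl_star$family)), n)
})

test_that("MPPD percentile extremes collapse or shatter the partition", {
  cfg <- sim_config(seed = 19, n_families = 3, haps_per_family = 3)
  f <- simulate_founders(cfg)
  tr <- bootstrap_support(f, n_reps = 50, seed = 19)
  all_one <- mppd_clusters(tr, percentile = 100, bootstrap_min = 0)
  expect_equal(length(unique(all_one$family)), 1)
  shattered <- mppd_clusters(tr, percentile = 1e-7, bootstrap_min = 0)
  expect_true(all(shattered$singleton))
  expect_error(mppd_clusters(tr, percentile = 0),
               class = "bsnphap_value_error")
  expect_error(mppd_clusters(tr, percentile = 101),
               class = "bsnphap_value_error")
})

test_that("clusters failing the bootstrap constraint keep letters but are flagged",
{
  tr <- ape::read.tree(
    text = "((a:0.01,b:0.012):0.5,(d:0.01,e:0.013):0.5,(f:0.4,g:0.45):0.1);")
  tr$node.label <- c("", "60", "95", "88")   # support per internal node
  cl <- mppd_clusters(tr, percentile = 20, bootstrap_min = 70)
  ab <- cl[cl$haplotype %in% c("a", "b"), ]
  expect_equal(length(unique(ab$family)), 1)
  expect_true(all(!ab$meets_bootstrap))      # 60 < 70: dashed-line status
  de <- cl[cl$haplotype %in% c("d", "e"), ]
  expect_true(all(de$meets_bootstrap))
  # letters are contiguous from A
  expect_equal(sort(unique(cl$family)),
               LETTERS[seq_along(unique(cl$family))])
})

test_that("simulated haplotype families are recovered exactly", {
  skip_if_not_installed("mclust")
  for (s in 1:5) {
    cfg <- sim_config(seed = s, within_family_diff = 3,
                      between_family_diff = 30)
    f <- simulate_founders(cfg)
    cl <- cluster_haplotypes(f, percentile = 10, bootstrap_min = 70,
                             n_reps = 100, seed = s)
    ari <- mclust::adjustedRandIndex(
      cl$family[match(f$hap_id, cl$haplotype)], f$family)
    expect_equal(ari, 1)
  }
})

test_that("jackknife persistence is high for well-separated families", {
  cfg <- sim_config(seed = 23, n_families = 5, haps_per_family = 3,
                    within_family_diff = 3, between_family_diff = 30)
  f <- simulate_founders(cfg)
  js <- jackknife_stability(f, drop_fraction = 0.25, n_reps = 20, seed = 23,
                            boot_reps = 20)
  expect_equal(nrow(js), 5)
  # dropping a quarter of the leaves occasionally shrinks a family below
  # the percentile threshold; persistence stays high but not exactly 1
  expect_true(all(js$persistence >= 0.85))
  js2 <- jackknife_stability(f, drop_fraction = 0.25, n_reps = 20, seed = 23,
                             boot_reps = 20)
  expect_identical(js, js2)
  # dropping a single leaf still perturbs the percentile threshold when it
  # shrinks a family to two members, so even the small-drop limit is only
  # near-perfect
  js1 <- jackknife_stability(f, drop_fraction = 1 / 15, n_reps = 10,
                             seed = 23, boot_reps = 20)
  expect_true(all(js1$persistence >= 0.9))
  expect_error(jackknife_stability(f, drop_fraction = 0),
               class = "bsnphap_value_error")
})
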