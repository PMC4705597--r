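#' Uncorrected fractional dissimilarity between two haplotypes
#'
#' The proportion of core SNPs, among those where both haplotypes have a
#' call, at which the states differ. The dual-allele state `B` is a state of
#' its own; missing (`F`) positions are pairwise-deleted.
#'
#' @param a,b Haplotype state vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
fractional_dissimilarity <- function(a, b) {
  if (length(a) != length(b)) {
    abort("haplotype lengths differ", class = "bsnphap_value_error")
  }
  comp <- a != "F" & b != "F"
  if (!any(comp)) {
    abort("no comparable positions", class = "bsnphap_value_error")
  }
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Pairwise fractional dissimilarity matrix of a haplotype set
#'
#' Pairs sharing fewer than half of the core SNPs (after pairwise deletion
#' of missing calls) are refused rather than silently distanced.
#'
#' @param haps A [haplotype_set]; haplotype labels default to `hap_id`.
#' @param labels Optional character labels.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(haps, labels = NULL) {
  labels <- labels %||% haps$hap_id
  n <- nrow(haps)
  L <- length(haps$alleles[[1]])
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- haps$alleles[[i]]; b <- haps$alleles[[j]]
      comp <- sum(a != "F" & b != "F")
      if (comp < L / 2) {
        abort(sprintf("haplotypes %s and %s share fewer than half their sites",
                      labels[i], labels[j]), class = "bsnphap_value_error")
      }
      D[i, j] <- D[j, i] <- fractional_dissimilarity(a, b)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape); negative branch lengths are
#' clamped to zero.
#'
#' @param D Symmetric distance matrix with labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 2) {
    abort("at least two haplotypes are required", class = "bsnphap_value_error")
  }
  if (nrow(D) == 2) {
    # two taxa: a single branch, half the distance on each side
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(D)[1], D[1, 2] / 2,
                                        rownames(D)[2], D[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support from SNP resampling
#'
#' Core SNP columns are resampled with replacement; distances and the NJ
#' topology are recomputed per replicate. Each internal branch of the
#' original tree gets the percentage of replicates containing its
#' bipartition (stored in `node.label`); the majority-rule (>50%) consensus
#' is attached as `attr(, "consensus")`.
#'
#' @param haps A [haplotype_set] (at least 3 haplotypes).
#' @param n_reps Number of bootstrap replicates (the analysis convention is
#'   1000).
#' @param seed Integer seed.
#' @return A `phylo` tree with `node.label` support percentages.
#' @export
bootstrap_support <- function(haps, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1) abort("n_reps must be >= 1", class = "bsnphap_value_error")
  set.seed(seed)
  states <- do.call(rbind, haps$alleles)
  rownames(states) <- haps$hap_id
  dist_of <- function(S) {
    hs <- haps
    hs$alleles <- lapply(seq_len(nrow(S)), function(i) S[i, ])
    dissimilarity_matrix(hs)
  }
  tr <- nj_tree(dist_of(states))
  L <- ncol(states)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    reps[[r]] <- nj_tree(dist_of(states[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tr$node.label <- round(100 * counts / n_reps, 1)
  attr(tr, "consensus") <- ape::consensus(reps, p = 0.5)
  attr(tr, "n_reps") <- n_reps
  tr
}

#' Patristic distances between all nodes of a tree
#'
#' Path-length distance between every pair of nodes, internal and terminal.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A symmetric matrix over tips then internal nodes (ape node
#'   numbering).
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "bsnphap_value_error")
  }
  ape::dist.nodes(tree)
}

#' Cluster haplotypes into lettered families by MPPD percentile
#'
#' The tree is midpoint-rooted for clade enumeration. The similarity
#' threshold is the given percentile of the distribution of pairwise
#' patristic distances over all nodes (internal and terminal) of the
#' topology. Candidate clusters are the maximal clades whose median
#' pairwise patristic distance (MPPD, over all nodes in the clade) does not
#' exceed the threshold; each is additionally checked against the bootstrap
#' support of its subtending branch. Leaves in no multi-member cluster
#' become singleton families. Letters A, B, C, ... are assigned in tree
#' (leaf traversal) order, singletons included.
#'
#' @param tree A `phylo` tree, typically from [bootstrap_support()] so that
#'   `node.label` carries supports.
#' @param percentile MPPD percentile in (0, 100); the analysis convention
#'   is 10.
#' @param bootstrap_min Minimum bootstrap support for a fully reliable
#'   cluster (the analysis convention is 70); clusters below it keep their
#'   letter but are flagged `meets_bootstrap = FALSE`.
#' @return A tibble of class `bsnp_clusters`: `haplotype`, `family`,
#'   `mppd`, `bootstrap`, `meets_mppd`, `meets_bootstrap`, `singleton`;
#'   the rooted tree and threshold are attributes.
#' @export
mppd_clusters <- function(tree, percentile = 10, bootstrap_min = 70) {
  if (percentile <= 0 || percentile > 100) {
    abort("percentile must be in (0, 100]", class = "bsnphap_value_error")
  }
  n_tip <- length(tree$tip.label)
  supports <- if (!is.null(tree$node.label)) {
    suppressWarnings(as.numeric(tree$node.label))
  } else rep(NA_real_, tree$Nnode)
  rooted <- phangorn::midpoint(tree, node.labels = "label")
  r_support <- if (!is.null(rooted$node.label)) {
    suppressWarnings(as.numeric(rooted$node.label))
  } else rep(NA_real_, rooted$Nnode)
  dn <- patristic_matrix(rooted)
  # threshold over all node pairs of the topology
  threshold <- unname(quantile(dn[upper.tri(dn)], percentile / 100))
  desc <- phangorn::Descendants(rooted, type = "all")
  root_node <- n_tip + 1L
  clade_nodes <- function(node) c(node, desc[[node]])
  clade_mppd <- function(nodes) {
    if (length(nodes) < 2) return(0)
    sub <- dn[nodes, nodes]
    median(sub[upper.tri(sub)])
  }
  # maximal clades under the threshold: walk down from the root, stop at the
  # first internal node whose MPPD is within the threshold
  selected <- integer(0)
  walk <- function(node) {
    if (node <= n_tip) return()
    if (clade_mppd(clade_nodes(node)) <= threshold) {
      selected <<- c(selected, node)
      return()
    }
    kids <- rooted$edge[rooted$edge[, 1] == node, 2]
    for (k in kids) walk(k)
  }
  walk(root_node)
  fam <- rep(NA_integer_, n_tip)
  mppd_v <- rep(NA_real_, n_tip)
  boot_v <- rep(NA_real_, n_tip)
  singleton <- rep(TRUE, n_tip)
  cluster_id <- 0L
  # leaves in traversal order so letters run along the tree
  leaf_order <- rooted$edge[rooted$edge[, 2] <= n_tip, 2]
  assigned_cluster <- rep(NA_integer_, length(selected))
  for (tip in leaf_order) {
    if (!is.na(fam[tip])) next
    sel <- which(vapply(selected, function(nd) tip %in% clade_nodes(nd),
                        logical(1)))
    cluster_id <- cluster_id + 1L
    if (length(sel) > 0) {
      nd <- selected[sel[1]]
      tips <- intersect(clade_nodes(nd), seq_len(n_tip))
      fam[tips] <- cluster_id
      mppd_v[tips] <- clade_mppd(clade_nodes(nd))
      boot_v[tips] <- if (nd == root_node) NA_real_ else
        r_support[nd - n_tip]
      singleton[tips] <- length(tips) == 1
    } else {
      fam[tip] <- cluster_id
      mppd_v[tip] <- 0
      singleton[tip] <- TRUE
    }
  }
  letters_of <- function(i) {
    if (i <= 26) LETTERS[i] else
      paste0(LETTERS[(i - 1) %/% 26], LETTERS[(i - 1) %% 26 + 1])
  }
  out <- tibble::tibble(
    haplotype = rooted$tip.label,
    family = vapply(fam, letters_of, character(1)),
    mppd = mppd_v,
    bootstrap = boot_v,
    meets_mppd = TRUE,
    meets_bootstrap = singleton | (!is.na(boot_v) & boot_v >= bootstrap_min),
    singleton = singleton)
  structure(out, tree = rooted, threshold = threshold,
            percentile = percentile, bootstrap_min = bootstrap_min,
            class = c("bsnp_clusters", class(tibble::tibble())))
}

#' End-to-end haplotype family clustering
#'
#' Distance matrix, NJ tree, bootstrap supports and MPPD-percentile
#' clustering in one call.
#'
#' @param haps A [haplotype_set] with at least 3 haplotypes.
#' @param percentile,bootstrap_min See [mppd_clusters()].
#' @param n_reps,seed See [bootstrap_support()].
#' @return A `bsnp_clusters` tibble (see [mppd_clusters()]).
#' @export
cluster_haplotypes <- function(haps, percentile = 10, bootstrap_min = 70,
                               n_reps = 1000L, seed = 1L) {
  tr <- bootstrap_support(haps, n_reps = n_reps, seed = seed)
  mppd_clusters(tr, percentile = percentile, bootstrap_min = bootstrap_min)
}

#' Jackknife stability of haplotype families
#'
#' Repeats the clustering on random leaf subsets and reports, for each
#' original multi-member family, the fraction of replicates in which its
#' retained members (when at least two are retained) still share one
#' family.
#'
#' @param haps A [haplotype_set].
#' @param drop_fraction Fraction of haplotypes dropped per replicate, in
#'   (0, 1).
#' @param n_reps Number of jackknife replicates.
#' @param seed Integer seed.
#' @param percentile,bootstrap_min,boot_reps Clustering parameters per
#'   replicate.
#' @return A tibble: `family`, `n_members`, `n_informative_reps`,
#'   `persistence`.
#' @export
jackknife_stability <- function(haps, drop_fraction = 0.2, n_reps = 100L,
                                seed = 1L, percentile = 10,
                                bootstrap_min = 0, boot_reps = 50L) {
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    abort("drop_fraction must be in (0, 1)", class = "bsnphap_value_error")
  }
  set.seed(seed)
  base <- cluster_haplotypes(haps, percentile, bootstrap_min,
                             n_reps = boot_reps, seed = seed)
  fams <- split(base$haplotype, base$family)
  fams <- fams[lengths(fams) >= 2]
  n <- nrow(haps)
  n_drop <- max(1L, round(drop_fraction * n))
  hits <- setNames(numeric(length(fams)), names(fams))
  informative <- setNames(integer(length(fams)), names(fams))
  for (r in seq_len(n_reps)) {
    keep <- sort(sample.int(n, n - n_drop))
    if (length(keep) < 3) next
    sub <- new_haplotype_set(tibble::as_tibble(haps)[keep, ], panel_of(haps))
    cl <- cluster_haplotypes(sub, percentile, bootstrap_min,
                             n_reps = boot_reps, seed = seed + r)
    for (f in names(fams)) {
      members <- intersect(fams[[f]], cl$haplotype)
      if (length(members) < 2) next
      informative[f] <- informative[f] + 1L
      if (length(unique(cl$family[cl$haplotype %in% members])) == 1) {
        hits[f] <- hits[f] + 1
      }
    }
  }
  tibble::tibble(family = names(fams),
                 n_members = lengths(fams),
                 n_informative_reps = unname(informative),
                 persistence = unname(ifelse(informative > 0,
                                             hits / informative, NA_real_)))
}
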