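#' Core-SNP call codes of a genotype matrix
#'
#' @param m A [genotype_matrix].
#' @return Character matrix birds x core SNPs (rownames = bird ids).
#' @export
core_codes <- function(m) {
  panel <- panel_of(m)
  call_matrix(m)[, panel$snp[panel$in_core], drop = FALSE]
}

# haplotype state read directly off a non-heterozygous call
state_from_code <- c(XX = "X", YY = "Y", AMBIG_BOTH = "B", FAIL = "F",
                     DUP_XXY = "B", DUP_XYY = "B")

# is `hap` (states X/Y/B/F) a possible component of genotype vector `g`
# (canonical codes)? F in the haplotype is compatible everywhere; AMBIG and
# FAIL genotypes constrain nothing.
hap_compatible <- function(hap, g) {
  ok <- (g == "XX" & hap %in% c("X", "F")) |
    (g == "YY" & hap %in% c("Y", "F")) |
    (g == "XY" & hap %in% c("X", "Y", "F")) |
    (g %in% c("AMBIG_BOTH", "DUP_XXY", "DUP_XYY", "FAIL"))
  all(ok)
}

#' Subtract a known haplotype from a diploid genotype vector
#'
#' The remaining haplotype takes the other allele at heterozygous SNPs, the
#' observed allele at homozygous SNPs, `B` at dual-allele SNPs and `F`
#' (missing) at failed SNPs. An allele conflict (e.g. genotype `XX` against
#' known allele `Y`) is an error naming the offending SNP.
#'
#' @param g Character vector of canonical call codes over the core SNPs.
#' @param known Haplotype state vector (X/Y/B/F) of the known component.
#' @param snp_names Optional SNP names used in error messages.
#' @return The complementary haplotype state vector.
#' @export
subtract_phase <- function(g, known, snp_names = NULL) {
  if (length(g) != length(known)) {
    abort("genotype and haplotype lengths differ",
          class = "bsnphap_value_error")
  }
  snp_names <- snp_names %||% as.character(seq_along(g))
  out <- character(length(g))
  for (i in seq_along(g)) {
    gi <- g[i]; ki <- known[i]
    out[i] <- switch(gi,
      XX = if (ki %in% c("X", "F")) "X" else NA_character_,
      YY = if (ki %in% c("Y", "F")) "Y" else NA_character_,
      XY = switch(ki, X = "Y", Y = "X", F = "F", NA_character_),
      AMBIG_BOTH = , DUP_XXY = , DUP_XYY = "B",
      FAIL = "F")
    if (is.na(out[i])) {
      abort(paste0("known haplotype incompatible with genotype at SNP ",
                   snp_names[i]), class = "bsnphap_subtraction_error")
    }
  }
  out
}

# read the haplotype pair of a bird with at most one heterozygous core SNP
unambiguous_pair <- function(g) {
  het <- which(g == "XY")
  if (length(het) > 1) return(NULL)
  base <- unname(state_from_code[g])
  if (length(het) == 0) return(list(base, base))
  h1 <- base; h2 <- base
  h1[het] <- "X"; h2[het] <- "Y"
  list(h1, h2)
}

#' Haplotypes defined by MHC-homozygous birds of one line
#'
#' A bird is homozygous when no core SNP is heterozygous (`XY`); dual-allele
#' and failed calls do not disqualify it (they become `B` and `F` states).
#' Identical haplotypes are collapsed with observation counts.
#'
#' @param m A [genotype_matrix].
#' @param line Line id.
#' @return A [haplotype_set] (possibly empty).
#' @export
haplotypes_from_homozygotes <- function(m, line) {
  if (!line %in% m$line_id) {
    abort(paste0("unknown line ", line), class = "bsnphap_value_error")
  }
  g <- core_codes(m)[m$line_id == line, , drop = FALSE]
  hom <- apply(g, 1, function(r) !any(r == "XY"))
  haps <- lapply(which(hom), function(i) unname(state_from_code[g[i, ]]))
  collapse_haps(haps, rownames(g)[hom], line, panel_of(m))
}

# collapse a list of haplotype vectors (one per carrying bird) into a set
# with counts and provenance
collapse_haps <- function(haps, bird_ids, line, panel) {
  if (length(haps) == 0) {
    out <- haplotype_set(list(), panel)
    return(out)
  }
  keys <- vapply(haps, paste, collapse = "", FUN.VALUE = character(1))
  ord <- !duplicated(keys)
  uniq <- haps[ord]
  counts <- as.integer(table(factor(keys, levels = keys[ord])))
  birds <- lapply(keys[ord], function(k) unique(bird_ids[keys == k]))
  haplotype_set(uniq, panel, count = counts,
                lines = rep(list(line), length(uniq)), birds = birds)
}

#' Infer the haplotypes segregating in one line
#'
#' Implements the iterative within-line procedure: (1) seed haplotypes from
#' birds whose phase is unambiguous (homozygous, or heterozygous at exactly
#' one core SNP, where the pair is read off directly); (2) for each remaining
#' heterozygous bird compatible with exactly one known haplotype, subtract it
#' and add the complementary haplotype; (3) repeat until a fixpoint. Birds
#' explained by a pair of known haplotypes add nothing; birds compatible
#' with none or with several known haplotypes (and no known pair) wait for
#' later rounds and are reported unresolved at the fixpoint.
#'
#' When stepwise subtraction stalls — heterozygous birds whose phase is only
#' determined jointly, not through any single known haplotype — a bounded
#' residual step enumerates all phasings of the remaining birds that add the
#' fewest new haplotypes and keeps the haplotypes common to all such minimal
#' completions. Residual birds with too many heterozygous SNPs (more than
#' `max_residual_hets`) are left unresolved rather than searched.
#'
#' @param m A [genotype_matrix].
#' @param line Line id.
#' @param max_rounds Iteration cap; defaults to the number of birds in the
#'   line (a fixpoint bound).
#' @param resolve_residual Run the joint residual step after the greedy
#'   fixpoint.
#' @param max_residual_hets Per-bird heterozygous-SNP cap for the residual
#'   search (its split count is `2^(hets-1)`).
#' @return A list of class `phasing_result`: `haplotypes` (a
#'   [haplotype_set]), `assignments` (bird id, the two haplotype keys, and
#'   how the bird was resolved) and `unresolved` (bird id and reason).
#' @export
infer_haplotypes <- function(m, line, max_rounds = NULL,
                             resolve_residual = TRUE,
                             max_residual_hets = 12L) {
  if (!line %in% m$line_id) {
    abort(paste0("unknown line ", line), class = "bsnphap_value_error")
  }
  g_all <- core_codes(m)[m$line_id == line, , drop = FALSE]
  n <- nrow(g_all)
  max_rounds <- max_rounds %||% n
  known <- list(); known_keys <- character(0)
  add_known <- function(h) {
    k <- paste(h, collapse = "")
    if (!k %in% known_keys) {
      known[[length(known) + 1]] <<- h
      known_keys <<- c(known_keys, k)
    }
    k
  }
  asn <- tibble::tibble(bird_id = rownames(g_all),
                        hap1 = NA_character_, hap2 = NA_character_,
                        method = NA_character_)
  # seed: unambiguous birds
  for (i in seq_len(n)) {
    pr <- unambiguous_pair(g_all[i, ])
    if (!is.null(pr)) {
      asn$hap1[i] <- add_known(pr[[1]])
      asn$hap2[i] <- add_known(pr[[2]])
      asn$method[i] <- if (identical(pr[[1]], pr[[2]])) "homozygous"
        else "single_het"
    }
  }
  snp_names <- colnames(g_all)
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (i in which(is.na(asn$method))) {
      g <- g_all[i, ]
      comp <- which(vapply(known, hap_compatible, logical(1), g = g))
      if (length(comp) == 0) next
      comps <- lapply(comp, function(j) subtract_phase(g, known[[j]], snp_names))
      comp_keys <- vapply(comps, paste, collapse = "", FUN.VALUE = character(1))
      hit <- which(comp_keys %in% known_keys)
      if (length(hit) > 0) {
        asn$hap1[i] <- known_keys[comp[hit[1]]]
        asn$hap2[i] <- comp_keys[hit[1]]
        asn$method[i] <- "explained"
        changed <- TRUE
      } else if (length(comp) == 1) {
        asn$hap1[i] <- known_keys[comp]
        asn$hap2[i] <- add_known(comps[[1]])
        asn$method[i] <- "subtraction"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # certainty pass: on small problems, re-phase all non-seed birds jointly
  # against the seed haplotypes, keeping only haplotypes present in every
  # phasing that adds the fewest new haplotypes. This both completes
  # stepwise subtraction (jointly-determined haplotypes it cannot reach)
  # and discards subtracted haplotypes that an alternative minimal phasing
  # avoids. On problems too large to search, the greedy chain stands.
  if (resolve_residual && !all(asn$method %in% c("homozygous", "single_het"))) {
    seed_idx <- which(asn$method %in% c("homozygous", "single_het"))
    seed_keys <- unique(stats::na.omit(c(asn$hap1[seed_idx],
                                         asn$hap2[seed_idx])))
    resid <- setdiff(seq_len(n), seed_idx)
    n_het <- vapply(resid, function(i) sum(g_all[i, ] == "XY"), integer(1))
    searchable <- resid
    feasible <- length(resid) <= 24 && all(n_het <= max_residual_hets) &&
      sum(pmax(n_het - 1, 0)) <= 30
    if (feasible && length(searchable) > 0) {
      splits_of <- function(g) {
        het <- which(g == "XY")
        base <- unname(state_from_code[ifelse(g == "XY", "FAIL", g)])
        k <- length(het)
        lapply(seq_len(2^(k - 1)) - 1L, function(mask) {
          bits <- as.integer(intToBits(mask))[seq_len(max(k - 1, 1))]
          h1 <- base; h2 <- base
          h1[het[1]] <- "X"; h2[het[1]] <- "Y"
          if (k > 1) for (b in seq_len(k - 1)) {
            if (bits[b] == 1L) { h1[het[b + 1]] <- "Y"; h2[het[b + 1]] <- "X" }
            else { h1[het[b + 1]] <- "X"; h2[het[b + 1]] <- "Y" }
          }
          list(h1 = h1, h2 = h2,
               k1 = paste(h1, collapse = ""), k2 = paste(h2, collapse = ""))
        })
      }
      bird_splits <- lapply(searchable, function(i) splits_of(g_all[i, ]))
      ord2 <- order(lengths(bird_splits))
      bird_splits <- bird_splits[ord2]
      searchable <- searchable[ord2]
      best_new <- Inf; sols <- list()
      nodes <- 0L; overflow <- FALSE
      dfs <- function(bi, new_keys, picks) {
        nodes <<- nodes + 1L
        if (nodes > 2e5) { overflow <<- TRUE; return() }
        if (length(new_keys) > best_new) return()
        if (bi > length(bird_splits)) {
          if (length(new_keys) < best_new) {
            best_new <<- length(new_keys); sols <<- list()
          }
          sols[[length(sols) + 1]] <<- list(new = sort(new_keys),
                                            picks = picks)
          return()
        }
        for (sp in bird_splits[[bi]]) {
          add <- setdiff(c(sp$k1, sp$k2), c(seed_keys, new_keys))
          dfs(bi + 1, c(new_keys, add), c(picks, list(c(sp$k1, sp$k2))))
        }
      }
      dfs(1, character(0), list())
      if (length(sols) > 0 && !overflow) {
        forced_new <- Reduce(intersect, lapply(sols, `[[`, "new"))
        key_to_hap <- list()
        for (s in sols) for (p in s$picks) for (kk in p) {
          if (!kk %in% names(key_to_hap)) {
            key_to_hap[[kk]] <- strsplit(kk, "")[[1]]
          }
        }
        # the certain set replaces the greedy chain: seeds plus haplotypes
        # present in every minimal phasing
        known <- c(known[match(seed_keys, known_keys)],
                   lapply(forced_new, function(kk) key_to_hap[[kk]]))
        known_keys <- c(seed_keys, forced_new)
        for (bi in seq_along(searchable)) {
          i <- searchable[bi]
          pairs <- unique(lapply(sols, function(s) sort(s$picks[[bi]])))
          if (length(pairs) == 1) {
            asn$hap1[i] <- pairs[[1]][1]
            asn$hap2[i] <- pairs[[1]][2]
            asn$method[i] <- "joint"
          } else {
            asn$hap1[i] <- NA_character_
            asn$hap2[i] <- NA_character_
            asn$method[i] <- NA_character_
          }
        }
      }
    }
  }
  unresolved_idx <- which(is.na(asn$method))
  reasons <- vapply(unresolved_idx, function(i) {
    g <- g_all[i, ]
    k <- sum(vapply(known, hap_compatible, logical(1), g = g))
    if (k == 0) "no compatible known haplotype" else
      sprintf("ambiguous: %d compatible known haplotypes", k)
  }, character(1))
  carried <- c(asn$hap1, asn$hap2)
  birds2 <- c(asn$bird_id, asn$bird_id)
  keep <- !is.na(carried)
  haps <- known
  keys <- known_keys
  counts <- vapply(keys, function(k)
    length(unique(birds2[keep & carried == k])), integer(1))
  hs <- haplotype_set(haps, panel_of(m), count = unname(counts),
                      lines = rep(list(line), length(haps)),
                      birds = lapply(keys, function(k)
                        unique(birds2[keep & carried == k])))
  structure(list(haplotypes = hs,
                 assignments = asn,
                 unresolved = tibble::tibble(
                   bird_id = asn$bird_id[unresolved_idx], reason = reasons),
                 line = line),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf(
    "Phasing of line %s: %d haplotypes, %d/%d birds resolved\n",
    x$line, nrow(x$haplotypes),
    sum(!is.na(x$assignments$method)), nrow(x$assignments)))
  invisible(x)
}

#' Reconcile independently inferred haplotype sets across lines
#'
#' Haplotypes identical over their non-missing core positions are merged:
#' missing (`F`) positions fill from the counterpart, counts add, and
#' provenance (lines, birds) unions. Haplotypes disagreeing at any position
#' where both are non-missing stay distinct. Merging is greedy in order of
#' decreasing observation count, so missing calls fill from the
#' best-supported counterpart.
#'
#' @param sets A list of [haplotype_set] objects (or `phasing_result`s)
#'   sharing one panel; a single set may be passed to self-reconcile.
#' @return A merged [haplotype_set].
#' @export
reconcile_haplotypes <- function(sets) {
  if (inherits(sets, "haplotype_set") || inherits(sets, "phasing_result")) {
    sets <- list(sets)
  }
  sets <- lapply(sets, function(s)
    if (inherits(s, "phasing_result")) s$haplotypes else s)
  panel <- panel_of(sets[[1]])
  all_haps <- dplyr::bind_rows(lapply(sets, tibble::as_tibble))
  if (nrow(all_haps) == 0) return(haplotype_set(list(), panel))
  all_haps <- all_haps[order(-all_haps$count, hap_key(all_haps$alleles)), ]
  merged <- list()  # each: alleles, count, lines, birds, lei, serology
  matches_no_conflict <- function(a, b) {
    comp <- a != "F" & b != "F"
    all(a[comp] == b[comp])
  }
  for (i in seq_len(nrow(all_haps))) {
    a <- all_haps$alleles[[i]]
    placed <- FALSE
    for (j in seq_along(merged)) {
      b <- merged[[j]]$alleles
      if (matches_no_conflict(a, b)) {
        fill <- b == "F" & a != "F"
        b[fill] <- a[fill]
        merged[[j]]$alleles <- b
        merged[[j]]$count <- merged[[j]]$count + all_haps$count[i]
        merged[[j]]$lines <- union(merged[[j]]$lines, all_haps$lines[[i]])
        merged[[j]]$birds <- union(merged[[j]]$birds, all_haps$birds[[i]])
        merged[[j]]$lei <- sort(union(merged[[j]]$lei, all_haps$lei[[i]]))
        merged[[j]]$serology <- union(merged[[j]]$serology,
                                      all_haps$serology[[i]])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      merged[[length(merged) + 1]] <- list(
        alleles = a, count = all_haps$count[i],
        lines = all_haps$lines[[i]], birds = all_haps$birds[[i]],
        lei = all_haps$lei[[i]], serology = all_haps$serology[[i]])
    }
  }
  haplotype_set(lapply(merged, `[[`, "alleles"), panel,
                count = vapply(merged, `[[`, numeric(1), "count"),
                lines = lapply(merged, `[[`, "lines"),
                birds = lapply(merged, `[[`, "birds"),
                lei = lapply(merged, function(x) as.integer(x$lei)),
                serology = lapply(merged, `[[`, "serology"))
}

#' Exhaustive parsimony phasing of a small line (reference algorithm)
#'
#' Enumerates, by depth-first search with branch-and-bound, every phasing of
#' a line (an assignment of a haplotype pair to every bird reproducing its
#' genotypes) that uses the minimum possible number of distinct haplotypes,
#' and reports the haplotypes common to all minimum-cardinality phasings.
#' Intended as an independent reference for [infer_haplotypes()] on small
#' problems; cost grows exponentially with birds and heterozygous SNPs.
#'
#' @param g Character matrix (birds x core SNPs) of codes `XX`, `YY`, `XY`.
#' @return A list: `min_haps` (the minimum number of distinct haplotypes),
#'   `n_solutions`, and `forced` (keys of haplotypes present in every
#'   minimum-cardinality phasing).
#' @export
enumerate_parsimony_phasings <- function(g) {
  if (any(!(g %in% c("XX", "YY", "XY")))) {
    abort("reference phasing enumerator handles XX/YY/XY codes only",
          class = "bsnphap_value_error")
  }
  n <- nrow(g)
  pairs_of <- function(row) {
    het <- which(row == "XY")
    base <- ifelse(row == "XX", "X", "Y")
    k <- length(het)
    if (k == 0) {
      key <- paste(base, collapse = "")
      return(list(c(key, key)))
    }
    lapply(seq_len(2^(k - 1)) - 1L, function(mask) {
      bits <- as.integer(intToBits(mask))[seq_len(max(k - 1, 1))]
      h1 <- base; h2 <- base
      h1[het[1]] <- "X"; h2[het[1]] <- "Y"
      if (k > 1) {
        for (b in seq_len(k - 1)) {
          if (bits[b] == 1L) {
            h1[het[b + 1]] <- "Y"; h2[het[b + 1]] <- "X"
          } else {
            h1[het[b + 1]] <- "X"; h2[het[b + 1]] <- "Y"
          }
        }
      }
      c(paste(h1, collapse = ""), paste(h2, collapse = ""))
    })
  }
  bird_pairs <- lapply(seq_len(n), function(i) pairs_of(g[i, ]))
  ord <- order(lengths(bird_pairs))
  bird_pairs <- bird_pairs[ord]
  best <- Inf
  solutions <- list()
  dfs <- function(i, used) {
    if (length(used) > best) return()
    if (i > n) {
      if (length(used) < best) {
        best <<- length(used)
        solutions <<- list(sort(used))
      } else {
        solutions <<- unique(c(solutions, list(sort(used))))
      }
      return()
    }
    for (p in bird_pairs[[i]]) {
      dfs(i + 1, union(used, p))
    }
  }
  dfs(1, character(0))
  forced <- Reduce(intersect, solutions)
  list(min_haps = best, n_solutions = length(solutions), forced = forced)
}
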