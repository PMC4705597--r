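#' Localize a crossover breakpoint between two parental haplotypes
#'
#' Informative sites are core SNPs where the two parents differ and all
#' three haplotypes have calls. The breakpoint interval runs from the last
#' informative SNP at which the recombinant matches the 5' parent to the
#' first subsequent informative SNP at which it matches the 3' parent;
#' crossovers inside parental identity blocks cannot be localized more
#' precisely than this interval. Sites matching neither parent are excluded
#' (they are mutation/deletion candidates, flagged by the caller).
#'
#' @param rec,p5,p3 Haplotype state vectors over the core SNPs.
#' @param panel The [snp_panel].
#' @return Named integer vector `c(start_bp, end_bp)`.
#' @export
localize_breakpoint <- function(rec, p5, p3, panel) {
  core <- core_snps(panel)
  informative <- p5 != p3 & rec != "F" & p5 != "F" & p3 != "F"
  m5 <- informative & rec == p5
  m3 <- informative & rec == p3
  use <- m5 | m3
  if (!any(m5) || !any(m3)) {
    abort("no breakpoint: recombinant matches a single parent at all informative sites",
          class = "bsnphap_breakpoint_error")
  }
  idx <- which(use)
  pattern <- m5[idx]
  switch_at <- which(!pattern)[1]
  if (any(pattern[switch_at:length(pattern)])) {
    abort("not a single-breakpoint mosaic of the given parents",
          class = "bsnphap_breakpoint_error")
  }
  start <- core$position_bp[idx[switch_at - 1]]
  end <- core$position_bp[idx[switch_at]]
  c(start_bp = start, end_bp = end)
}

# best single-breakpoint fit of candidate against an ordered parent pair:
# minimal number of exception sites over all split points, restricted to
# sites where candidate and the relevant parent both have calls
mosaic_fit <- function(cand, p5, p3) {
  L <- length(cand)
  mm5 <- cand != p5 & cand != "F" & p5 != "F"
  mm3 <- cand != p3 & cand != "F" & p3 != "F"
  pre <- cumsum(mm5)                       # mismatches if prefix ends at k
  suf <- rev(cumsum(rev(mm3)))             # mismatches from k..L as suffix
  tot <- c(suf[1], pre[-L] + suf[-1], pre[L])  # split after k = 0..L
  k <- which.min(tot) - 1L
  list(mismatches = tot[k + 1], split = k,
       mismatch_sites = which((seq_len(L) <= k & mm5) |
                                (seq_len(L) > k & mm3)))
}

#' Detect recombinant haplotypes against a population haplotype set
#'
#' A candidate haplotype absent from the population set is called
#' recombinant when it is a single-breakpoint mosaic of an ordered pair of
#' population haplotypes with at most `max_mismatches` exception SNPs, and
#' both parents are present in the same population — candidates whose best
#' mosaic lacks a second parental match are reported separately as apparent
#' recombination. Among valid parent pairs the call minimizes mismatches,
#' then maximizes the breakpoint interval width. Mismatch SNPs are annotated
#' as putative mutation (allele in neither parent) or deletion (failed in
#' recombinant and one parent).
#'
#' @param candidates A [haplotype_set] of candidate haplotypes (typically a
#'   line's inferred set; members of `population` are skipped).
#' @param population A [haplotype_set]: the haplotypes established in the
#'   same population/line.
#' @param max_mismatches Maximum exception SNPs tolerated (default 1).
#' @return A list of class `recombinant_scan`: `calls` (one row per
#'   recombinant: name, candidate/parent ids, breakpoint interval,
#'   mismatches) and `apparent` (candidates with evidence of recombination
#'   that fail the both-parents rule).
#' @export
detect_recombinants <- function(candidates, population, max_mismatches = 1L) {
  panel <- panel_of(candidates)
  core <- core_snps(panel)
  pop_keys <- hap_key(population)
  cand_idx <- which(!(hap_key(candidates) %in% pop_keys))
  calls <- list(); apparent <- list()
  n_pop <- nrow(population)
  for (ci in cand_idx) {
    cand <- candidates$alleles[[ci]]
    best <- NULL
    partial <- FALSE
    if (n_pop >= 2) {
      for (i5 in seq_len(n_pop)) for (i3 in seq_len(n_pop)) {
        if (i5 == i3) next
        p5 <- population$alleles[[i5]]; p3 <- population$alleles[[i3]]
        fit <- mosaic_fit(cand, p5, p3)
        if (fit$mismatches > max_mismatches) next
        clean <- cand
        clean[fit$mismatch_sites] <- "F"   # exceptions excluded from localization
        iv <- tryCatch(localize_breakpoint(clean, p5, p3, panel),
                       error = function(e) NULL)
        if (is.null(iv)) { partial <- TRUE; next }
        width <- iv["end_bp"] - iv["start_bp"]
        cand_rec <- list(i5 = i5, i3 = i3, fit = fit, iv = iv, width = width)
        if (is.null(best) ||
            fit$mismatches < best$fit$mismatches ||
            (fit$mismatches == best$fit$mismatches && width > best$width)) {
          best <- cand_rec
        }
      }
    }
    if (is.null(best)) {
      apparent[[length(apparent) + 1]] <- tibble::tibble(
        hap_id = candidates$hap_id[ci], key = hap_key(candidates)[ci],
        reason = if (partial) "single-breakpoint fit exists but breakpoint not localizable"
          else "no parental pair within the population")
      next
    }
    mm <- best$fit$mismatch_sites
    mm_ann <- vapply(mm, function(s) {
      p5a <- population$alleles[[best$i5]][s]
      p3a <- population$alleles[[best$i3]][s]
      if (cand[s] == "F" || p5a == "F" || p3a == "F") "deletion" else "mutation"
    }, character(1))
    calls[[length(calls) + 1]] <- tibble::tibble(
      hap_id = candidates$hap_id[ci],
      key = hap_key(candidates)[ci],
      p5_id = population$hap_id[best$i5],
      p3_id = population$hap_id[best$i3],
      interval_start_bp = unname(best$iv["start_bp"]),
      interval_end_bp = unname(best$iv["end_bp"]),
      n_mismatches = best$fit$mismatches,
      mismatch_snps = list(core$snp[mm]),
      mismatch_type = list(mm_ann))
  }
  calls <- if (length(calls)) dplyr::bind_rows(calls) else
    tibble::tibble(hap_id = character(0), key = character(0),
                   p5_id = character(0), p3_id = character(0),
                   interval_start_bp = integer(0), interval_end_bp = integer(0),
                   n_mismatches = integer(0), mismatch_snps = list(),
                   mismatch_type = list())
  if (nrow(calls) > 0) {
    calls$name <- vapply(seq_len(nrow(calls)), bsnp_rec_name, character(1))
  } else calls$name <- character(0)
  structure(list(calls = calls,
                 apparent = if (length(apparent)) dplyr::bind_rows(apparent)
                   else tibble::tibble(hap_id = character(0),
                                       key = character(0),
                                       reason = character(0)),
                 panel = panel),
            class = "recombinant_scan")
}

# can haplotype h be attributed to a parent carrying pair (pa, pb):
# identical to one of them, or a clean single-breakpoint mosaic of the two
attributable_to <- function(h, pa, pb, panel) {
  key <- paste(h, collapse = "")
  if (key == paste(pa, collapse = "") || key == paste(pb, collapse = "")) {
    return(TRUE)
  }
  for (pr in list(list(pa, pb), list(pb, pa))) {
    fit <- mosaic_fit(h, pr[[1]], pr[[2]])
    if (fit$mismatches == 0) {
      iv <- tryCatch(localize_breakpoint(h, pr[[1]], pr[[2]], panel),
                     error = function(e) NULL)
      if (!is.null(iv)) return(TRUE)
    }
  }
  FALSE
}

#' Scan one line for recombinant haplotypes
#'
#' Phases the line, treats well-supported haplotypes (observed in at least
#' `established_min_count` birds) as the population set, and scans the rest
#' with [detect_recombinants()]. Birds the phasing leaves unresolved —
#' typically heterozygotes compatible with more than one known haplotype —
#' are then examined individually: every complement against a compatible
#' established haplotype is tested as a recombinant candidate, and when the
#' line is pedigreed each candidate pair is additionally required to be
#' attributable to the bird's parents (each haplotype identical to, or a
#' clean mosaic of, one parent's pair). One call at most is emitted per
#' unresolved bird (fewest mismatches, then widest interval).
#'
#' @param m A [genotype_matrix].
#' @param line Line id.
#' @param max_mismatches Passed to [detect_recombinants()].
#' @param established_min_count Minimum observation count for a haplotype
#'   to act as a potential parent.
#' @param use_pedigree Use sire/dam haplotype assignments to filter
#'   candidate pairs when pedigree columns are present.
#' @param phasing Optional precomputed [infer_haplotypes()] result.
#' @return A `recombinant_scan`; calls carry a `bird_ids` list-column.
#' @export
scan_line_recombinants <- function(m, line, max_mismatches = 1L,
                                   established_min_count = 2L,
                                   use_pedigree = TRUE, phasing = NULL) {
  panel <- panel_of(m)
  res <- phasing %||% infer_haplotypes(m, line)
  hs <- res$haplotypes
  est <- new_haplotype_set(
    tibble::as_tibble(hs)[hs$count >= established_min_count, ], panel)
  cand <- new_haplotype_set(
    tibble::as_tibble(hs)[hs$count < established_min_count, ], panel)
  sc <- detect_recombinants(cand, est, max_mismatches)
  calls <- sc$calls
  if (nrow(calls) > 0) {
    calls$bird_ids <- cand$birds[match(calls$hap_id, cand$hap_id)]
  } else calls$bird_ids <- list()
  apparent <- sc$apparent

  has_ped <- use_pedigree &&
    all(c("sire_id", "dam_id") %in% names(m))
  g_core <- core_codes(m)
  asn <- res$assignments
  pair_of <- function(bird) {
    i <- match(bird, asn$bird_id)
    if (is.na(i) || is.na(asn$hap1[i])) return(NULL)
    list(strsplit(asn$hap1[i], "")[[1]], strsplit(asn$hap2[i], "")[[1]])
  }
  for (bird in res$unresolved$bird_id) {
    g <- g_core[bird, ]
    comp_idx <- which(vapply(est$alleles, hap_compatible, logical(1), g = g))
    if (length(comp_idx) == 0) next
    options <- list()
    for (j in comp_idx) {
      h <- est$alleles[[j]]
      comp <- subtract_phase(g, h)
      if (paste(comp, collapse = "") %in% hap_key(est)) next
      if (has_ped) {
        row <- tibble::as_tibble(m)[m$bird_id == bird, ]
        sp <- pair_of(row$sire_id[1]); dp <- pair_of(row$dam_id[1])
        if (!is.null(sp) && !is.null(dp)) {
          ok <- (attributable_to(h, sp[[1]], sp[[2]], panel) &&
                   attributable_to(comp, dp[[1]], dp[[2]], panel)) ||
            (attributable_to(h, dp[[1]], dp[[2]], panel) &&
               attributable_to(comp, sp[[1]], sp[[2]], panel))
          if (!ok) next
        }
      }
      options[[length(options) + 1]] <- comp
    }
    if (length(options) == 0) next
    opt_set <- haplotype_set(options, panel)
    opt_set$hap_id <- paste0(bird, "_c", seq_along(options))
    sc_b <- detect_recombinants(opt_set, est, max_mismatches)
    if (nrow(sc_b$calls) == 0) {
      apparent <- dplyr::bind_rows(apparent, tibble::tibble(
        hap_id = bird, key = NA_character_,
        reason = "unresolved bird: no complement forms a valid mosaic"))
      next
    }
    b_calls <- sc_b$calls
    b_calls <- b_calls[order(b_calls$n_mismatches,
                             -(b_calls$interval_end_bp -
                                 b_calls$interval_start_bp),
                             b_calls$key), ]
    pick <- b_calls[1, ]
    pick$bird_ids <- list(bird)
    calls <- dplyr::bind_rows(calls, pick)
  }
  calls <- calls[!duplicated(calls$key), , drop = FALSE]
  if (nrow(calls) > 0) {
    calls$name <- vapply(seq_len(nrow(calls)), bsnp_rec_name, character(1))
  }
  structure(list(calls = calls, apparent = apparent, panel = panel),
            class = "recombinant_scan")
}

#' @export
print.recombinant_scan <- function(x, ...) {
  cat(sprintf("Recombinant scan: %d call(s), %d apparent (excluded)\n",
              nrow(x$calls), nrow(x$apparent)))
  invisible(x)
}

#' Profile recombination intervals in fixed-width bins
#'
#' Each unique recombinant haplotype contributes once; a bin is counted when
#' it is contained in the breakpoint interval (`mode = "contained"`, the
#' default: the bin lies inside the region where the crossover must have
#' occurred) or when it merely overlaps it (`mode = "overlap"`). Hotspots
#' are maximal runs of bins whose count reaches `threshold`, lettered A, B,
#' C, ... in coordinate order.
#'
#' @param calls A `recombinant_scan` or a data frame with columns `key`,
#'   `interval_start_bp`, `interval_end_bp`.
#' @param panel The [snp_panel] (supplies the reference length).
#' @param bin_size Bin width in bp (the analysis convention is 1000).
#' @param threshold Minimum unique-recombinant count for a hotspot bin
#'   (the analysis convention is 4).
#' @param mode Bin counting rule, `"contained"` or `"overlap"`.
#' @return A tibble of class `hotspot_profile` (`bin_start`, `bin_end`,
#'   `count`, `hotspot`, `letter`) with the hotspot intervals in
#'   `attr(, "hotspots")`.
#' @export
hotspot_profile <- function(calls, panel, bin_size = 1000L, threshold = 4L,
                            mode = c("contained", "overlap")) {
  mode <- match.arg(mode)
  if (bin_size <= 0) {
    abort("bin_size must be positive", class = "bsnphap_value_error")
  }
  if (inherits(calls, "recombinant_scan")) calls <- calls$calls
  calls <- tibble::as_tibble(calls)
  calls <- calls[!duplicated(calls$key), , drop = FALSE]
  ref_len <- attr(panel, "reference_length")
  starts <- seq(0L, ref_len - 1L, by = bin_size)
  bins <- tibble::tibble(bin_start = starts, bin_end = starts + bin_size,
                         count = 0L)
  for (i in seq_len(nrow(calls))) {
    s <- calls$interval_start_bp[i]; e <- calls$interval_end_bp[i]
    hit <- if (mode == "contained") bins$bin_start >= s & bins$bin_end <= e
      else bins$bin_end > s & bins$bin_start < e
    bins$count[hit] <- bins$count[hit] + 1L
  }
  bins$hotspot <- bins$count >= threshold
  runs <- rle(bins$hotspot)
  ends <- cumsum(runs$lengths)
  hot_runs <- which(runs$values)
  hotspots <- tibble::tibble(
    letter = LETTERS[seq_along(hot_runs)],
    start_bp = bins$bin_start[ends[hot_runs] - runs$lengths[hot_runs] + 1L],
    end_bp = bins$bin_end[ends[hot_runs]])
  bins$letter <- NA_character_
  for (i in seq_len(nrow(hotspots))) {
    in_run <- bins$bin_start >= hotspots$start_bp[i] &
      bins$bin_end <= hotspots$end_bp[i]
    bins$letter[in_run] <- hotspots$letter[i]
  }
  structure(bins, hotspots = hotspots, threshold = threshold,
            bin_size = bin_size, mode = mode,
            class = c("hotspot_profile", class(tibble::tibble())))
}

#' Hotspot intervals of a profile
#' @param profile A `hotspot_profile`.
#' @return Tibble with `letter`, `start_bp`, `end_bp`.
#' @export
hotspots <- function(profile) attr(profile, "hotspots")

#' Write hotspot intervals as a BED file
#'
#' BED is 0-based half-open; bin coordinates already are, so intervals are
#' written as-is with the hotspot letter in the name field.
#'
#' @param profile A `hotspot_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(profile, path) {
  hs <- hotspots(profile)
  bed <- tibble::tibble(chrom = "AB268588", start = hs$start_bp,
                        end = hs$end_bp, name = hs$letter)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

new_rate_estimate <- function(events, denominator, per_unit) {
  if (denominator <= 0) {
    abort("denominator must be positive", class = "bsnphap_value_error")
  }
  if (events < 0 || events > denominator) {
    abort("events must lie in 0..denominator", class = "bsnphap_value_error")
  }
  ci <- binom.test(events, denominator)$conf.int
  structure(list(events = as.integer(events),
                 denominator = as.integer(denominator),
                 per_unit = as.integer(per_unit),
                 rate = per_unit * events / denominator,
                 ci95 = per_unit * ci),
            class = "rate_estimate")
}

#' Recombination rate per 100 birds
#'
#' @param n_events Number of detected recombinant haplotypes.
#' @param n_birds Number of birds screened.
#' @return A `rate_estimate` (events, denominator, rate per 100, exact
#'   binomial 95% CI). The conventional report rounds to one decimal:
#'   7 events among 1189 birds is 0.6 per 100.
#' @export
recombination_rate <- function(n_events, n_birds) {
  new_rate_estimate(n_events, n_birds, 100L)
}

#' LEI0258 mutation rate per 1000 birds
#'
#' @param events Either an event count or a data frame of events with a
#'   `delta` column (bp size changes); deltas that are not multiples of the
#'   12/13-bp repeat units are flagged with a warning but still counted.
#' @param n_birds Number of pedigree-checked birds.
#' @return A `rate_estimate` per 1000.
#' @export
lei_mutation_rate <- function(events, n_birds) {
  if (is.data.frame(events)) {
    deltas <- abs(events$delta)
    odd <- deltas %% 12 != 0 & deltas %% 13 != 0
    if (any(odd)) {
      warn(sprintf("%d event(s) with size change not a 12/13-bp multiple",
                   sum(odd)))
    }
    events <- nrow(events)
  }
  new_rate_estimate(events, n_birds, 1000L)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%d events / %d birds = %.1f per %d (95%% CI %.2f-%.2f)\n",
              x$events, x$denominator, x$rate, x$per_unit,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Detect LEI0258 allele-size mutations from pedigree data
#'
#' An event is an offspring allele size found in neither parent's allele
#' pair; the size change to the nearest parental allele is recorded.
#' Offspring with missing LEI0258 typing or incomplete parental typing are
#' skipped.
#'
#' @param m A [genotype_matrix] with pedigree (`sire_id`, `dam_id`) and
#'   LEI0258 columns (`lei_1`, `lei_2`).
#' @return A tibble: `bird_id`, `allele` (bp), `nearest_parent_allele`,
#'   `delta`, `step_multiple` (is the change a 12/13-bp multiple), plus an
#'   attribute `n_checked` (birds with complete trios) and `skipped`.
#' @export
detect_lei_mutations <- function(m) {
  if (!all(c("sire_id", "dam_id", "lei_1", "lei_2") %in% names(m))) {
    abort("pedigree and LEI0258 columns are required",
          class = "bsnphap_value_error")
  }
  df <- tibble::as_tibble(m)
  kids <- df[!is.na(df$sire_id) & !is.na(df$dam_id), , drop = FALSE]
  lookup <- function(id) {
    r <- df[df$bird_id == id, c("lei_1", "lei_2")]
    if (nrow(r) == 0) c(NA_integer_, NA_integer_) else unlist(r[1, ])
  }
  events <- list(); skipped <- character(0); checked <- 0L
  for (i in seq_len(nrow(kids))) {
    kid <- unname(unlist(kids[i, c("lei_1", "lei_2")]))
    par <- unname(c(lookup(kids$sire_id[i]), lookup(kids$dam_id[i])))
    if (anyNA(kid) || anyNA(par)) {
      skipped <- c(skipped, kids$bird_id[i])
      next
    }
    checked <- checked + 1L
    for (a in kid) {
      if (!a %in% par) {
        delta <- a - par[which.min(abs(a - par))]
        events[[length(events) + 1]] <- tibble::tibble(
          bird_id = kids$bird_id[i], allele = a,
          nearest_parent_allele = a - delta, delta = delta,
          step_multiple = abs(delta) %% 12 == 0 | abs(delta) %% 13 == 0)
      }
    }
  }
  out <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(bird_id = character(0), allele = integer(0),
                   nearest_parent_allele = integer(0), delta = integer(0),
                   step_multiple = logical(0))
  structure(out, n_checked = checked, skipped = skipped)
}
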