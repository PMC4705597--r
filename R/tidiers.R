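#' Tidy a rate estimate
#'
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `events`, `denominator`, `per_unit`, `rate`
#'   (exact), `rate_1dp` (conventional one-decimal report), `conf.low`,
#'   `conf.high`.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(events = x$events, denominator = x$denominator,
                 per_unit = x$per_unit, rate = x$rate,
                 rate_1dp = round(x$rate, 1),
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @rdname tidy.rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) tidy.rate_estimate(x, ...)

#' Tidy a recombinant scan
#'
#' @param x A `recombinant_scan`.
#' @param ... Unused.
#' @return The calls as a flat tibble (mismatch SNP lists collapsed to
#'   comma-separated strings).
#' @export
tidy.recombinant_scan <- function(x, ...) {
  calls <- x$calls
  calls$mismatch_snps <- vapply(calls$mismatch_snps, paste, collapse = ",",
                                FUN.VALUE = character(1))
  calls$mismatch_type <- vapply(calls$mismatch_type, paste, collapse = ",",
                                FUN.VALUE = character(1))
  if ("bird_ids" %in% names(calls)) {
    calls$bird_ids <- vapply(calls$bird_ids, paste, collapse = ",",
                             FUN.VALUE = character(1))
  }
  tibble::as_tibble(calls)
}

#' @rdname tidy.recombinant_scan
#' @export
glance.recombinant_scan <- function(x, ...) {
  tibble::tibble(n_recombinants = nrow(x$calls),
                 n_apparent = nrow(x$apparent),
                 mean_interval_bp = if (nrow(x$calls)) mean(
                   x$calls$interval_end_bp - x$calls$interval_start_bp)
                 else NA_real_)
}

#' Tidy a cluster assignment
#'
#' @param x A `bsnp_clusters`.
#' @param ... Unused.
#' @return The per-haplotype assignment as a plain tibble.
#' @export
tidy.bsnp_clusters <- function(x, ...) {
  tibble::new_tibble(as.list(x), nrow = nrow(x))
}

#' @rdname tidy.bsnp_clusters
#' @export
glance.bsnp_clusters <- function(x, ...) {
  tibble::tibble(n_haplotypes = nrow(x),
                 n_families = length(unique(x$family)),
                 n_singletons = sum(x$singleton),
                 n_reliable = length(unique(x$family[x$meets_bootstrap &
                                                       !x$singleton])),
                 mppd_threshold = attr(x, "threshold"),
                 percentile = attr(x, "percentile"),
                 bootstrap_min = attr(x, "bootstrap_min"))
}

#' Tidy a hotspot profile
#'
#' @param x A `hotspot_profile`.
#' @param ... Unused.
#' @return The per-bin counts as a plain tibble.
#' @export
tidy.hotspot_profile <- function(x, ...) {
  tibble::new_tibble(as.list(x), nrow = nrow(x))
}

#' @rdname tidy.hotspot_profile
#' @export
glance.hotspot_profile <- function(x, ...) {
  hs <- hotspots(x)
  tibble::tibble(n_hotspots = nrow(hs),
                 threshold = attr(x, "threshold"),
                 bin_size = attr(x, "bin_size"),
                 mode = attr(x, "mode"),
                 max_count = max(x$count))
}

#' Tidy a within-line phasing result
#'
#' @param x A `phasing_result`.
#' @param ... Unused.
#' @return The per-bird assignments (haplotype key pair and resolution
#'   method).
#' @export
tidy.phasing_result <- function(x, ...) x$assignments

#' @rdname tidy.phasing_result
#' @export
glance.phasing_result <- function(x, ...) {
  tibble::tibble(line = x$line,
                 n_haplotypes = nrow(x$haplotypes),
                 n_birds = nrow(x$assignments),
                 n_unresolved = nrow(x$unresolved))
}
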