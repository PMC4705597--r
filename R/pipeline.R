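#' Assemble a pipeline configuration
#'
#' @param panel Path to the SNP panel TSV.
#' @param genotypes Path to the genotype TSV (omit when `fluorescence` is
#'   given, in which case genotypes are called from endpoint fluorescence).
#' @param fluorescence Optional path to a long fluorescence TSV
#'   (`bird_id`, `snp`, `vic`, `fam`, optional `line_id`).
#' @param out_dir Output (run) directory; created if absent.
#' @param seed Integer seed, required (clustering bootstrap is stochastic).
#' @param max_mismatches,candidate_max_count Recombinant detection
#'   parameters: exception SNPs tolerated, and the maximum observation
#'   count for a haplotype to be treated as a recombination candidate
#'   (better-supported haplotypes form the population set).
#' @param bin_size,threshold,hotspot_mode Hotspot profiling parameters.
#' @param percentile,bootstrap_min,reps Clustering parameters.
#' @param max_radius KASP rejection radius (fluorescence input only).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel, genotypes = NULL, fluorescence = NULL,
                            out_dir, seed,
                            max_mismatches = 1L, candidate_max_count = 1L,
                            bin_size = 1000L, threshold = 4L,
                            hotspot_mode = "contained",
                            percentile = 10, bootstrap_min = 70,
                            reps = 1000L, max_radius = 0.25) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file whose keys match the arguments
#'   of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  inform(msg)
  if (!is.null(con)) writeLines(paste(format(Sys.time(), "%H:%M:%S"), msg), con)
}

#' Run the full typing pipeline
#'
#' Stages: genotype calling from fluorescence (when provided), within-line
#' haplotype inference and cross-line reconciliation, recombinant detection
#' under the both-parents rule, hotspot profiling, rate estimation, and
#' haplotype family clustering with naming. Stage outputs (TSV/newick/BED/
#' JSON) and a machine-readable manifest (inputs with checksums,
#' parameters, seed, package version) are written to the run directory.
#' With `resume = TRUE`, stages whose outputs already exist are skipped
#' when the recorded input checksums and parameters match the manifest.
#'
#' @param cfg A [pipeline_config()] (or path to a YAML config).
#' @param resume Reuse completed stage outputs when checksums match.
#' @return The run directory path, invisibly; stage results are attached as
#'   attributes (`haplotypes`, `scan`, `profile`, `rates`, `clusters`).
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (is.null(cfg$seed)) {
    abort("a seed is required", class = "bsnphap_value_error")
  }
  inputs <- c(panel = cfg$panel, genotypes = cfg$genotypes,
              fluorescence = cfg$fluorescence)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    abort(paste0("missing input file(s): ",
                 paste(missing_in, collapse = ", ")),
          class = "bsnphap_value_error")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  checksums <- vapply(inputs, function(p) unname(tools::md5sum(p)),
                      character(1))
  params <- cfg[setdiff(names(cfg), c("panel", "genotypes", "fluorescence",
                                      "out_dir"))]
  manifest_path <- out("manifest.json")
  prev <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  param_fingerprint <- function(p) {
    p <- p[!vapply(p, is.null, logical(1))]
    p <- p[order(names(p))]
    as.character(jsonlite::toJSON(lapply(p, function(x)
      if (is.numeric(x)) as.numeric(x) else x), auto_unbox = TRUE))
  }
  can_resume <- !is.null(prev) &&
    identical(unname(unlist(prev$inputs$md5)), unname(checksums)) &&
    identical(param_fingerprint(as.list(prev$params)),
              param_fingerprint(params))
  log_con <- file(out("run.log"), open = "a")
  on.exit(close(log_con))
  set.seed(cfg$seed)

  panel <- read_snp_panel(cfg$panel)
  log_line(log_con, "panel: %d SNPs (%d core)", nrow(panel),
           sum(panel$in_core))

  geno_path <- cfg$genotypes
  if (!is.null(cfg$fluorescence)) {
    fluor <- readr::read_tsv(cfg$fluorescence, comment = "#",
                             show_col_types = FALSE)
    geno <- call_genotypes(fluor, panel, max_radius = cfg$max_radius)
    geno_path <- out("called_genotypes.tsv")
    write_genotypes(geno, geno_path)
    log_line(log_con, "called genotypes for %d birds from fluorescence",
             nrow(geno))
  } else {
    geno <- read_genotypes(geno_path, panel)
  }

  # --- haplotype inference ---------------------------------------------------
  hap_path <- out("haplotypes.tsv")
  unres_path <- out("unresolved.tsv")
  lines <- sort(unique(geno$line_id))
  results <- NULL
  if (can_resume && file.exists(hap_path) && file.exists(unres_path)) {
    haps <- read_haplotypes(hap_path, panel)
    unresolved <- readr::read_tsv(unres_path, show_col_types = FALSE)
    log_line(log_con, "resume: reused %d haplotypes", nrow(haps))
  } else {
    results <- lapply(lines, function(l) infer_haplotypes(geno, l))
    haps <- reconcile_haplotypes(results)
    unresolved <- dplyr::bind_rows(lapply(results, function(r)
      dplyr::mutate(r$unresolved, line_id = r$line)))
    if (nrow(unresolved) == 0) {
      unresolved <- tibble::tibble(bird_id = character(0),
                                   reason = character(0),
                                   line_id = character(0))
    }
    write_haplotypes(haps, hap_path)
    readr::write_tsv(unresolved, unres_path)
    log_line(log_con, "inferred %d haplotypes across %d line(s); %d unresolved bird(s)",
             nrow(haps), length(lines), nrow(unresolved))
  }

  # --- recombinant detection (per line, both parents within the line) --------
  scans <- list()
  for (li in seq_along(lines)) {
    l <- lines[li]
    sc <- scan_line_recombinants(
      geno, l, max_mismatches = cfg$max_mismatches,
      established_min_count = cfg$candidate_max_count + 1L,
      phasing = if (is.null(results)) NULL else results[[li]])
    if (nrow(sc$calls)) sc$calls$line_id <- l
    if (nrow(sc$apparent)) sc$apparent$line_id <- l
    scans[[l]] <- sc
  }
  calls <- dplyr::bind_rows(lapply(scans, function(s) s$calls))
  calls <- calls[!duplicated(calls$key), , drop = FALSE]
  if (nrow(calls)) {
    calls$name <- vapply(seq_len(nrow(calls)), bsnp_rec_name, character(1))
  }
  scan <- structure(list(
    calls = calls,
    apparent = dplyr::bind_rows(lapply(scans, function(s) s$apparent)),
    panel = panel), class = "recombinant_scan")
  flat <- tidy(scan)
  readr::write_tsv(flat, out("recombinants.tsv"))
  readr::write_tsv(scan$apparent, out("apparent_recombinants.tsv"))
  log_line(log_con, "detected %d recombinant haplotype(s), %d apparent",
           nrow(calls), nrow(scan$apparent))

  # --- hotspots and rates ----------------------------------------------------
  profile <- hotspot_profile(scan, panel, bin_size = cfg$bin_size,
                             threshold = cfg$threshold,
                             mode = cfg$hotspot_mode)
  readr::write_tsv(tibble::as_tibble(profile), out("hotspot_counts.tsv"))
  write_hotspots_bed(profile, out("hotspots.bed"))
  n_offspring <- sum(!is.na(geno$sire_id))
  denom <- if (n_offspring > 0) n_offspring else nrow(geno)
  rates <- list(recombination = recombination_rate(nrow(calls), denom))
  if (all(c("lei_1", "lei_2", "sire_id", "dam_id") %in% names(geno)) &&
      n_offspring > 0) {
    ev <- detect_lei_mutations(geno)
    if (attr(ev, "n_checked") > 0) {
      rates$lei0258 <- lei_mutation_rate(ev, attr(ev, "n_checked"))
    }
  }
  jsonlite::write_json(lapply(rates, function(r)
    list(events = r$events, denominator = r$denominator,
         per_unit = r$per_unit, rate = round(r$rate, 1),
         ci95 = round(r$ci95, 3))),
    out("rates.json"), auto_unbox = TRUE)
  log_line(log_con, "recombination rate %.1f per 100 (%d/%d)",
           rates$recombination$rate, nrow(calls), denom)

  # --- clustering and naming -------------------------------------------------
  established <- new_haplotype_set(
    tibble::as_tibble(haps)[!(hap_key(haps) %in% calls$key), ], panel)
  clusters <- NULL
  if (nrow(established) >= 3) {
    clusters <- cluster_haplotypes(established,
                                   percentile = cfg$percentile,
                                   bootstrap_min = cfg$bootstrap_min,
                                   n_reps = cfg$reps, seed = cfg$seed)
    ape::write.tree(attr(clusters, "tree"), out("tree.nwk"))
    readr::write_tsv(tidy(clusters), out("clusters.tsv"))
    established <- name_haplotypes(established, clusters)
    write_haplotypes(established, out("named_haplotypes.tsv"))
    log_line(log_con, "clustered %d haplotypes into %d families",
             nrow(established), length(unique(clusters$family)))
  }

  manifest <- list(
    package = as.character(utils::packageVersion("bsnphap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    inputs = list(path = unname(inputs), role = names(inputs),
                  md5 = unname(checksums)),
    params = params,
    outputs = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  res <- cfg$out_dir
  attr(res, "haplotypes") <- if (is.null(clusters)) haps else established
  attr(res, "scan") <- scan
  attr(res, "profile") <- profile
  attr(res, "rates") <- rates
  attr(res, "clusters") <- clusters
  invisible(res)
}

#' Assign family letters, indices and names to a haplotype set
#'
#' Within each family, indices are assigned by decreasing observation
#' count, ties broken lexicographically by allele vector; names are
#' composed with [bsnp_name()] from the LEI0258 and serology annotations.
#'
#' @param haps A [haplotype_set].
#' @param clusters A `bsnp_clusters` assignment whose `haplotype` labels
#'   are `haps$hap_id`.
#' @return The haplotype set with `family`, `index` and `name` filled.
#' @export
name_haplotypes <- function(haps, clusters) {
  fam <- clusters$family[match(haps$hap_id, clusters$haplotype)]
  haps$family <- fam
  haps$index <- NA_integer_
  for (f in unique(fam[!is.na(fam)])) {
    members <- which(fam == f)
    ord <- members[order(-haps$count[members], hap_key(haps)[members])]
    haps$index[ord] <- seq_along(ord)
  }
  haps$name <- vapply(seq_len(nrow(haps)), function(i) {
    if (is.na(haps$family[i])) return(NA_character_)
    bsnp_name(haps$family[i], haps$index[i],
              suffix = haps$suffix[i], lei = haps$lei[[i]],
              serology = haps$serology[[i]])
  }, character(1))
  haps
}
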