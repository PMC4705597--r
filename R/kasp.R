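#' Geometric centroids of the six endpoint-fluorescence clusters
#'
#' On the normalized plane (total signal = 1) the five genotype clusters and
#' the no-amplification origin sit at the allele-dosage ratios: a 2:1
#' duplication heterozygote reads two parts of one fluorophore to one of the
#' other.
#'
#' @return A 6 x 2 numeric matrix (rows `XX`, `YY`, `XY`, `DUP_XXY`,
#'   `DUP_XYY`, `FAIL`; columns `vic`, `fam`).
#' @export
kasp_centroids <- function() {
  matrix(c(1, 0,
           0, 1,
           0.5, 0.5,
           2 / 3, 1 / 3,
           1 / 3, 2 / 3,
           0, 0),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("XX", "YY", "XY", "DUP_XXY", "DUP_XYY", "FAIL"),
                         c("vic", "fam")))
}

#' Classify endpoint-fluorescence points into genotype clusters
#'
#' Nearest-centroid classification with a fixed rejection radius: a point
#' farther than `max_radius` (Euclidean) from every centroid is returned as
#' `UNDEFINED` (an aberrant product, not a genotype).
#'
#' @param points Data frame with columns `vic` and `fam`.
#' @param centroids Centroid matrix as from [kasp_centroids()]; must contain
#'   the six canonical codes.
#' @param max_radius Rejection radius on the normalized plane.
#' @return Character vector of codes (`XX`, `YY`, `XY`, `DUP_XXY`,
#'   `DUP_XYY`, `FAIL`) or `UNDEFINED`.
#' @export
classify_kasp <- function(points, centroids = kasp_centroids(),
                          max_radius = 0.25) {
  if (is.null(dim(centroids)) || nrow(centroids) == 0) {
    abort("empty centroid map", class = "bsnphap_value_error")
  }
  need <- c("XX", "YY", "XY", "DUP_XXY", "DUP_XYY", "FAIL")
  if (!all(need %in% rownames(centroids))) {
    abort("centroids must include all six canonical codes",
          class = "bsnphap_value_error")
  }
  pts <- cbind(points$vic, points$fam)
  d2 <- outer(pts[, 1], centroids[, "vic"], "-")^2 +
    outer(pts[, 2], centroids[, "fam"], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  out <- rownames(centroids)[nearest]
  out[sqrt(d2[cbind(seq_len(nrow(pts)), nearest)]) > max_radius] <- "UNDEFINED"
  out
}

#' Call a genotype matrix from a grid of fluorescence points
#'
#' Applies [classify_kasp()] per well. In haplotype (core-SNP) context the
#' 2:1 duplication clusters collapse to the dual-allele code `AMBIG_BOTH`,
#' mirroring how duplication signals are recorded in haplotype tables;
#' `UNDEFINED` wells are recorded as `FAIL`.
#'
#' @param fluor Long data frame with columns `bird_id`, `snp`, `vic`, `fam`
#'   and optionally `line_id` and `is_ntc` (no-template control wells).
#' @param panel The [snp_panel].
#' @param centroids,max_radius Passed to [classify_kasp()].
#' @return A [genotype_matrix].
#' @export
call_genotypes <- function(fluor, panel, centroids = kasp_centroids(),
                           max_radius = 0.25) {
  fluor <- tibble::as_tibble(fluor)
  unknown <- setdiff(unique(fluor$snp), panel$snp)
  if (length(unknown)) {
    abort(paste0("unknown SNP in fluorescence data: ", unknown[1]),
          class = "bsnphap_format_error")
  }
  fluor$call <- classify_kasp(fluor, centroids, max_radius)
  fluor$call[fluor$call == "UNDEFINED"] <- "FAIL"
  core_set <- panel$snp[panel$in_core]
  dup <- fluor$call %in% c("DUP_XXY", "DUP_XYY") & fluor$snp %in% core_set
  fluor$call[dup] <- "AMBIG_BOTH"
  wide <- tidyr::pivot_wider(fluor[, c("bird_id", "snp", "call")],
                             names_from = "snp", values_from = "call")
  missing_snp <- setdiff(panel$snp, names(wide))
  if (length(missing_snp)) {
    abort(paste0("fluorescence grid lacks SNP(s): ",
                 paste(head(missing_snp, 5), collapse = ", ")),
          class = "bsnphap_format_error")
  }
  n_per <- table(fluor$bird_id)
  if (length(unique(n_per)) > 1) {
    abort("fluorescence grid is not rectangular",
          class = "bsnphap_format_error")
  }
  calls <- as.matrix(wide[, panel$snp, drop = FALSE])
  meta <- tibble::tibble(bird_id = wide$bird_id, line_id = "pop")
  if ("line_id" %in% names(fluor)) {
    meta$line_id <- fluor$line_id[match(meta$bird_id, fluor$bird_id)]
  }
  genotype_matrix(meta, calls, panel)
}

# mean Cq with outlier replicates (> 1.5 Cq from the median) dropped
aggregate_cq <- function(cqs, label = "replicates") {
  cqs <- cqs[!is.na(cqs)]
  if (length(cqs) == 0) return(NA_real_)
  keep <- abs(cqs - median(cqs)) <= 1.5
  if (any(!keep)) {
    warn(sprintf("dropping %d outlier %s (> 1.5 Cq from median)",
                 sum(!keep), label))
  }
  mean(cqs[keep])
}

#' Relative genome equivalents from qPCR Cq replicates
#'
#' Computes `efficiency ^ -(dCq_sample - dCq_calibrator)` where
#' `dCq = mean(target Cq) - mean(control Cq)`, i.e. copy number relative to
#' a disomic calibrator after normalization to a single-copy control gene.
#' Replicates more than 1.5 Cq from their median are dropped with a warning.
#'
#' @param target_cq,control_cq Replicate Cq values for the sample.
#' @param calibrator_target_cq,calibrator_control_cq Replicates for the
#'   disomic calibrator sample.
#' @param efficiency PCR efficiency in (1, 2].
#' @return A one-row tibble with `value` (NA when the target failed to
#'   amplify) and `no_amplification`.
#' @export
genome_equivalents <- function(target_cq, control_cq,
                               calibrator_target_cq, calibrator_control_cq,
                               efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2) {
    abort("efficiency must be in (1, 2]", class = "bsnphap_value_error")
  }
  if (all(is.na(control_cq)) || all(is.na(calibrator_control_cq))) {
    abort("control replicates are required", class = "bsnphap_value_error")
  }
  if (all(is.na(target_cq))) {
    return(tibble::tibble(value = NA_real_, no_amplification = TRUE))
  }
  dcq_s <- aggregate_cq(target_cq, "target replicates") -
    aggregate_cq(control_cq, "control replicates")
  dcq_c <- aggregate_cq(calibrator_target_cq, "calibrator target replicates") -
    aggregate_cq(calibrator_control_cq, "calibrator control replicates")
  tibble::tibble(value = efficiency^-(dcq_s - dcq_c), no_amplification = FALSE)
}
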