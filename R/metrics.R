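# Per-plan dosimetric metrics: high- and intermediate-dose spillage
# (R100%, R50%, D2cm), normal-lung V20/V5 and fixed-volume OAR doses, and
# rib dose documentation. All metrics are defined on the dose grid of a
# coverage-normalized plan; extract_metrics() applies the 95% PTV coverage
# normalization by default before measuring.

#' Conformity index R100%
#'
#' Ratio of the prescription isodose volume (voxels with dose at or above
#' the prescription) to the PTV volume. Values near 1 indicate a conformal
#' plan; the evaluation is meaningful on a coverage-normalized plan.
#'
#' @param plan a (normalized) [sbrt_plan()].
#' @return Dimensionless ratio.
#' @export
compute_r100 <- function(plan) {
  ptv <- get_structure(plan, "PTV")
  v_ptv <- mask_volume_cc(ptv)
  if (v_ptv <= 0) stop_validation("PTV is empty")
  isodose_volume(plan$dose, plan$prescription$total_dose) / v_ptv
}

#' Intermediate-dose spillage R50%
#'
#' Ratio of the half-prescription isodose volume to the PTV volume. Always
#' at least as large as R100% because the 50% isodose encloses the 100%
#' isodose.
#'
#' @param plan a (normalized) [sbrt_plan()].
#' @return Dimensionless ratio.
#' @export
compute_r50 <- function(plan) {
  ptv <- get_structure(plan, "PTV")
  v_ptv <- mask_volume_cc(ptv)
  if (v_ptv <= 0) stop_validation("PTV is empty")
  isodose_volume(plan$dose, 0.5 * plan$prescription$total_dose) / v_ptv
}

#' Maximum dose 2 cm away from the PTV (D2cm)
#'
#' Maximum dose over all voxels farther than 20 mm (in any direction) from
#' the PTV, as a percentage of the prescription. The exclusion region is
#' the complement of the 20 mm expansion of the PTV (voxels at exactly
#' 20 mm belong to the expansion). A warning is recorded when the grid does
#' not extend at least 20 mm beyond the PTV bounding box, since the shell
#' is then truncated.
#'
#' @param plan a (normalized) [sbrt_plan()].
#' @param margin shell distance in mm; default 20.
#' @return Percent of prescription dose.
#' @export
compute_d2cm <- function(plan, margin = 20) {
  ptv <- get_structure(plan, "PTV")
  idx <- which(ptv$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_validation("PTV is empty")
  lo <- apply(idx, 2, min) - 1
  hi <- ptv$shape - apply(idx, 2, max)
  if (any(lo * ptv$spacing < margin) || any(hi * ptv$spacing < margin)) {
    warning(sprintf("dose grid extends less than %g mm beyond the PTV; D2cm shell is truncated", margin),
            call. = FALSE)
  }
  shell <- mask_complement(expand_mask(ptv, margin), name = "D2cm-region")
  if (!any(shell$occupancy)) {
    stop_geometry("no voxels beyond the 2 cm expansion of the PTV")
  }
  100 * max_dose(plan$dose, shell) / plan$prescription$total_dose
}

#' Normal-lung dose metrics: V20, V5 and the dose to 1000 cc
#'
#' Computed on "total normal lung": the lungs structure minus the internal
#' target volume. V20 and V5 are the percent of normal lung receiving at
#' least 20 and 5 Gy. The 1000 cc dose is the minimum dose to the hottest
#' 1000 cc; when the normal lung is smaller than 1000 cc, the minimum lung
#' dose is reported and flagged.
#'
#' @param plan a (normalized) [sbrt_plan()].
#' @return A list with `v20_pct`, `v5_pct`, `d1000cc_gy` and the logical
#'   flag `d1000cc_truncated`.
#' @export
compute_lung_metrics <- function(plan) {
  lungs <- get_structure(plan, "lungs_total")
  itv <- get_structure(plan, "ITV")
  normal <- mask_subtract(lungs, itv, name = "normal_lung")
  if (!any(normal$occupancy)) {
    stop_validation("normal lung (lungs minus ITV) is empty")
  }
  curve <- compute_dvh(plan$dose, normal)
  v <- volume_at_dose(curve, c(20, 5), mode = "percent")
  truncated <- curve$total_volume_cc < 1000
  d1000 <- if (truncated) {
    warning("normal lung is smaller than 1000 cc; reporting minimum lung dose",
            call. = FALSE)
    min(curve$doses)
  } else {
    dose_at_volume(curve, 1000, mode = "absolute_cc")
  }
  list(v20_pct = v[1], v5_pct = v[2], d1000cc_gy = d1000,
       d1000cc_truncated = truncated)
}

#' Rib dose documentation
#'
#' Maximum rib dose, the DVH doses to the hottest 1, 5 and 10 cc of rib,
#' and the 3D distance from the plan isocenter to the proximal rib contour.
#' Volume queries larger than the rib volume are reported as `NA` with a
#' warning.
#'
#' @param plan a (normalized) [sbrt_plan()].
#' @return A list with `dmax_gy`, `d1cc_gy`, `d5cc_gy`, `d10cc_gy` and
#'   `iso_to_rib_mm`.
#' @export
compute_rib_metrics <- function(plan) {
  ribs <- get_structure(plan, "ribs")
  curve <- compute_dvh(plan$dose, ribs)
  dv <- function(v_cc) {
    if (curve$total_volume_cc < v_cc) {
      warning(sprintf("rib volume %.1f cc < %g cc; D%gcc undefined",
                      curve$total_volume_cc, v_cc, v_cc), call. = FALSE)
      return(NA_real_)
    }
    dose_at_volume(curve, v_cc, mode = "absolute_cc")
  }
  list(
    dmax_gy = max_dose(plan$dose, ribs),
    d1cc_gy = dv(1),
    d5cc_gy = dv(5),
    d10cc_gy = dv(10),
    iso_to_rib_mm = min_distance_point_to_mask(plan$structures$isocenter, ribs)
  )
}

#' Spinal cord dose to the hottest 0.35 cc
#'
#' When the cord structure is smaller than 0.35 cc the maximum cord dose is
#' reported and flagged with a warning.
#'
#' @param plan a (normalized) [sbrt_plan()].
#' @return Dose in Gy, or `NA` if the cord structure is absent.
#' @export
compute_cord_metric <- function(plan) {
  cord <- get_structure(plan, "spinal_cord", required = FALSE)
  if (is.null(cord)) return(NA_real_)
  curve <- compute_dvh(plan$dose, cord)
  if (curve$total_volume_cc < 0.35) {
    warning("spinal cord volume < 0.35 cc; reporting maximum cord dose",
            call. = FALSE)
    return(max(curve$doses))
  }
  dose_at_volume(curve, 0.35, mode = "absolute_cc")
}

fixed_volume_metric <- function(plan, structure, v_cc) {
  m <- get_structure(plan, structure, required = FALSE)
  if (is.null(m) || !any(m$occupancy)) return(NA_real_)
  curve <- compute_dvh(plan$dose, m)
  if (curve$total_volume_cc < v_cc) return(max(curve$doses))
  dose_at_volume(curve, v_cc, mode = "absolute_cc")
}

#' Extract the full metric set from a plan
#'
#' Applies DVH normalization (95% PTV coverage by default) and computes
#' every spillage, lung, cord and rib metric. Optional structures
#' (esophagus, heart) yield `NA` when absent. The result is deterministic
#' for a given plan.
#'
#' @param plan an [sbrt_plan()] with `PTV`, `ITV`, `lungs_total` and `ribs`
#'   structures.
#' @param normalize apply [normalize_to_coverage()] first (default `TRUE`).
#' @param coverage_percent coverage level for normalization.
#' @return An object of class `plan_metrics`: a one-row data frame with
#'   columns `patient_id`, `ptv_cc`, `rx_gy`, `n_fx`, `r100`, `r50`,
#'   `d2cm_pct`, `lung_v20_pct`, `lung_v5_pct`, `lung_d1000cc_gy`,
#'   `cord_d035cc_gy`, `esophagus_d5cc_gy`, `heart_d15cc_gy`, `rib_dmax_gy`,
#'   `rib_d1cc_gy`, `rib_d5cc_gy`, `rib_d10cc_gy`, `iso_to_rib_mm`, plus the
#'   normalization scale in `attr(, "normalization_scale")`.
#' @export
extract_metrics <- function(plan, normalize = TRUE, coverage_percent = 95) {
  scale <- 1
  if (normalize) {
    plan <- normalize_to_coverage(plan, coverage_percent, "PTV")
    scale <- attr(plan, "normalization_scale")
  }
  lung <- compute_lung_metrics(plan)
  rib <- compute_rib_metrics(plan)
  out <- data.frame(
    patient_id = plan$patient_id,
    ptv_cc = mask_volume_cc(get_structure(plan, "PTV")),
    rx_gy = plan$prescription$total_dose,
    n_fx = plan$prescription$n_fractions,
    r100 = compute_r100(plan),
    r50 = compute_r50(plan),
    d2cm_pct = compute_d2cm(plan),
    lung_v20_pct = lung$v20_pct,
    lung_v5_pct = lung$v5_pct,
    lung_d1000cc_gy = lung$d1000cc_gy,
    cord_d035cc_gy = compute_cord_metric(plan),
    esophagus_d5cc_gy = fixed_volume_metric(plan, "esophagus", 5),
    heart_d15cc_gy = fixed_volume_metric(plan, "heart", 15),
    rib_dmax_gy = rib$dmax_gy,
    rib_d1cc_gy = rib$d1cc_gy,
    rib_d5cc_gy = rib$d5cc_gy,
    rib_d10cc_gy = rib$d10cc_gy,
    iso_to_rib_mm = rib$iso_to_rib_mm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("plan_metrics", "data.frame")
  attr(out, "normalization_scale") <- scale
  out
}
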