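# Cumulative DVH machinery. The curve is voxel-exact: it stores every voxel
# dose inside the structure sorted in descending order, so no bin width enters
# any query; binning, if wanted, is presentation-only.

#' Compute a cumulative dose-volume histogram
#'
#' Collects the dose of every voxel where the mask is occupied and sorts it
#' in descending order. All volume/dose queries ([volume_at_dose()],
#' [dose_at_volume()]) operate on this voxel-exact representation.
#'
#' @param dose a [dose_grid()].
#' @param mask a [structure_mask()] on the same frame; must be non-empty
#'   (an empty mask signals a missing contour and raises a validation error).
#' @return An object of class `dvh_curve` with fields `structure_name`,
#'   `doses` (sorted descending, Gy), `voxel_volume_cc` and
#'   `total_volume_cc`.
#' @examples
#' g <- dose_grid(array(10, c(2, 2, 2)), spacing = c(10, 10, 10))
#' m <- structure_mask("PTV", array(TRUE, c(2, 2, 2)), grid = g)
#' dvh <- compute_dvh(g, m)
#' volume_at_dose(dvh, 10)          # 8 cc
#' @export
compute_dvh <- function(dose, mask) {
  check_same_frame(dose, mask)
  sel <- mask$occupancy
  if (!any(sel)) {
    stop_validation(sprintf("structure '%s' is empty: missing contour?", mask$name))
  }
  d <- sort(dose$dose[sel], decreasing = TRUE)
  vv <- voxel_volume_cc(dose)
  structure(
    list(
      structure_name = mask$name,
      doses = d,
      voxel_volume_cc = vv,
      total_volume_cc = length(d) * vv
    ),
    class = "dvh_curve"
  )
}

#' Volume receiving at least a given dose
#'
#' Inclusive threshold: a voxel at exactly `level` Gy counts ("dose equal to
#' the level or more").
#'
#' @param curve a `dvh_curve`.
#' @param level dose threshold in Gy (>= 0); may be a vector.
#' @param mode `"absolute_cc"` for cc, `"percent"` for percent of the
#'   structure volume.
#' @return Numeric volume(s), same length as `level`.
#' @export
volume_at_dose <- function(curve, level, mode = c("absolute_cc", "percent")) {
  mode <- match.arg(mode)
  if (any(level < 0)) stop_validation("dose level must be >= 0 Gy")
  counts <- vapply(level, function(l) sum(curve$doses >= l), numeric(1))
  v <- counts * curve$voxel_volume_cc
  if (mode == "percent") v / curve$total_volume_cc * 100 else v
}

#' Minimum dose to the hottest given volume (DVH dose query)
#'
#' Returns the largest dose `D` such that at least the requested volume
#' receives `D` or more; this is the protocol reading of "dose to < X cc":
#' the minimum dose received by the hottest X cc. Linear interpolation is
#' used between adjacent sorted voxel doses; as the volume tends to zero the
#' result tends to the maximum voxel dose.
#'
#' @param curve a `dvh_curve`.
#' @param volume requested volume, cc or percent according to `mode`; must
#'   be positive and no larger than the structure volume.
#' @param mode `"absolute_cc"` or `"percent"`.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(curve, volume, mode = c("absolute_cc", "percent")) {
  mode <- match.arg(mode)
  v_cc <- if (mode == "percent") volume / 100 * curve$total_volume_cc else volume
  if (any(v_cc <= 0)) stop_validation("requested volume must be positive")
  if (any(v_cc > curve$total_volume_cc * (1 + 1e-9))) {
    stop_validation(sprintf(
      "requested volume %.3f cc exceeds structure volume %.3f cc",
      max(v_cc), curve$total_volume_cc
    ))
  }
  d <- curve$doses
  n <- length(d)
  vapply(v_cc, function(v) {
    k <- min(v / curve$voxel_volume_cc, n)
    if (k <= 1) return(d[1])
    i <- floor(k)
    frac <- k - i
    if (i >= n) return(d[n])
    d[i] + frac * (d[i + 1] - d[i])
  }, numeric(1))
}

#' Maximum voxel dose within a region
#'
#' The voxel maximum stands in for the reported "maximum point dose"; no
#' sub-voxel interpolation is attempted.
#'
#' @param dose a [dose_grid()].
#' @param mask optional [structure_mask()]; when `NULL` the whole grid is
#'   scanned.
#' @return Maximum dose in Gy.
#' @export
max_dose <- function(dose, mask = NULL) {
  if (is.null(mask)) return(max(dose$dose))
  check_same_frame(dose, mask)
  if (!any(mask$occupancy)) {
    stop_validation(sprintf("structure '%s' is empty", mask$name))
  }
  max(dose$dose[mask$occupancy])
}

#' Rescale a plan so a coverage dose equals the prescription (DVH
#' normalization)
#'
#' Scales every dose voxel by `s = Rx / D_cov`, where `D_cov` is the dose
#' currently received by `coverage_percent` of the target structure. After
#' scaling, at least `coverage_percent` of the target receives the full
#' prescription (to within DVH interpolation tolerance). The default
#' reproduces the common clinical choice "at least 95% of the PTV receives
#' 100% of the prescription dose".
#'
#' @param plan an [sbrt_plan()].
#' @param coverage_percent coverage level in (0, 100]; default 95.
#' @param target_structure structure name; default `"PTV"`.
#' @return The rescaled plan, with the applied scale factor in
#'   `attr(, "normalization_scale")`.
#' @export
normalize_to_coverage <- function(plan, coverage_percent = 95,
                                  target_structure = "PTV") {
  if (coverage_percent <= 0 || coverage_percent > 100) {
    stop_validation("`coverage_percent` must be in (0, 100]")
  }
  target <- get_structure(plan, target_structure)
  curve <- compute_dvh(plan$dose, target)
  d_cov <- dose_at_volume(curve, coverage_percent, mode = "percent")
  if (!is.finite(d_cov) || d_cov <= 0) {
    stop_validation(sprintf(
      "cannot normalize: dose at %.1f%% of '%s' is zero",
      coverage_percent, target_structure
    ))
  }
  s <- plan$prescription$total_dose / d_cov
  scaled <- plan
  scaled$dose$dose <- plan$dose$dose * s
  attr(scaled, "normalization_scale") <- s
  scaled
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> '%s': %.2f cc, dose %.2f-%.2f Gy\n",
    x$structure_name, x$total_volume_cc, min(x$doses), max(x$doses)
  ))
  invisible(x)
}

#' Export a cumulative DVH as a two-column data frame
#'
#' @param x a `dvh_curve`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data frame with columns `dose_gy` (descending) and
#'   `volume_cc` (cumulative volume receiving at least that dose).
#' @export
as.data.frame.dvh_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    dose_gy = x$doses,
    volume_cc = seq_along(x$doses) * x$voxel_volume_cc
  )
}
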