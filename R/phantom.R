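# Synthetic lung-SBRT dose phantoms with analytic ground truth.
#
# The dose model is deliberately analytic rather than beam-based: an
# ellipsoidal target receives the full prescription out to a scaled radius
# r_rx, beyond which the dose falls off monotonically along every ray with a
# smooth sigmoid profile whose half-value sits g50 mm past r_rx:
#
#   dose(x) = Rx                                      r_eff(x) <= r_rx
#           = Rx / (1 + ((r_eff - r_rx)/g50)^2)       otherwise
#
# The heavy (Lorentzian) tail mirrors the slow scatter-dominated falloff of
# photon dose in low-density lung; a Gaussian tail would fall off much
# faster than clinical profiles at 2 cm from the target.
#
# where r_eff is the ellipsoid-normalised radius rescaled by the
# volume-equivalent PTV radius. For spherical targets every spillage metric
# then has a closed form (volume ratios are cube ratios of isodose radii),
# which is what makes the generator usable as an oracle for the evaluation
# pipeline.

#' Configuration for a synthetic lung-SBRT phantom
#'
#' Defaults emulate the planning conditions of a peripheral lung SBRT
#' cohort: a 2 mm isotropic dose grid, a spherical PTV inside a large
#' low-density lung region, a rib shell at a configurable 3D distance from
#' the isocenter, a spinal-cord cylinder, 50 Gy in 5 fractions, and a
#' radially monotone dose falloff normalized so the PTV is fully covered by
#' the prescription isodose.
#'
#' @param spacing_mm voxel pitch per axis (mm); default 2 mm isotropic.
#' @param extent_mm physical grid size per axis (mm); default 140.
#' @param ptv_volume_cc target PTV volume in cc (spherical PTV); ignored
#'   when `ptv_semi_axes_mm` is given.
#' @param ptv_semi_axes_mm optional length-3 ellipsoid semi-axes (mm).
#' @param itv_margin_mm PTV = ITV + this uniform margin; the ITV ellipsoid
#'   is shrunk by it (default 5 mm).
#' @param rx_gy,n_fractions prescription; default 50 Gy in 5 fractions.
#' @param r100_scale prescription-isodose radius as a multiple of the PTV
#'   radius (>= 1); the resulting conformity index is `r100_scale^3`.
#' @param g50_mm radial distance from the prescription isodose to the
#'   half-prescription isodose (mm).
#' @param iso_to_rib_mm inner radius of the rib shell, i.e. the target 3D
#'   isocenter-to-rib distance (mm).
#' @param rib_thickness_mm rib shell thickness (mm).
#' @param lung_semi_axes_mm semi-axes of the lung ellipsoid (mm).
#' @param cord_offset_mm (x, y) offset of the spinal-cord cylinder axis
#'   from the grid centre (mm).
#' @param cord_radius_mm cord cylinder radius (mm).
#' @param noise_sd relative standard deviation of optional multiplicative
#'   Gaussian noise emulating Monte Carlo statistical noise; 0 (off) by
#'   default.
#' @param seed integer seed used when `noise_sd > 0`.
#' @param patient_id label.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(spacing_mm = c(2, 2, 2),
                           extent_mm = c(140, 140, 140),
                           ptv_volume_cc = 30,
                           ptv_semi_axes_mm = NULL,
                           itv_margin_mm = 5,
                           rx_gy = 50, n_fractions = 5,
                           r100_scale = 1.05,
                           g50_mm = 10,
                           iso_to_rib_mm = 35,
                           rib_thickness_mm = 5,
                           lung_semi_axes_mm = c(64, 64, 68),
                           cord_offset_mm = c(-55, 0),
                           cord_radius_mm = 5,
                           noise_sd = 0,
                           seed = 1,
                           patient_id = "phantom") {
  if (is.null(ptv_semi_axes_mm)) {
    if (!is.finite(ptv_volume_cc) || ptv_volume_cc <= 0) {
      stop_validation("`ptv_volume_cc` must be positive")
    }
    r <- (3 * 1000 * ptv_volume_cc / (4 * pi))^(1 / 3)
    ptv_semi_axes_mm <- rep(r, 3)
  }
  cfg <- list(
    spacing_mm = as.numeric(spacing_mm),
    extent_mm = as.numeric(extent_mm),
    ptv_semi_axes_mm = as.numeric(ptv_semi_axes_mm),
    itv_margin_mm = itv_margin_mm,
    rx_gy = rx_gy, n_fractions = as.integer(n_fractions),
    r100_scale = r100_scale, g50_mm = g50_mm,
    iso_to_rib_mm = iso_to_rib_mm, rib_thickness_mm = rib_thickness_mm,
    lung_semi_axes_mm = as.numeric(lung_semi_axes_mm),
    cord_offset_mm = as.numeric(cord_offset_mm),
    cord_radius_mm = cord_radius_mm,
    noise_sd = noise_sd, seed = as.integer(seed),
    patient_id = patient_id
  )
  if (any(cfg$spacing_mm <= 0) || any(cfg$extent_mm <= 0) ||
      any(cfg$ptv_semi_axes_mm <= 0) || cfg$g50_mm <= 0 ||
      cfg$rib_thickness_mm <= 0 || cfg$cord_radius_mm <= 0) {
    stop_validation("all geometric sizes must be positive")
  }
  if (cfg$r100_scale < 1) stop_validation("`r100_scale` must be >= 1")
  class(cfg) <- "phantom_config"
  cfg
}

#' Solve the falloff profile for target conformity and spillage
#'
#' Closed-form inversion for spherical targets: a conformity target R100
#' fixes the prescription-isodose radius at `ptv_radius * R100^(1/3)`, and
#' an intermediate-spillage target R50 fixes the half-prescription radius
#' at `ptv_radius * R50^(1/3)`; their difference is the falloff distance
#' `g50`.
#'
#' @param target_r100 desired conformity index (>= 1).
#' @param target_r50 desired 50%-isodose/PTV volume ratio
#'   (> `target_r100`).
#' @param ptv_radius_mm PTV radius in mm.
#' @return A list with `r100_scale`, `g50_mm`, and the two isodose radii
#'   `r100_radius_mm`, `r50_radius_mm`.
#' @examples
#' solve_profile_for_targets(1.0, 8.0, 10)  # half-Rx radius 20 mm
#' @export
solve_profile_for_targets <- function(target_r100, target_r50, ptv_radius_mm) {
  if (!is.finite(target_r100) || target_r100 < 1) {
    stop_validation("`target_r100` must be >= 1")
  }
  if (!is.finite(target_r50) || target_r50 <= target_r100) {
    stop_validation("`target_r50` must exceed `target_r100`")
  }
  if (!is.finite(ptv_radius_mm) || ptv_radius_mm <= 0) {
    stop_validation("`ptv_radius_mm` must be positive")
  }
  r100_radius <- ptv_radius_mm * target_r100^(1 / 3)
  r50_radius <- ptv_radius_mm * target_r50^(1 / 3)
  list(
    r100_scale = target_r100^(1 / 3),
    g50_mm = r50_radius - r100_radius,
    r100_radius_mm = r100_radius,
    r50_radius_mm = r50_radius
  )
}

# Radial dose profile as a fraction of prescription.
phantom_profile <- function(r_eff, r_rx, g50) {
  ifelse(r_eff <= r_rx, 1, 1 / (1 + ((r_eff - r_rx) / g50)^2))
}

#' Generate a synthetic lung-SBRT plan
#'
#' Builds the dose grid and the PTV, ITV, lungs, spinal-cord and rib
#' structures described by a [phantom_config()]. The dose is radially
#' non-increasing from the target centre along every ray; every PTV voxel
#' receives at least the prescription, so the plan passes 95% coverage
#' normalization with a scale factor of 1 (up to optional noise).
#' Deterministic for a given config (including `seed` when noise is on).
#'
#' @param config a [phantom_config()].
#' @return An [sbrt_plan()]; the analytic metric ground truth is attached
#'   as `attr(, "ground_truth")` (list with `r100`, `r50`, `d2cm_pct`,
#'   `ptv_cc`).
#' @export
make_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) {
    stop_validation("`config` must be a phantom_config")
  }
  sp <- config$spacing_mm
  shape <- pmax(3L, as.integer(round(config$extent_mm / sp)))
  center <- (shape - 1) / 2 * sp
  a <- config$ptv_semi_axes_mm
  r_equiv <- prod(a)^(1 / 3)
  half <- (shape - 1) / 2 * sp
  if (any(a >= half) || any(config$lung_semi_axes_mm >= half)) {
    stop_geometry("structure exceeds the grid extent")
  }
  if (config$iso_to_rib_mm + config$rib_thickness_mm >= min(half)) {
    stop_geometry("rib shell exceeds the grid extent")
  }

  ax <- lapply(1:3, function(k) (seq_len(shape[k]) - 1) * sp[k] - center[k])
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)

  # ellipsoid-normalised radius, rescaled to physical units via the
  # volume-equivalent PTV radius
  u <- sqrt((X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2)
  r_eff <- u * r_equiv
  r_rx <- config$r100_scale * r_equiv
  frac <- phantom_profile(r_eff, r_rx, config$g50_mm)
  dosearr <- config$rx_gy * frac

  if (config$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(config$seed)
    dosearr <- dosearr * pmax(0, 1 + stats::rnorm(length(dosearr),
                                                  sd = config$noise_sd))
    dim(dosearr) <- shape
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }

  frame <- sprintf("phantom-%s", config$patient_id)
  grid <- dose_grid(dosearr, spacing = sp, origin = -center, frame_id = frame)

  ptv_occ <- u <= 1
  a_itv <- pmax(a - config$itv_margin_mm, 1)
  itv_occ <- ((X / a_itv[1])^2 + (Y / a_itv[2])^2 + (Z / a_itv[3])^2) <= 1
  ls <- config$lung_semi_axes_mm
  lung_occ <- ((X / ls[1])^2 + (Y / ls[2])^2 + (Z / ls[3])^2) <= 1
  riso <- sqrt(X^2 + Y^2 + Z^2)
  rib_occ <- riso >= config$iso_to_rib_mm &
    riso <= config$iso_to_rib_mm + config$rib_thickness_mm
  co <- config$cord_offset_mm
  cord_occ <- ((X - co[1])^2 + (Y - co[2])^2) <= config$cord_radius_mm^2
  lung_occ <- lung_occ & !rib_occ & !cord_occ

  masks <- list(
    structure_mask("PTV", ptv_occ, grid = grid),
    structure_mask("ITV", itv_occ, grid = grid),
    structure_mask("lungs_total", lung_occ, grid = grid),
    structure_mask("spinal_cord", cord_occ, grid = grid),
    structure_mask("ribs", rib_occ, grid = grid)
  )
  ss <- structure_set(masks, isocenter = c(0, 0, 0))
  plan <- sbrt_plan(grid, ss, prescription(config$rx_gy, config$n_fractions),
                    patient_id = config$patient_id)
  attr(plan, "ground_truth") <- list(
    r100 = config$r100_scale^3,
    r50 = ((r_rx + config$g50_mm) / r_equiv)^3,
    d2cm_pct = 100 * phantom_profile(r_equiv + 20, r_rx, config$g50_mm),
    ptv_cc = 4 / 3 * pi * prod(a) / 1000
  )
  plan
}

#' Generate a seeded cohort of phantoms with ground-truth metrics
#'
#' Samples `n` spherical-target configurations with PTV volumes, conformity
#' and spillage targets drawn uniformly from the given ranges, builds each
#' phantom, and returns the generator's analytic ground truth alongside the
#' plans for parameter-recovery testing. Reproducible for a fixed seed.
#'
#' @param n number of plans (>= 1).
#' @param ptv_volume_range_cc PTV volume range in cc; default 11.1-163,
#'   the span of the embedded reference cohort.
#' @param r100_range conformity-target range; default 1.05-1.35.
#' @param r50_range spillage-target range; default 3.5-5.5 (each draw is
#'   forced above its plan's R100 target).
#' @param iso_to_rib_range_mm rib distance range in mm.
#' @param seed RNG seed.
#' @param spacing_mm grid spacing; default 2 mm isotropic.
#' @return A list with `plans` (list of [sbrt_plan()]) and `truth` (data
#'   frame with `patient_id`, `ptv_cc`, `r100`, `r50`, `d2cm_pct`).
#' @export
make_cohort <- function(n = 20,
                        ptv_volume_range_cc = c(11.1, 163),
                        r100_range = c(1.05, 1.35),
                        r50_range = c(3.5, 5.5),
                        iso_to_rib_range_mm = c(20, 55),
                        seed = 1,
                        spacing_mm = c(2, 2, 2)) {
  if (!is.finite(n) || n < 1) stop_validation("`n` must be >= 1")
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2] && r[1] > 0
  if (!rng_ok(ptv_volume_range_cc) || !rng_ok(r100_range) || !rng_ok(r50_range) ||
      !rng_ok(iso_to_rib_range_mm)) {
    stop_validation("parameter ranges must be finite positive (lo <= hi) pairs")
  }
  set.seed(seed)
  vols <- stats::runif(n, ptv_volume_range_cc[1], ptv_volume_range_cc[2])
  r100s <- stats::runif(n, r100_range[1], r100_range[2])
  r50s <- pmax(stats::runif(n, r50_range[1], r50_range[2]), r100s + 0.5)
  ribs <- stats::runif(n, iso_to_rib_range_mm[1], iso_to_rib_range_mm[2])
  plans <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    radius <- (3 * 1000 * vols[i] / (4 * pi))^(1 / 3)
    prof <- solve_profile_for_targets(r100s[i], r50s[i], radius)
    cfg <- phantom_config(
      spacing_mm = spacing_mm,
      ptv_volume_cc = vols[i],
      r100_scale = prof$r100_scale,
      g50_mm = prof$g50_mm,
      iso_to_rib_mm = ribs[i],
      patient_id = sprintf("phantom-%02d", i)
    )
    plans[[i]] <- make_phantom(cfg)
    gt <- attr(plans[[i]], "ground_truth")
    truth[[i]] <- data.frame(
      patient_id = cfg$patient_id, ptv_cc = gt$ptv_cc,
      r100 = gt$r100, r50 = gt$r50, d2cm_pct = gt$d2cm_pct,
      iso_to_rib_mm = ribs[i], stringsAsFactors = FALSE
    )
  }
  list(plans = plans, truth = do.call(rbind, truth))
}
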