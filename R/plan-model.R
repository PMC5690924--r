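#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish failure modes.
stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("sbrteval_validation_error", "error", "condition")))
}
stop_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("sbrteval_geometry_error", "error", "condition")))
}
stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("sbrteval_format_error", "error", "condition")))
}

#' Regular 3D dose grid
#'
#' A `dose_grid` holds absorbed dose (Gy) on a regular, axis-aligned voxel
#' grid with physical geometry in millimetres. The centre of voxel
#' `(1, 1, 1)` sits at `origin`; voxel centres along axis `k` are
#' `origin[k] + (0:(shape[k] - 1)) * spacing[k]`.
#'
#' @param dose numeric 3D array of non-negative doses in Gy.
#' @param spacing numeric length-3 vector of voxel pitch in mm (may be
#'   anisotropic); all entries must be positive.
#' @param origin numeric length-3 physical coordinate (mm) of the first
#'   voxel centre.
#' @param frame_id opaque geometry identifier; structures can only be
#'   combined with a dose grid sharing the same `frame_id`.
#' @return An object of class `dose_grid`.
#' @examples
#' g <- dose_grid(array(10, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(dose, spacing, origin = c(0, 0, 0), frame_id = "frame-1") {
  dose <- as.array(dose)
  if (length(dim(dose)) != 3L) {
    stop_validation("`dose` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_validation("`spacing` must be 3 positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop_validation("`origin` must be a finite length-3 coordinate (mm)")
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop_validation("dose values must be finite and non-negative (Gy)")
  }
  structure(
    list(
      dose = dose,
      spacing = spacing,
      origin = origin,
      shape = dim(dose),
      frame_id = as.character(frame_id)
    ),
    class = "dose_grid"
  )
}

#' Voxel volume of a grid in cubic centimetres
#'
#' @param x a `dose_grid` or `structure_mask`.
#' @return Volume of one voxel in cc.
#' @export
voxel_volume_cc <- function(x) {
  prod(x$spacing) / 1000
}

#' Physical voxel-centre coordinates along each axis
#'
#' @param x a `dose_grid` or `structure_mask`.
#' @return A list of three numeric vectors (mm), one per axis.
#' @export
axis_coords <- function(x) {
  lapply(1:3, function(k) x$origin[k] + (seq_len(x$shape[k]) - 1) * x$spacing[k])
}

#' Named boolean structure mask on a grid geometry
#'
#' @param name structure label, e.g. `"PTV"`.
#' @param occupancy logical 3D array; `TRUE` marks voxels inside the
#'   structure.
#' @param spacing,origin,frame_id grid geometry, as in [dose_grid()]. Pass
#'   `grid` instead to copy geometry from an existing grid.
#' @param grid optional `dose_grid` whose geometry the mask inherits.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, occupancy, spacing = NULL, origin = NULL,
                           frame_id = NULL, grid = NULL) {
  occupancy <- as.array(occupancy)
  if (!is.logical(occupancy) || length(dim(occupancy)) != 3L) {
    stop_validation("`occupancy` must be a logical 3D array")
  }
  if (!is.null(grid)) {
    spacing <- grid$spacing
    origin <- grid$origin
    frame_id <- grid$frame_id
    if (!identical(dim(occupancy), grid$shape)) {
      stop_geometry("mask occupancy shape does not match grid shape")
    }
  }
  if (is.null(spacing) || is.null(origin) || is.null(frame_id)) {
    stop_validation("provide either `grid` or all of spacing/origin/frame_id")
  }
  occupancy[is.na(occupancy)] <- FALSE
  structure(
    list(
      name = as.character(name),
      occupancy = occupancy,
      spacing = as.numeric(spacing),
      origin = as.numeric(origin),
      shape = dim(occupancy),
      frame_id = as.character(frame_id)
    ),
    class = "structure_mask"
  )
}

#' Structure volume in cubic centimetres
#'
#' @param mask a `structure_mask`.
#' @return Occupied volume in cc (voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$occupancy) * voxel_volume_cc(mask)
}

check_same_frame <- function(a, b) {
  if (!identical(a$frame_id, b$frame_id)) {
    stop_geometry(sprintf(
      "frame of reference mismatch: '%s' vs '%s'", a$frame_id, b$frame_id
    ))
  }
  if (!identical(a$shape, b$shape)) {
    stop_geometry("grid shape mismatch between objects sharing a frame")
  }
  invisible(TRUE)
}

#' Structure set: named masks plus the plan isocenter
#'
#' All masks must share one frame of reference. For a full RTOG-style
#' evaluation the set should contain `PTV`, `ITV`, `lungs_total`,
#' `spinal_cord` and `ribs`; `esophagus` and `heart` are optional.
#'
#' @param masks a list of `structure_mask` objects (named or carrying their
#'   own `name` fields).
#' @param isocenter numeric length-3 physical coordinate (mm).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, isocenter) {
  if (length(masks) == 0) {
    stop_validation("structure set must contain at least one mask")
  }
  if (!all(vapply(masks, inherits, logical(1), "structure_mask"))) {
    stop_validation("all elements of `masks` must be structure_mask objects")
  }
  names(masks) <- vapply(masks, function(m) m$name, character(1))
  frame <- masks[[1]]$frame_id
  for (m in masks) check_same_frame(masks[[1]], m)
  isocenter <- as.numeric(isocenter)
  if (length(isocenter) != 3L || any(!is.finite(isocenter))) {
    stop_validation("`isocenter` must be a finite length-3 coordinate (mm)")
  }
  structure(
    list(masks = masks, isocenter = isocenter, frame_id = frame),
    class = "structure_set"
  )
}

#' Prescription: total dose and fractionation
#'
#' @param total_dose total prescribed dose in Gy (> 0).
#' @param n_fractions number of fractions (integer >= 1).
#' @return An object of class `prescription` with the derived
#'   `dose_per_fraction`.
#' @examples
#' prescription(50, 5)  # 10 Gy per fraction
#' @export
prescription <- function(total_dose, n_fractions) {
  total_dose <- as.numeric(total_dose)
  n_fractions <- as.integer(n_fractions)
  if (!is.finite(total_dose) || total_dose <= 0) {
    stop_validation("`total_dose` must be positive (Gy)")
  }
  if (is.na(n_fractions) || n_fractions < 1L) {
    stop_validation("`n_fractions` must be a positive integer")
  }
  structure(
    list(
      total_dose = total_dose,
      n_fractions = n_fractions,
      dose_per_fraction = total_dose / n_fractions
    ),
    class = "prescription"
  )
}

#' Treatment plan: dose grid, structures and prescription
#'
#' @param dose a [dose_grid()].
#' @param structures a [structure_set()] sharing the dose grid's frame.
#' @param rx a [prescription()].
#' @param patient_id label for reports.
#' @return An object of class `sbrt_plan`.
#' @export
sbrt_plan <- function(dose, structures, rx, patient_id = "anonymous") {
  if (!inherits(dose, "dose_grid")) stop_validation("`dose` must be a dose_grid")
  if (!inherits(structures, "structure_set")) {
    stop_validation("`structures` must be a structure_set")
  }
  if (!inherits(rx, "prescription")) stop_validation("`rx` must be a prescription")
  check_same_frame(dose, structures$masks[[1]])
  structure(
    list(
      dose = dose,
      structures = structures,
      prescription = rx,
      patient_id = as.character(patient_id)
    ),
    class = "sbrt_plan"
  )
}

#' Fetch a structure mask from a plan by name
#'
#' @param plan an `sbrt_plan`.
#' @param name structure name.
#' @param required error (validation) if absent; otherwise return `NULL`.
#' @return A `structure_mask` or `NULL`.
#' @export
get_structure <- function(plan, name, required = TRUE) {
  m <- plan$structures$masks[[name]]
  if (is.null(m) && required) {
    stop_validation(sprintf("required structure '%s' is missing", name))
  }
  m
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, spacing %s mm, dose %.2f-%.2f Gy\n",
    x$shape[1], x$shape[2], x$shape[3],
    paste(format(x$spacing), collapse = " x "),
    min(x$dose), max(x$dose)
  ))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask> '%s': %d voxels, %.2f cc\n",
    x$name, sum(x$occupancy), mask_volume_cc(x)
  ))
  invisible(x)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf(
    "<structure_set> %d structures (%s); isocenter (%.1f, %.1f, %.1f) mm\n",
    length(x$masks), paste(names(x$masks), collapse = ", "),
    x$isocenter[1], x$isocenter[2], x$isocenter[3]
  ))
  invisible(x)
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf(
    "<prescription> %.1f Gy in %d fractions (%.2f Gy/fx)\n",
    x$total_dose, x$n_fractions, x$dose_per_fraction
  ))
  invisible(x)
}

#' @export
print.sbrt_plan <- function(x, ...) {
  cat(sprintf("<sbrt_plan> patient '%s'\n", x$patient_id))
  print(x$prescription)
  print(x$dose)
  print(x$structures)
  invisible(x)
}
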