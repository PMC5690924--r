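# Portable on-disk plan format: a directory holding plan.json (geometry,
# prescription, structure names, isocenter) plus one raw little-endian array
# per field (dose as float64, masks as uint8). Arrays are written in R's
# native column-major order; the round trip is bit-exact.

#' Write a plan to a portable directory
#'
#' Layout: `plan.json` (header with full-precision geometry) plus
#' `dose.f64` (IEEE-754 doubles, little-endian, column-major) and one
#' `mask_<i>.u8` per structure. `read_plan(write_plan(plan))` is bit-exact
#' and writing the same plan twice yields byte-identical files.
#'
#' @param plan an [sbrt_plan()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  if (!inherits(plan, "sbrt_plan")) stop_validation("`plan` must be an sbrt_plan")
  if (length(plan$structures$masks) == 0) {
    stop_validation("plan has an empty structure set")
  }
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    stop(errorCondition(sprintf("cannot create directory '%s'", path),
                        class = c("sbrteval_io_error", "error", "condition")))
  }
  snames <- names(plan$structures$masks)
  header <- list(
    format = "sbrteval-plan",
    version = 1L,
    patient_id = plan$patient_id,
    frame_id = plan$dose$frame_id,
    origin_mm = plan$dose$origin,
    spacing_mm = plan$dose$spacing,
    shape = plan$dose$shape,
    prescription = list(
      total_dose_gy = plan$prescription$total_dose,
      n_fractions = plan$prescription$n_fractions
    ),
    isocenter_mm = plan$structures$isocenter,
    structures = lapply(seq_along(snames), function(i) {
      list(name = snames[i], file = sprintf("mask_%03d.u8", i))
    })
  )
  jsonlite::write_json(header, file.path(path, "plan.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "dose.f64"), "wb")
  writeBin(as.vector(plan$dose$dose), con, size = 8, endian = "little")
  close(con)
  for (i in seq_along(snames)) {
    con <- file(file.path(path, sprintf("mask_%03d.u8", i)), "wb")
    writeBin(as.integer(plan$structures$masks[[i]]$occupancy), con,
             size = 1, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a plan from disk
#'
#' Reads the portable directory format written by [write_plan()]. DICOM-RT
#' input (`format = "dicom_rt"`) is not supported by this build; convert
#' DICOM plans to the portable format externally (the slice-wise contour
#' rasterizer [rasterize_contours()] covers the geometric step).
#'
#' @param path plan directory.
#' @param format `"portable"` (default) or `"dicom_rt"`.
#' @return An [sbrt_plan()].
#' @export
read_plan <- function(path, format = c("portable", "dicom_rt")) {
  format <- match.arg(format)
  if (format == "dicom_rt") {
    stop_format("DICOM-RT reading is not supported; use the portable format")
  }
  hfile <- file.path(path, "plan.json")
  if (!file.exists(hfile)) {
    stop_format(sprintf("'%s' is not a portable plan directory (no plan.json)", path))
  }
  h <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  if (!identical(h$format, "sbrteval-plan")) {
    stop_format("unrecognised plan header format")
  }
  shape <- as.integer(h$shape)
  n <- prod(shape)
  con <- file(file.path(path, "dose.f64"), "rb")
  dvec <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(dvec) != n) stop_format("dose array is truncated")
  grid <- dose_grid(array(dvec, shape), spacing = h$spacing_mm,
                    origin = h$origin_mm, frame_id = h$frame_id)
  sdefs <- h$structures
  masks <- lapply(seq_len(nrow(sdefs)), function(i) {
    con <- file(file.path(path, sdefs$file[i]), "rb")
    mvec <- readBin(con, what = "integer", n = n, size = 1, signed = FALSE,
                    endian = "little")
    close(con)
    if (length(mvec) != n) stop_format("mask array is truncated")
    structure_mask(sdefs$name[i], array(mvec > 0, shape), grid = grid)
  })
  if (!"PTV" %in% sdefs$name) {
    stop_validation("plan has no PTV structure")
  }
  ss <- structure_set(masks, isocenter = h$isocenter_mm)
  sbrt_plan(grid, ss, prescription(h$prescription$total_dose_gy,
                                   h$prescription$n_fractions),
            patient_id = h$patient_id)
}

#' Rasterize planar contours onto a grid geometry
#'
#' Converts a stack of closed planar polygons (the geometry carried by an
#' RT structure set) into a voxel mask by a voxel-centre-inside test with
#' the even-odd rule, slice by slice: each contour is assigned to the grid
#' slice whose voxel-centre z is nearest, and voxels whose (x, y) centre
#' falls inside an odd number of polygons on that slice are occupied.
#' Partial voxels are not fractionally weighted.
#'
#' @param name structure name for the resulting mask.
#' @param contours a list; each element is a list with `z` (mm) and
#'   `vertices`, an n x 2 matrix of (x, y) mm polygon vertices (closed
#'   implicitly).
#' @param grid a [dose_grid()] supplying the geometry.
#' @return A [structure_mask()].
#' @export
rasterize_contours <- function(name, contours, grid) {
  occ <- array(FALSE, grid$shape)
  ax <- axis_coords(grid)
  for (ct in contours) {
    k <- which.min(abs(ax[[3]] - ct$z))
    if (abs(ax[[3]][k] - ct$z) > grid$spacing[3] / 2 + 1e-9) next  # off-grid slice
    inside <- point_in_polygon(ax[[1]], ax[[2]], ct$vertices)
    occ[, , k] <- xor(occ[, , k], inside)                 # even-odd across contours
  }
  structure_mask(name, occ, grid = grid)
}

# Even-odd (ray-crossing) test of the grid of points (xs x ys) against one
# polygon given as an n x 2 vertex matrix. Returns a logical matrix.
point_in_polygon <- function(xs, ys, verts) {
  nx <- length(xs); ny <- length(ys)
  px <- verts[, 1]; py <- verts[, 2]
  n <- length(px)
  inside <- matrix(FALSE, nx, ny)
  j <- n
  Y <- matrix(rep(ys, each = nx), nx, ny)
  X <- matrix(rep(xs, ny), nx, ny)
  for (i in seq_len(n)) {
    crosses <- ((py[i] > Y) != (py[j] > Y))
    if (any(crosses)) {
      xint <- px[i] + (Y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      inside <- xor(inside, crosses & (X < xint))
    }
    j <- i
  }
  inside
}

#' Write a compliance report or cohort table to CSV or JSON
#'
#' Deterministic row and column ordering; CSV and JSON carry identical
#' values. Compliance reports use the fixed columns `patient_id`, `metric`,
#' `value`, `band_low`, `band_high`, `category`.
#'
#' @param report a `compliance_report` or any data frame (e.g. a cohort or
#'   metrics table).
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_format("unknown report format"))
  df <- as.data.frame(report)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}
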