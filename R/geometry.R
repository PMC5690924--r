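# 3D mask algebra and metric geometry on the dose grid.
#
# Margin expansion is exact binary dilation with an anisotropic ellipsoidal
# structuring element: voxel j belongs to expand(mask, m) iff some occupied
# voxel i satisfies ||(i - j) * spacing|| <= m. This is identical to
# thresholding the Euclidean distance transform at m, and is evaluated here
# by FFT convolution of the mask with the 0/1 structuring element (the
# convolution value is an integer overlap count, so thresholding at 0.5 is
# robust to FFT round-off).

#' Expand a structure mask by a physical margin
#'
#' Returns the set of voxels whose centre lies within `margin` mm
#' (anisotropic Euclidean distance, inclusive) of the centre of some
#' occupied voxel. `margin = 0` is the identity. Used for PTV margin growth
#' and for the 2 cm exclusion shell of the D2cm metric.
#'
#' @param mask a [structure_mask()].
#' @param margin margin in mm (>= 0).
#' @param name name for the result; default `"<name>+<margin>mm"`.
#' @return A `structure_mask` on the same grid.
#' @export
expand_mask <- function(mask, margin, name = NULL) {
  if (!is.finite(margin) || margin < 0) {
    stop_validation("`margin` must be a non-negative number of mm")
  }
  if (is.null(name)) name <- sprintf("%s+%gmm", mask$name, margin)
  out <- mask
  out$name <- name
  if (margin == 0 || !any(mask$occupancy)) return(out)

  sp <- mask$spacing
  r <- floor(margin / sp)                       # kernel half-extent in voxels
  kd <- 2 * r + 1
  off <- lapply(1:3, function(k) ((-r[k]):(r[k])) * sp[k])
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, `+`), off[[3]]^2, `+`)
  kern <- array(as.numeric(d2 <= margin^2 + 1e-9), dim = kd)
  if (sum(kern) == 1) return(out)               # margin below half a voxel

  out$occupancy <- fft_dilate(mask$occupancy, kern, r)
  out
}

# Full 3D binary dilation via FFT convolution; `r` is the kernel centre
# offset (half-extent in voxels per axis).
fft_dilate <- function(occ, kern, r) {
  d <- dim(occ)
  kd <- dim(kern)
  cd <- d + kd - 1
  pd <- vapply(cd, function(n) stats::nextn(n, factors = c(2, 3, 5)), numeric(1))
  a <- array(0, pd)
  a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- occ
  b <- array(0, pd)
  b[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kern
  conv <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / prod(pd)
  win <- conv[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), r[3] + seq_len(d[3])]
  win > 0.5
}

#' Boolean operations on structure masks
#'
#' Voxelwise set algebra; both masks must share one frame of reference.
#' `mask_subtract(a, b)` is the canonical way to form "total normal lung" as
#' lungs minus the internal target volume.
#'
#' @param a,b `structure_mask` objects on the same frame.
#' @param name name for the result.
#' @return A `structure_mask`.
#' @export
mask_subtract <- function(a, b, name = sprintf("%s-%s", a$name, b$name)) {
  check_same_frame(a, b)
  out <- a
  out$name <- name
  out$occupancy <- a$occupancy & !b$occupancy
  out
}

#' @rdname mask_subtract
#' @export
mask_union <- function(a, b, name = sprintf("%s+%s", a$name, b$name)) {
  check_same_frame(a, b)
  out <- a
  out$name <- name
  out$occupancy <- a$occupancy | b$occupancy
  out
}

#' @rdname mask_subtract
#' @export
mask_intersect <- function(a, b, name = sprintf("%s&%s", a$name, b$name)) {
  check_same_frame(a, b)
  out <- a
  out$name <- name
  out$occupancy <- a$occupancy & b$occupancy
  out
}

#' Complement of a structure mask
#'
#' @param a a `structure_mask`.
#' @param name name for the result.
#' @return A `structure_mask` occupying every voxel not in `a`.
#' @export
mask_complement <- function(a, name = sprintf("not-%s", a$name)) {
  out <- a
  out$name <- name
  out$occupancy <- !a$occupancy
  out
}

#' Volume enclosed by an isodose level
#'
#' Volume (cc) of voxels with dose greater than or equal to `level`,
#' optionally restricted to a mask. The numerator of the conformity and
#' intermediate-spillage ratios.
#'
#' @param dose a [dose_grid()].
#' @param level dose level in Gy (>= 0).
#' @param within optional `structure_mask` restricting the count.
#' @return Volume in cc.
#' @export
isodose_volume <- function(dose, level, within = NULL) {
  if (!is.finite(level) || level < 0) stop_validation("`level` must be >= 0 Gy")
  sel <- dose$dose >= level
  if (!is.null(within)) {
    check_same_frame(dose, within)
    sel <- sel & within$occupancy
  }
  sum(sel) * voxel_volume_cc(dose)
}

#' Minimum 3D distance from a point to a structure
#'
#' Minimum Euclidean distance (mm) from a physical point to the centre of
#' any occupied voxel; 0 if the point lies inside an occupied voxel. Used
#' for the isocenter-to-proximal-rib distance.
#'
#' @param point numeric length-3 coordinate in mm.
#' @param mask a non-empty `structure_mask`.
#' @return Distance in mm.
#' @export
min_distance_point_to_mask <- function(point, mask) {
  point <- as.numeric(point)
  if (length(point) != 3L || any(!is.finite(point))) {
    stop_validation("`point` must be a finite length-3 coordinate (mm)")
  }
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_validation(sprintf("structure '%s' is empty", mask$name))
  }
  # containing voxel: nearest voxel centre within half a voxel on every axis
  rel <- (point - mask$origin) / mask$spacing
  home <- round(rel) + 1
  if (all(home >= 1) && all(home <= mask$shape) &&
      mask$occupancy[home[1], home[2], home[3]]) {
    return(0)
  }
  centers <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin - point, `+`)
  sqrt(min(rowSums(centers^2)))
}
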