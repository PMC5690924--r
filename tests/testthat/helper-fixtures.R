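# Shared builders for tiny in-code fixtures and brute-force oracles.

# A uniform-dose grid with unit-cc voxels (10 mm pitch).
uniform_grid <- function(value = 10, shape = c(2, 2, 2), spacing = c(10, 10, 10)) {
  dose_grid(array(value, shape), spacing = spacing)
}

full_mask <- function(grid, name = "PTV") {
  structure_mask(name, array(TRUE, grid$shape), grid = grid)
}

# A random non-negative dose field with a fixed seed.
random_grid <- function(seed, shape = c(8, 8, 8), spacing = c(2, 2, 2)) {
  set.seed(seed)
  dose_grid(array(stats::runif(prod(shape), 0, 60), shape), spacing = spacing)
}

random_mask <- function(seed, grid, p = 0.3, name = "m") {
  set.seed(seed)
  structure_mask(name, array(stats::runif(prod(grid$shape)) < p, grid$shape),
                 grid = grid)
}

# Brute-force margin expansion: voxel j occupied iff some occupied voxel i
# has center-to-center anisotropic distance <= margin. O(N * M); small
# grids only.
brute_expand <- function(mask, margin) {
  occ <- mask$occupancy
  sp <- mask$spacing
  idx_true <- which(occ, arr.ind = TRUE)
  if (nrow(idx_true) == 0) return(occ)
  all_idx <- which(array(TRUE, dim(occ)), arr.ind = TRUE)
  out <- logical(nrow(all_idx))
  tx <- t(idx_true)
  for (i in seq_len(nrow(all_idx))) {
    d2 <- colSums(((tx - all_idx[i, ]) * sp)^2)
    out[i] <- any(d2 <= margin^2 + 1e-9)
  }
  array(out, dim(occ))
}

# A quick small phantom for pipeline tests (2 mm grid, ~0.2 s to build).
quick_phantom <- function(ptv_volume_cc = 14.1, r100_scale = 1.05,
                          g50_mm = 8, ...) {
  make_phantom(phantom_config(ptv_volume_cc = ptv_volume_cc,
                              r100_scale = r100_scale, g50_mm = g50_mm, ...))
}

# Closed circular contours approximating a sphere of radius r_mm centred at
# `center`, one polygon per grid slice intersecting the sphere.
sphere_contours <- function(r_mm, center, grid, n_vertices = 144) {
  zs <- axis_coords(grid)[[3]]
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  out <- list()
  for (z in zs) {
    dz <- z - center[3]
    if (abs(dz) >= r_mm) next
    rho <- sqrt(r_mm^2 - dz^2)
    out[[length(out) + 1]] <- list(
      z = z,
      vertices = cbind(center[1] + rho * cos(th), center[2] + rho * sin(th))
    )
  }
  out
}
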