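# A hand-built miniature plan: known masks on a 20^3 grid of 2 mm voxels
# (coords 0..38 mm, centre at 19 mm). The rib shell spans radii 12-18 mm
# (~17 cc, enough for the 10 cc DVH query).
make_box_plan <- function(dose_fun, rx = 50, n_fx = 5) {
  shape <- c(20, 20, 20)
  g0 <- dose_grid(array(0, shape), spacing = c(2, 2, 2))
  ax <- axis_coords(g0)
  ctr <- c(19, 19, 19)
  X <- array(rep(ax[[1]], times = 400), shape) - ctr[1]
  Y <- array(rep(rep(ax[[2]], each = 20), times = 20), shape) - ctr[2]
  Z <- array(rep(ax[[3]], each = 400), shape) - ctr[3]
  r <- sqrt(X^2 + Y^2 + Z^2)
  grid <- dose_grid(dose_fun(r), spacing = c(2, 2, 2))
  ptv <- structure_mask("PTV", r <= 8, grid = grid)
  itv <- structure_mask("ITV", r <= 4, grid = grid)
  lungs <- structure_mask("lungs_total", array(TRUE, shape), grid = grid)
  ribs <- structure_mask("ribs", r >= 12 & r <= 18, grid = grid)
  cord <- structure_mask("spinal_cord", abs(X + 16) <= 2 & abs(Y) <= 2,
                         grid = grid)
  ss <- structure_set(list(ptv, itv, lungs, ribs, cord), isocenter = ctr)
  sbrt_plan(grid, ss, prescription(rx, n_fx), patient_id = "box")
}

test_that("conformity and spillage ratios behave on constructed plans", {
  # dose = Rx exactly on PTV, zero outside -> R100 = R50 = 1, D2cm = 0
  p <- make_box_plan(function(r) array(ifelse(r <= 8, 50, 0), dim(r)))
  expect_equal(compute_r100(p), 1)
  expect_equal(compute_r50(p), 1)
  expect_equal(suppressWarnings(compute_d2cm(p)), 0)

  # dose >= Rx everywhere -> R100 = grid volume / PTV volume, D2cm = 100%
  pu <- make_box_plan(function(r) array(60, dim(r)))
  ptv_cc <- mask_volume_cc(get_structure(pu, "PTV"))
  expect_equal(compute_r100(pu), 8000 * 0.008 / ptv_cc)
  expect_equal(suppressWarnings(compute_d2cm(pu)), 100 * 60 / 50)
  # the tight grid around this PTV legitimately truncates the 2 cm shell
  expect_warning(compute_d2cm(pu), "truncated")
})

test_that("R50 dominates R100 and D2cm tracks the analytic profile", {
  p <- quick_phantom()
  r100 <- compute_r100(p)
  r50 <- compute_r50(p)
  expect_gte(r50, r100)                       # 50% isodose encloses 100%
  gt <- attr(p, "ground_truth")
  expect_lt(abs(compute_d2cm(p) - gt$d2cm_pct), 2)
  expect_lt(compute_d2cm(p), 100)             # monotone falloff
})

test_that("lung metrics use lungs-minus-ITV and flag small lungs", {
  shape <- c(20, 20, 20)
  p0 <- make_box_plan(function(r) array(0, dim(r)))
  itv <- get_structure(p0, "ITV")
  n_normal <- 8000 - sum(itv$occupancy)
  k <- round(0.128 * n_normal)
  dosev <- rep(5, 8000)
  normal_idx <- which(!itv$occupancy)
  dosev[normal_idx[seq_len(k)]] <- 20        # inclusive threshold
  p <- p0
  p$dose <- dose_grid(array(dosev, shape), spacing = c(2, 2, 2))
  lm <- suppressWarnings(compute_lung_metrics(p))
  expect_equal(lm$v20_pct, 100 * k / n_normal)
  expect_equal(lm$v5_pct, 100)
  expect_true(lm$d1000cc_truncated)          # 64 cc of lung < 1000 cc
  # lung entirely inside the ITV is a contouring error
  p_bad <- p
  p_bad$structures$masks$lungs_total$occupancy <- itv$occupancy
  expect_error(suppressWarnings(compute_lung_metrics(p_bad)),
               class = "sbrteval_validation_error")
})

test_that("rib metrics obey the volume ordering and report the distance", {
  # uniform rib dose: every DVH query returns that dose
  p <- make_box_plan(function(r) array(ifelse(r >= 12 & r <= 18, 40, 0), dim(r)))
  rm <- compute_rib_metrics(p)
  expect_equal(rm$dmax_gy, 40)
  expect_equal(rm$d1cc_gy, 40)
  expect_equal(rm$d5cc_gy, 40)
  expect_equal(rm$d10cc_gy, 40)
  expect_equal(rm$iso_to_rib_mm, min_distance_point_to_mask(
    p$structures$isocenter, get_structure(p, "ribs")))

  # gradient across the ribs: queries match the brute-force sorted voxels
  pg <- make_box_plan(function(r) array(pmax(0, 60 - 2 * r), dim(r)))
  ribs <- get_structure(pg, "ribs")
  rg <- compute_rib_metrics(pg)
  sorted <- sort(pg$dose$dose[ribs$occupancy], decreasing = TRUE)
  expect_true(rg$dmax_gy >= rg$d1cc_gy && rg$d1cc_gy >= rg$d5cc_gy &&
                rg$d5cc_gy >= rg$d10cc_gy)
  expect_equal(rg$dmax_gy, sorted[1])
  expect_equal(rg$d1cc_gy, sorted[125])      # 1 cc = exactly 125 voxels
  expect_equal(rg$d5cc_gy, sorted[625])
  expect_equal(rg$d10cc_gy, sorted[1250])

  # rib smaller than 10 cc: D10cc undefined
  ps <- make_box_plan(function(r) array(ifelse(r >= 14 & r <= 15, 30, 0), dim(r)))
  shell_idx <- which(ps$structures$masks$ribs$occupancy)
  keep <- array(FALSE, c(20, 20, 20))
  keep[shell_idx[seq_len(900)]] <- TRUE
  ps$structures$masks$ribs$occupancy <- keep
  expect_lt(mask_volume_cc(get_structure(ps, "ribs")), 10)
  expect_warning(rs <- compute_rib_metrics(ps), "undefined")
  expect_true(is.na(rs$d10cc_gy))
})

test_that("cord metric reads the hottest 0.35 cc and degrades gracefully", {
  # hottest 0.35 cc (43.75 of the 0.008 cc voxels) constructed at 18.3 Gy
  p <- make_box_plan(function(r) array(0, dim(r)))
  cord <- get_structure(p, "spinal_cord")
  idx <- which(cord$occupancy)
  expect_gte(length(idx), 60)
  dosev <- rep(0, 8000)
  dosev[idx] <- 2
  dosev[idx[1:50]] <- 18.3
  p$dose <- dose_grid(array(dosev, c(20, 20, 20)), spacing = c(2, 2, 2))
  expect_equal(compute_cord_metric(p), 18.3)
  # missing cord: metric absent, no crash
  p$structures$masks$spinal_cord <- NULL
  expect_true(is.na(compute_cord_metric(p)))
})

test_that("metric extraction is deterministic and complete on a phantom", {
  p <- quick_phantom(iso_to_rib_mm = 30)
  m1 <- suppressWarnings(extract_metrics(p))
  m2 <- suppressWarnings(extract_metrics(p))
  expect_identical(m1, m2)
  expect_lt(abs(m1$iso_to_rib_mm - 30), 2 * sqrt(3))  # within a voxel diagonal
  expect_false(any(is.na(m1[c("r100", "r50", "d2cm_pct", "lung_v20_pct",
                              "rib_dmax_gy", "rib_d1cc_gy")])))
  # rescaling by 1 changes nothing
  p1 <- p
  p1$dose$dose <- p$dose$dose * 1.0
  expect_identical(suppressWarnings(extract_metrics(p1)), m1)
})
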