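test_that("margin expansion equals the brute-force distance predicate", {
  # single seed voxel, isotropic spacing
  g <- dose_grid(array(0, c(15, 15, 15)), spacing = c(2, 2, 2))
  occ <- array(FALSE, g$shape); occ[8, 8, 8] <- TRUE
  m <- structure_mask("seed", occ, grid = g)
  ex <- expand_mask(m, 10)
  expect_identical(ex$occupancy, brute_expand(m, 10))

  # anisotropic spacing
  ga <- dose_grid(array(0, c(13, 13, 9)), spacing = c(2, 2, 4))
  occa <- array(FALSE, ga$shape); occa[7, 7, 5] <- TRUE
  ma <- structure_mask("seed", occa, grid = ga)
  exa <- expand_mask(ma, 6)
  expect_identical(exa$occupancy, brute_expand(ma, 6))

  # random sparse masks
  for (seed in 1:3) {
    gr <- dose_grid(array(0, c(14, 12, 10)), spacing = c(2, 3, 2.5))
    mr <- random_mask(seed, gr, p = 0.04)
    for (margin in c(0, 4, 7.3)) {
      expect_identical(expand_mask(mr, margin)$occupancy,
                       brute_expand(mr, margin))
    }
  }
})

test_that("expansion is monotone and the identity at zero margin", {
  g <- dose_grid(array(0, c(12, 12, 12)), spacing = c(2, 2, 2))
  m <- random_mask(42, g, p = 0.05)
  expect_identical(expand_mask(m, 0)$occupancy, m$occupancy)
  e1 <- expand_mask(m, 4)$occupancy
  e2 <- expand_mask(m, 8)$occupancy
  expect_true(all(e1[m$occupancy]))        # mask contained in its expansion
  expect_true(all(e2[e1]))                 # nesting in the margin
  expect_error(expand_mask(m, -1), class = "sbrteval_validation_error")
})

test_that("boolean mask algebra partitions volumes and matches vector ops", {
  g <- dose_grid(array(0, c(8, 8, 8)), spacing = c(5, 5, 5))
  a <- random_mask(1, g, p = 0.4, name = "a")
  b <- random_mask(2, g, p = 0.4, name = "b")
  expect_equal(sum(mask_subtract(a, a)$occupancy), 0)
  expect_equal(mask_volume_cc(mask_subtract(a, b)) +
                 mask_volume_cc(mask_intersect(a, b)),
               mask_volume_cc(a))
  expect_identical(mask_union(a, b)$occupancy, a$occupancy | b$occupancy)
  expect_identical(mask_subtract(a, b)$occupancy, a$occupancy & !b$occupancy)
  other <- dose_grid(array(0, c(8, 8, 8)), spacing = c(5, 5, 5),
                     frame_id = "x")
  expect_error(mask_union(a, full_mask(other, "c")),
               class = "sbrteval_geometry_error")
})

test_that("isodose volumes count inclusively and follow an analytic falloff", {
  g <- dose_grid(array(50, c(10, 10, 10)), spacing = c(2, 2, 2))
  expect_equal(isodose_volume(g, 50), 8)   # 1000 voxels x 0.008 cc
  expect_equal(isodose_volume(g, 50.1), 0)

  # radial exponential falloff: dose = 100 exp(-r / 20) on a 1 mm grid;
  # the level-L isodose is a sphere of radius r(L) = -20 log(L / 100)
  n <- 81
  ax <- (seq_len(n) - 1) - (n - 1) / 2
  r <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  gf <- dose_grid(array(100 * exp(-r / 20), c(n, n, n)), spacing = c(1, 1, 1))
  for (level in c(40, 60, 80)) {
    analytic <- 4 / 3 * pi * (-20 * log(level / 100))^3 / 1000
    expect_lt(abs(isodose_volume(gf, level) - analytic) / analytic, 0.02)
  }
  expect_true(isodose_volume(gf, 40) > isodose_volume(gf, 60))
})

test_that("point-to-structure distance is Euclidean and zero inside", {
  g <- dose_grid(array(0, c(40, 50, 10)), spacing = c(1, 1, 1))
  occ <- array(FALSE, g$shape); occ[31, 41, 1] <- TRUE  # center (30, 40, 0)
  m <- structure_mask("rib", occ, grid = g)
  expect_equal(min_distance_point_to_mask(c(0, 0, 0), m), 50)  # 3-4-5 triangle
  expect_equal(min_distance_point_to_mask(c(30.3, 40.2, 0.1), m), 0)

  for (seed in 4:5) {
    gr <- dose_grid(array(0, c(10, 10, 10)), spacing = c(2, 3, 2))
    mr <- random_mask(seed, gr, p = 0.05)
    pt <- c(-3, 7, 11)
    idx <- which(mr$occupancy, arr.ind = TRUE)
    centers <- sweep(idx - 1, 2, gr$spacing, `*`)
    brute <- sqrt(min(rowSums(sweep(centers, 2, pt)^2)))
    expect_equal(min_distance_point_to_mask(pt, mr), brute)
  }
  empty <- structure_mask("rib", array(FALSE, g$shape), grid = g)
  expect_error(min_distance_point_to_mask(c(0, 0, 0), empty),
               class = "sbrteval_validation_error")
})
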