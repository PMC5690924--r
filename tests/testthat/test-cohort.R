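test_that("linear-quadratic BED has the closed form and its monotonicities", {
  expect_equal(bed(0, 3), 0)
  expect_equal(bed(50, 5), 50 * (1 + 10 / 3))       # 216.67 Gy
  expect_equal(bed(54, 3), 54 * (1 + 18 / 3))       # 378 Gy
  # strictly increasing in total dose for fixed n
  doses <- seq(10, 60, by = 5)
  expect_true(all(diff(bed(doses, 5)) > 0))
  # fractionation sparing: more fractions, lower BED at fixed total dose
  expect_true(all(diff(bed(50, 1:8)) < 0))
  # BED -> physical dose as alpha/beta -> infinity
  expect_equal(bed(50, 5, alpha_beta = 1e9), 50, tolerance = 1e-6)
  expect_error(bed(50, 0), class = "sbrteval_validation_error")
  expect_error(bed(50, 5, alpha_beta = -3), class = "sbrteval_validation_error")
  expect_error(bed(-1, 5), class = "sbrteval_validation_error")
})

test_that("cohort summaries use the sample standard deviation", {
  co <- reference_cohort()
  s <- summarize_cohort(co, "r100")
  expect_equal(round(s$mean, 2), 1.25)
  expect_equal(round(s$sd, 2), 0.09)
  expect_equal(s$n, 20)
  two <- data.frame(x = c(1, 3))
  s2 <- summarize_cohort(two, "x")
  expect_equal(s2$mean, 2)
  expect_equal(s2$sd, sqrt(2))
  expect_equal(summarize_cohort(data.frame(x = rep(4, 5)), "x")$sd, 0)
  expect_warning(s1 <- summarize_cohort(data.frame(x = 1), "x"), "sd undefined")
  expect_true(is.na(s1$sd))
  expect_error(summarize_cohort(co, "nope"), class = "sbrteval_validation_error")
})

test_that("deviation counting generalises beyond the reference cohort", {
  crit <- load_criteria()
  # an all-compliant synthetic cohort
  synth <- data.frame(
    patient_id = 1:6,
    ptv_cc = c(15, 25, 40, 60, 100, 150),
    r100 = rep(1.1, 6),
    r50 = c(4.0, 4.0, 3.8, 3.5, 3.2, 2.8),
    d2cm_pct = c(45, 50, 55, 60, 65, 70),
    lung_v20_pct = rep(5, 6)
  )
  dc <- deviation_counts(synth, crit)
  expect_true(all(dc$minor == 0) && all(dc$major == 0))
  expect_equal(dc$fully_compliant, 6)
  # a single-patient cohort equals its own plan-level report
  one <- reference_cohort()[2, ]
  dc1 <- deviation_counts(one, crit)
  rep1 <- evaluate_plan_compliance(one, crit)
  spill <- rep1$metric %in% c("r100", "r50", "d2cm", "lung_v20_pct")
  expect_equal(sum(dc1$minor),
               sum(rep1$category[rep1$metric %in%
                                   c("r100", "r50", "d2cm_pct",
                                     "lung_v20_pct")] == "minor"))
})

test_that("distance-dose association reports rank correlation and bands", {
  co <- reference_cohort()
  assoc <- distance_dose_association(co)
  expect_lt(assoc$rho, 0)                       # dose falls with distance
  expect_equal(assoc$n, 20)
  expect_named(assoc$band_means, c("<2cm", "2-5cm", ">5cm"))
  # near ribs run hotter than far ribs in this cohort
  expect_gt(assoc$band_means["<2cm"], assoc$band_means[">5cm"])

  # perfectly anti-monotone pairs give rho = -1
  anti <- data.frame(iso_to_rib_cm = 1:6, rib_dmax_gy = 60 - (1:6))
  expect_equal(distance_dose_association(anti)$rho, -1)
  # constant dose: undefined, flagged, no crash
  const <- data.frame(iso_to_rib_cm = 1:5, rib_dmax_gy = rep(50, 5))
  expect_warning(a0 <- distance_dose_association(const), "undefined")
  expect_true(is.na(a0$rho))
  tiny <- data.frame(iso_to_rib_cm = 1:2, rib_dmax_gy = c(50, 40))
  expect_warning(distance_dose_association(tiny), "fewer than 3")
})

test_that("the embedded cohort is complete and internally consistent", {
  co <- reference_cohort()
  expect_equal(nrow(co), 20)
  expect_equal(co$ptv_cc[1], 11.1)
  expect_equal(co$lung_v20_pct[20], 12.8)
  expect_false(anyDuplicated(co$patient_id) > 0)
  expect_true(all(co$rx_gy[co$n_fx == 3] == 54))
  expect_true(all(co$rx_gy[co$n_fx == 5] == 50))
  # rib dose ordering holds in every record
  expect_true(all(co$rib_dmax_gy >= co$rib_d1cc_gy &
                    co$rib_d1cc_gy >= co$rib_d5cc_gy &
                    co$rib_d5cc_gy >= co$rib_d10cc_gy))
})

test_that("cohort BED applies per-patient fractionation", {
  co <- reference_cohort()
  cb <- cohort_bed(co, "rib_dmax_gy")
  manual <- bed(co$rib_dmax_gy, co$n_fx)
  expect_equal(cb$per_patient, manual)
  expect_equal(cb$mean, mean(manual))
  expect_error(cohort_bed(co, "nope"), class = "sbrteval_validation_error")
})
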