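# Radiobiology and cohort-level analysis: linear-quadratic BED, summary
# statistics mirroring the published AVG/STDEV rows, deviation counting
# across the four spillage metrics, and the distance-dose association for
# rib toxicity screening.

#' Biologically effective dose (linear-quadratic model)
#'
#' `BED = n d (1 + d / (alpha/beta))` with `d = total_dose / n_fractions`,
#' i.e. the total physical dose is assumed to be delivered in equal
#' fractions. For rib (late-responding bone) analyses the conventional
#' `alpha_beta = 3` Gy is the default. Vectorised over `total_dose` and
#' `n_fractions`.
#'
#' @param total_dose total physical dose in Gy (>= 0).
#' @param n_fractions number of fractions (integer >= 1).
#' @param alpha_beta tissue alpha/beta ratio in Gy (> 0); default 3.
#' @return BED in Gy.
#' @examples
#' bed(50, 5)            # 50 * (1 + 10/3) = 216.67 Gy
#' bed(54, 3)            # 54 * (1 + 18/3) = 378 Gy
#' @export
bed <- function(total_dose, n_fractions, alpha_beta = 3) {
  if (any(!is.finite(alpha_beta)) || any(alpha_beta <= 0)) {
    stop_validation("`alpha_beta` must be > 0 Gy")
  }
  if (any(!is.finite(n_fractions)) || any(n_fractions < 1)) {
    stop_validation("`n_fractions` must be >= 1")
  }
  if (any(total_dose < 0)) stop_validation("`total_dose` must be >= 0 Gy")
  d <- total_dose / n_fractions
  total_dose * (1 + d / alpha_beta)
}

#' Cohort summary of one metric column
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum over the non-missing values of a cohort column — the
#' published tables' AVG and STDEV rows.
#'
#' @param cohort a data frame (e.g. [reference_cohort()] or row-bound
#'   [extract_metrics()] results).
#' @param field column name.
#' @return A list with `mean`, `sd`, `min`, `max` and `n`. With fewer than
#'   two values `sd` is `NA` and a warning is issued.
#' @export
summarize_cohort <- function(cohort, field) {
  x <- cohort[[field]]
  if (is.null(x)) stop_validation(sprintf("no column '%s' in cohort", field))
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    warning(sprintf("fewer than 2 values for '%s'; sd undefined", field),
            call. = FALSE)
    return(list(mean = if (length(x)) mean(x) else NA_real_, sd = NA_real_,
                min = if (length(x)) min(x) else NA_real_,
                max = if (length(x)) max(x) else NA_real_, n = length(x)))
  }
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
       n = length(x))
}

#' Count protocol deviations across a cohort
#'
#' Classifies R100%, R50%, D2cm and normal-lung V20 for every patient
#' (volume-dependent bands resolved from each patient's PTV volume) and
#' counts minor and major deviations per metric, plus the number of
#' patients with no deviation in any of the four metrics.
#'
#' @param cohort a data frame with columns `ptv_cc`, `r100`, `r50`,
#'   `d2cm_pct`, `lung_v20_pct` (e.g. [reference_cohort()]).
#' @param criteria a [load_criteria()] table.
#' @return A list with `minor` and `major` (named integer vectors over the
#'   four metrics), `fully_compliant` (count of patients), and `per_patient`
#'   (data frame of per-patient categories).
#' @export
deviation_counts <- function(cohort, criteria = load_criteria()) {
  metrics <- c("r100", "r50", "d2cm_pct", "lung_v20_pct")
  cats <- vapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    c(
      r100 = classify_value(row$r100, criteria$r100_band),
      r50 = classify_value(row$r50, interpolate_band(criteria, "r50", row$ptv_cc)),
      d2cm_pct = classify_value(row$d2cm_pct,
                                interpolate_band(criteria, "d2cm", row$ptv_cc)),
      lung_v20_pct = classify_value(row$lung_v20_pct, criteria$v20_band)
    )
  }, character(4))
  per_patient <- as.data.frame(t(cats), stringsAsFactors = FALSE)
  per_patient <- cbind(
    patient_id = if (!is.null(cohort$patient_id)) cohort$patient_id
                 else seq_len(nrow(cohort)),
    per_patient
  )
  minor <- vapply(metrics, function(mt) sum(cats[mt, ] == "minor"), integer(1))
  major <- vapply(metrics, function(mt) sum(cats[mt, ] == "major"), integer(1))
  fully <- sum(colSums(cats != "per_protocol") == 0)
  list(minor = minor, major = major, fully_compliant = fully,
       per_patient = per_patient)
}

#' Association between isocenter-to-rib distance and maximum rib dose
#'
#' Spearman rank correlation between the 3D isocenter-to-proximal-rib
#' distance and the maximum rib dose, plus mean maximum rib dose in the
#' qualitative distance bands below 2 cm, 2 to 5 cm and above 5 cm.
#'
#' @param cohort a data frame with columns `iso_to_rib_cm` and
#'   `rib_dmax_gy`.
#' @return A list with `rho` (Spearman; `NA` with a warning when either
#'   variable is constant), `n`, and `band_means` (named numeric vector for
#'   the three distance bands).
#' @export
distance_dose_association <- function(cohort) {
  ok <- !is.na(cohort$iso_to_rib_cm) & !is.na(cohort$rib_dmax_gy)
  d <- cohort$iso_to_rib_cm[ok]
  dose <- cohort$rib_dmax_gy[ok]
  if (length(d) < 3) {
    warning("fewer than 3 complete (distance, dose) pairs", call. = FALSE)
    return(list(rho = NA_real_, n = length(d), band_means = NULL))
  }
  rho <- if (stats::sd(d) == 0 || stats::sd(dose) == 0) {
    warning("constant distance or dose; correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(d, dose, method = "spearman")
  }
  band <- cut(d, breaks = c(-Inf, 2, 5, Inf),
              labels = c("<2cm", "2-5cm", ">5cm"), right = TRUE)
  band_means <- tapply(dose, band, mean)
  list(rho = rho, n = length(d), band_means = band_means)
}

#' Cohort BED summary for rib dose metrics
#'
#' Applies [bed()] to a rib dose column using each patient's own
#' fractionation (`n_fx` column) and summarizes the result.
#'
#' @param cohort a data frame with the dose column and `n_fx`.
#' @param field dose column, e.g. `"rib_dmax_gy"` or `"rib_d1cc_gy"`.
#' @param alpha_beta alpha/beta ratio in Gy; default 3 (ribs).
#' @return A list with `mean`, `sd`, `per_patient` (BED vector, Gy).
#' @examples
#' # reproduces the published rib BED3 means (249 and 173 Gy):
#' round(cohort_bed(reference_cohort(), "rib_dmax_gy")$mean)
#' round(cohort_bed(reference_cohort(), "rib_d1cc_gy")$mean)
#' @export
cohort_bed <- function(cohort, field, alpha_beta = 3) {
  dose <- cohort[[field]]
  if (is.null(dose)) stop_validation(sprintf("no column '%s' in cohort", field))
  if (is.null(cohort$n_fx)) stop_validation("cohort has no `n_fx` column")
  b <- bed(dose, cohort$n_fx, alpha_beta)
  list(mean = mean(b), sd = stats::sd(b), per_patient = b)
}
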