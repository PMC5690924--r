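# Protocol compliance classification.
#
# The high-dose conformity band (R100%) and the normal-lung V20 band are
# volume-independent; the intermediate-dose spillage bands (R50%, D2cm) vary
# with PTV volume and are interpolated linearly between anchor rows of a
# criteria table. OAR limits are single thresholds.
#
# Boundary rule: a value at or below the lower bound is per-protocol; above
# the lower bound up to and including the upper bound is a minor deviation;
# beyond the upper bound is major. This strict-lower / inclusive-upper rule
# is the one that reproduces every published deviation flag of the embedded
# reference cohort (e.g. R50% = 4.2 against band 4.2-5.2 is per-protocol,
# while D2cm = 61.9 against band 53.1-61.9 is a minor deviation).

#' A compliance band for one metric
#'
#' @param lower per-protocol threshold (values <= lower are per-protocol).
#' @param upper minor-deviation ceiling (values > upper are major).
#' @return An object of class `metric_band`.
#' @export
metric_band <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (!is.finite(lower) || !is.finite(upper) || lower > upper) {
    stop_validation("band requires finite lower <= upper")
  }
  structure(list(lower = lower, upper = upper), class = "metric_band")
}

#' @export
print.metric_band <- function(x, ...) {
  cat(sprintf("<metric_band> per-protocol <= %g; minor <= %g; major above\n",
              x$lower, x$upper))
  invisible(x)
}

#' Load a compliance criteria table
#'
#' Reads a JSON criteria file holding the volume-independent `r100_band`
#' and `v20_band`, the volume-dependent `r50_anchors` and `d2cm_anchors`
#' (rows of `ptv_cc`, `lower`, `upper` with strictly increasing volumes),
#' and named `oar_limits` in Gy. The default file shipped with the package
#' encodes the RTOG 0915 criteria for peripheral lung SBRT.
#'
#' @param path JSON file; default is the in-package criteria file.
#' @return An object of class `criteria_table`.
#' @examples
#' crit <- load_criteria()
#' interpolate_band(crit, "r50", 27.1)
#' @export
load_criteria <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rtog0915_criteria.json", package = "sbrteval")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_format("criteria file not found")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_anchors <- function(a, what) {
    if (is.null(a) || nrow(a) == 0) {
      stop(errorCondition(sprintf("criteria table has no %s anchors", what),
                          class = c("sbrteval_config_error", "error", "condition")))
    }
    if (is.unsorted(a$ptv_cc, strictly = TRUE)) {
      stop_validation(sprintf("%s anchor volumes must be strictly increasing", what))
    }
    if (any(a$lower > a$upper)) {
      stop_validation(sprintf("%s anchors contain an invalid band", what))
    }
    a
  }
  structure(
    list(
      name = raw$name,
      r100_band = metric_band(raw$r100_band$lower, raw$r100_band$upper),
      v20_band = metric_band(raw$v20_band$lower, raw$v20_band$upper),
      r50_anchors = check_anchors(raw$r50_anchors, "R50%"),
      d2cm_anchors = check_anchors(raw$d2cm_anchors, "D2cm"),
      oar_limits = unlist(raw$oar_limits)
    ),
    class = "criteria_table"
  )
}

#' Resolve the volume-dependent band for a PTV volume
#'
#' Linear interpolation of the lower and upper bounds between the two
#' bracketing anchor rows; outside the anchored volume range the end
#' anchor's band applies (clamping). At an anchor volume the anchor's band
#' is returned exactly.
#'
#' @param criteria a [load_criteria()] table.
#' @param metric `"r50"` or `"d2cm"`.
#' @param ptv_cc PTV volume in cc (> 0).
#' @return A [metric_band()].
#' @export
interpolate_band <- function(criteria, metric = c("r50", "d2cm"), ptv_cc) {
  metric <- match.arg(metric)
  if (!is.finite(ptv_cc) || ptv_cc <= 0) {
    stop_validation("`ptv_cc` must be positive")
  }
  a <- if (metric == "r50") criteria$r50_anchors else criteria$d2cm_anchors
  lo <- stats::approx(a$ptv_cc, a$lower, xout = ptv_cc, rule = 2)$y
  hi <- stats::approx(a$ptv_cc, a$upper, xout = ptv_cc, rule = 2)$y
  metric_band(lo, hi)
}

#' Classify a metric value against a band
#'
#' Per-protocol if `value <= lower`; minor deviation if
#' `lower < value <= upper`; major deviation if `value > upper`.
#'
#' @param value metric value.
#' @param band a [metric_band()].
#' @return One of `"per_protocol"`, `"minor"`, `"major"` (or
#'   `"not_applicable"` for `NA` input).
#' @export
classify_value <- function(value, band) {
  if (is.na(value)) return("not_applicable")
  if (value <= band$lower) "per_protocol"
  else if (value <= band$upper) "minor"
  else "major"
}

#' Check an organ-at-risk dose against a single threshold
#'
#' OAR limits are stated as a single "greater than X Gy" threshold, so
#' exceedance is reported as a (minor) deviation with no minor/major split.
#'
#' @param value dose in Gy (`NA` allowed: not applicable).
#' @param limit threshold in Gy (> 0). Values at the limit are
#'   per-protocol.
#' @return `"per_protocol"`, `"minor"` or `"not_applicable"`.
#' @export
check_oar <- function(value, limit) {
  if (!is.finite(limit) || limit <= 0) stop_validation("`limit` must be > 0 Gy")
  if (is.na(value)) return("not_applicable")
  if (value <= limit) "per_protocol" else "minor"
}

#' Evaluate a plan's metrics against a criteria table
#'
#' Resolves the volume-dependent bands from the plan's PTV volume,
#' classifies the four spillage metrics (R100%, R50%, D2cm, V20) and the
#' OAR doses, and sets the plan-level `fully_compliant` flag: no minor or
#' major deviation among the four spillage metrics and no OAR limit
#' exceeded.
#'
#' @param metrics a [extract_metrics()] result, or any one-row data frame /
#'   list with fields `patient_id`, `ptv_cc`, `r100`, `r50`, `d2cm_pct`,
#'   `lung_v20_pct` and (optionally) the OAR dose fields named as in the
#'   criteria `oar_limits`.
#' @param criteria a [load_criteria()] table.
#' @return An object of class `compliance_report`: a data frame with
#'   columns `patient_id`, `metric`, `value`, `band_low`, `band_high`,
#'   `category`, and the logical `attr(, "fully_compliant")`.
#' @export
evaluate_plan_compliance <- function(metrics, criteria = load_criteria()) {
  m <- as.list(metrics)
  required <- c("ptv_cc", "r100", "r50", "d2cm_pct", "lung_v20_pct")
  missing <- required[!vapply(required, function(f)
    !is.null(m[[f]]) && !is.na(m[[f]]), logical(1))]
  if (length(missing) > 0) {
    stop_validation(paste("missing required metric(s):",
                          paste(missing, collapse = ", ")))
  }
  pid <- if (is.null(m$patient_id)) "anonymous" else m$patient_id
  r50_band <- interpolate_band(criteria, "r50", m$ptv_cc)
  d2cm_band <- interpolate_band(criteria, "d2cm", m$ptv_cc)

  rows <- list(
    list("r100", m$r100, criteria$r100_band),
    list("r50", m$r50, r50_band),
    list("d2cm_pct", m$d2cm_pct, d2cm_band),
    list("lung_v20_pct", m$lung_v20_pct, criteria$v20_band)
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = pid, metric = r[[1]], value = r[[2]],
               band_low = r[[3]]$lower, band_high = r[[3]]$upper,
               category = classify_value(r[[2]], r[[3]]),
               stringsAsFactors = FALSE)
  }))
  oar <- do.call(rbind, lapply(names(criteria$oar_limits), function(f) {
    val <- if (is.null(m[[f]])) NA_real_ else as.numeric(m[[f]])
    lim <- criteria$oar_limits[[f]]
    data.frame(patient_id = pid, metric = f, value = val,
               band_low = NA_real_, band_high = lim,
               category = check_oar(val, lim), stringsAsFactors = FALSE)
  }))
  report <- rbind(df, oar)
  fully <- all(df$category == "per_protocol") &&
    !any(oar$category %in% c("minor", "major"))
  class(report) <- c("compliance_report", "data.frame")
  attr(report, "fully_compliant") <- fully
  report
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> patient '%s' — %s\n",
              x$patient_id[1],
              if (isTRUE(attr(x, "fully_compliant"))) "fully compliant"
              else "deviations present"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
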