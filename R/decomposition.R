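#' Per-sample quadrature decomposition of total variation
#'
#' The measured total variation of a propagated contour mixes residual
#' registration error with intraobserver delineation variation. Treating
#' the two as independent, population-like components, the registration
#' residual is recovered per contour by quadrature subtraction:
#' `Edef = sqrt(max(vt^2 - via^2, 0))`, where `via` is the ROI-level mean
#' intraobserver variation (intraobserver variation is measured only on a
#' patient subset, so a per-patient subtraction is not available — using
#' the ROI-level mean is also the only construction that gives Edef the
#' same sample size and a spread like the total variation's). A negative
#' discriminant is clamped to zero and flagged rather than silently
#' producing complex output.
#'
#' @param vt_value_mm total-variation distance(s), mm (vectorized)
#' @param via_mean_mm ROI-level mean intraobserver variation, mm (scalar)
#' @return numeric vector of Edef samples with logical attribute
#'   `"clamped"` marking entries where `vt < via`
#' @export
edef_per_sample <- function(vt_value_mm, via_mean_mm) {
  if (any(vt_value_mm < 0) || via_mean_mm < 0) {
    stop("distances must be non-negative")
  }
  disc <- vt_value_mm^2 - via_mean_mm^2
  clamped <- disc < 0
  out <- sqrt(pmax(disc, 0))
  attr(out, "clamped") <- clamped
  out
}

#' Quadrature margin synthesis
#'
#' Combined planning-margin expansion covering both the residual
#' registration error and interobserver variation, assumed independent:
#' `sqrt(edef^2 + vio^2)`. Inputs are unrounded means; rounding is applied
#' only at presentation.
#'
#' @param edef_mean_mm mean residual registration error, mm
#' @param vio_mean_mm mean interobserver variation, mm
#' @return combined margin, mm
#' @export
combined_margin <- function(edef_mean_mm, vio_mean_mm) {
  if (any(edef_mean_mm < 0) || any(vio_mean_mm < 0)) {
    stop("distances must be non-negative")
  }
  sqrt(edef_mean_mm^2 + vio_mean_mm^2)
}

#' Percent reduction achieved by the second registration pass
#'
#' @param edef_mean_mm mean residual error after the first pass, mm (> 0)
#' @param edef2_mean_mm mean residual error after the focused second pass, mm
#' @return percent decrease, `100 * (edef - edef2) / edef`
#' @export
second_pass_reduction <- function(edef_mean_mm, edef2_mean_mm) {
  if (edef_mean_mm <= 0) {
    stop("percent reduction undefined for edef_mean_mm <= 0")
  }
  100 * (edef_mean_mm - edef2_mean_mm) / edef_mean_mm
}

#' Decompose one ROI's variation records
#'
#' Applies the per-sample quadrature subtraction to every total-variation
#' record, aggregates with n-1 standard deviations, and synthesizes the
#' combined margin from the mean Edef (second-pass value when available
#' and `margin_uses_second_pass` is TRUE) and the mean interobserver
#' variation.
#'
#' @param vt_records tibble of `VT` variation records for one ROI
#' @param via_summary,vio_summary single summary rows (from
#'   [summarize_records()]) for the same ROI
#' @param vt2_records optional tibble of second-pass `VT2` records
#' @param margin_uses_second_pass use the second-pass Edef for the margin
#'   when available (default TRUE)
#' @return a one-row tibble (`decomposition result`) with means, SDs,
#'   counts, clamp counts, the margin, and the Edef sample vectors in list
#'   columns `edef_records` / `edef2_records`
#' @export
decompose_roi <- function(vt_records, via_summary, vio_summary,
                          vt2_records = NULL,
                          margin_uses_second_pass = TRUE) {
  roi <- unique(vt_records$roi)
  if (length(roi) != 1) stop("vt_records must cover exactly one ROI")
  if (via_summary$roi != roi || vio_summary$roi != roi) {
    stop("summary rows do not match ROI '", roi, "'")
  }
  via_mean <- via_summary$mean_mm
  e <- edef_per_sample(vt_records$value_mm, via_mean)
  clamped <- sum(attr(e, "clamped"))
  e <- as.numeric(e)
  e2 <- NULL
  clamped2 <- 0L
  if (!is.null(vt2_records) && nrow(vt2_records) > 0) {
    e2 <- edef_per_sample(vt2_records$value_mm, via_mean)
    clamped2 <- sum(attr(e2, "clamped"))
    e2 <- as.numeric(e2)
  }
  edef_for_margin <- if (margin_uses_second_pass && !is.null(e2)) {
    mean(e2)
  } else {
    mean(e)
  }
  tibble(
    roi = roi,
    n_vt = nrow(vt_records),
    vt_mean_mm = mean(vt_records$value_mm),
    vt_sd_mm = sd(vt_records$value_mm),
    via_n = via_summary$n,
    via_mean_mm = via_mean,
    vio_n = vio_summary$n,
    vio_mean_mm = vio_summary$mean_mm,
    vio_sd_mm = vio_summary$sd_mm,
    edef_records = list(e),
    edef_mean_mm = mean(e),
    edef_sd_mm = if (length(e) > 1) sd(e) else 0,
    edef2_n = if (is.null(e2)) 0L else length(e2),
    edef2_mean_mm = if (is.null(e2)) NA_real_ else mean(e2),
    edef2_sd_mm = if (is.null(e2) || length(e2) < 2) NA_real_ else sd(e2),
    edef2_records = list(e2),
    clamped_count = clamped + clamped2,
    margin_uses_second_pass = margin_uses_second_pass && !is.null(e2),
    margin_mm = combined_margin(edef_for_margin, vio_summary$mean_mm)
  )
}

#' Decompose every ROI of a cohort's records
#'
#' @param records tibble from [compute_all_records()] (or equivalent)
#' @param margin_uses_second_pass see [decompose_roi()]
#' @return tibble with one decomposition row per ROI
#' @export
decompose_records <- function(records, margin_uses_second_pass = TRUE) {
  summ <- summarize_records(records)
  rois <- unique(records$roi)
  rows <- lapply(rois, function(r) {
    vt <- dplyr::filter(records, .data$roi == r, .data$quantity == "VT")
    vt2 <- dplyr::filter(records, .data$roi == r, .data$quantity == "VT2")
    via_s <- dplyr::filter(summ, .data$roi == r, .data$quantity == "VIA")
    vio_s <- dplyr::filter(summ, .data$roi == r, .data$quantity == "VIO")
    if (nrow(vt) == 0 || nrow(via_s) == 0 || nrow(vio_s) == 0) return(NULL)
    decompose_roi(vt, via_s, vio_s,
                  vt2_records = if (nrow(vt2)) vt2 else NULL,
                  margin_uses_second_pass = margin_uses_second_pass)
  })
  dplyr::bind_rows(rows)
}
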