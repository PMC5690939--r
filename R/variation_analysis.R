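#' Interobserver variation records
#'
#' One record per patient: the directed mean surface distance between the
#' two observers' CT1 contours of one ROI, with observer 1's contour as the
#' primary surface. Patients missing the ROI (in either observer's set)
#' are skipped and reported in the `"skipped"` attribute, never imputed.
#'
#' @param bundle a `cohort_bundle`
#' @param roi ROI name
#' @param spacing_mm surface sampling step (mm)
#' @return tibble of variation records with columns `patient_id, roi,
#'   quantity, observer, value_mm, n_points`
#' @export
compute_vio <- function(bundle, roi, spacing_mm = 0.5) {
  rows <- list()
  skipped <- character()
  for (pat in bundle$patients) {
    a <- pat$roles$ROI11
    b <- pat$roles$ROI21
    if (!(roi %in% names(a$rois)) || !(roi %in% names(b$rois))) {
      skipped <- c(skipped, pat$id)
      next
    }
    res <- directed_mean_surface_distance(sample_surface(a, roi, spacing_mm),
                                          sample_surface(b, roi, spacing_mm))
    rows[[length(rows) + 1L]] <- tibble(
      patient_id = pat$id, roi = roi, quantity = "VIO",
      observer = NA_integer_, value_mm = res$mean_mm,
      n_points = res$n_primary)
  }
  if (length(rows) == 0) stop("ROI '", roi, "' absent for all patients")
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Total variation records
#'
#' Two records per patient — one per observer — comparing each observer's
#' original CT1 contour (primary) against that observer's propagated CT2
#' contour. The total-variation sample size is therefore twice the
#' interobserver one. `pass = 2` compares against the focused second-pass
#' propagation instead, for the patient/ROI subset that has one.
#'
#' @param bundle a `cohort_bundle`
#' @param roi ROI name
#' @param pass 1 (default) or 2
#' @param spacing_mm surface sampling step (mm)
#' @return tibble of variation records (`quantity` is `"VT"` or `"VT2"`)
#' @export
compute_vt <- function(bundle, roi, pass = 1, spacing_mm = 0.5) {
  stopifnot(pass %in% c(1, 2))
  qty <- if (pass == 1) "VT" else "VT2"
  suffix <- if (pass == 1) "D" else "D2"
  rows <- list()
  skipped <- character()
  for (pat in bundle$patients) {
    for (i in 1:2) {
      orig <- pat$roles[[paste0("ROI", i, "1")]]
      def <- pat$roles[[paste0("ROI", i, suffix)]]
      if (is.null(def) || !(roi %in% names(orig$rois)) ||
          !(roi %in% names(def$rois))) {
        skipped <- c(skipped, paste0(pat$id, "/obs", i))
        next
      }
      res <- directed_mean_surface_distance(
        sample_surface(orig, roi, spacing_mm),
        sample_surface(def, roi, spacing_mm))
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pat$id, roi = roi, quantity = qty,
        observer = i, value_mm = res$mean_mm, n_points = res$n_primary)
    }
  }
  if (length(rows) == 0) stop("no propagated contours for ROI '", roi, "'")
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Intraobserver variation records
#'
#' One record per observer per recontoured patient: each observer's
#' original CT1 contour (primary) against that observer's recontouring
#' session.
#'
#' @param bundle a `cohort_bundle`
#' @param roi ROI name
#' @param spacing_mm surface sampling step (mm)
#' @return tibble of variation records (`quantity = "VIA"`)
#' @export
compute_via <- function(bundle, roi, spacing_mm = 0.5) {
  if (length(bundle$recontour_ids) == 0) stop("recontour subset is empty")
  rows <- list()
  for (p in bundle$recontour_ids) {
    pat <- bundle$patients[[p]]
    for (i in 1:2) {
      orig <- pat$roles[[paste0("ROI", i, "1")]]
      rec <- pat$roles[[paste0("ROI", i, "A")]]
      if (is.null(rec) || !(roi %in% names(orig$rois)) ||
          !(roi %in% names(rec$rois))) next
      res <- directed_mean_surface_distance(
        sample_surface(orig, roi, spacing_mm),
        sample_surface(rec, roi, spacing_mm))
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pat$id, roi = roi, quantity = "VIA",
        observer = i, value_mm = res$mean_mm, n_points = res$n_primary)
    }
  }
  if (length(rows) == 0) stop("no recontours available for ROI '", roi, "'")
  dplyr::bind_rows(rows)
}

#' Ground-truth injected deformation distance records
#'
#' Only available for synthetic cohorts: the directed mean distance between
#' the residual-free propagated contour (primary) and the actually
#' propagated contour, i.e. the surface displacement caused purely by the
#' injected registration residual. This is the quantity the quadrature
#' decomposition is supposed to recover.
#'
#' @param bundle a `cohort_bundle`
#' @param roi ROI name
#' @param spacing_mm surface sampling step (mm)
#' @return tibble of variation records (`quantity = "VDEF_TRUE"`)
#' @export
compute_vdef_true <- function(bundle, roi, spacing_mm = 0.5) {
  rows <- list()
  for (pat in bundle$patients) {
    for (i in 1:2) {
      pre <- pat$roles[[paste0("ROI", i, "P")]]
      def <- pat$roles[[paste0("ROI", i, "D")]]
      if (is.null(pre) || is.null(def) || !(roi %in% names(pre$rois)) ||
          !(roi %in% names(def$rois))) next
      res <- directed_mean_surface_distance(
        sample_surface(pre, roi, spacing_mm),
        sample_surface(def, roi, spacing_mm))
      rows[[length(rows) + 1L]] <- tibble(
        patient_id = pat$id, roi = roi, quantity = "VDEF_TRUE",
        observer = i, value_mm = res$mean_mm, n_points = res$n_primary)
    }
  }
  if (length(rows) == 0) stop("no ground-truth propagation pairs for '", roi, "'")
  dplyr::bind_rows(rows)
}

#' All variation records of a cohort
#'
#' Convenience wrapper running [compute_vio()], [compute_vt()] (both
#' passes where present), [compute_via()] and [compute_vdef_true()] over
#' every ROI of the cohort.
#'
#' @param bundle a `cohort_bundle`
#' @param spacing_mm surface sampling step (mm)
#' @param include_truth include the synthetic ground-truth `VDEF_TRUE`
#'   records (default TRUE)
#' @return tibble of variation records
#' @export
compute_all_records <- function(bundle, spacing_mm = 0.5,
                                include_truth = TRUE) {
  rois <- vapply(bundle$phantoms, function(sp) sp$roi_name, character(1))
  out <- list()
  for (r in rois) {
    out[[length(out) + 1L]] <- compute_vio(bundle, r, spacing_mm)
    out[[length(out) + 1L]] <- compute_vt(bundle, r, 1, spacing_mm)
    if (r %in% names(bundle$second_pass_ids)) {
      out[[length(out) + 1L]] <- compute_vt(bundle, r, 2, spacing_mm)
    }
    out[[length(out) + 1L]] <- compute_via(bundle, r, spacing_mm)
    if (include_truth) {
      out[[length(out) + 1L]] <- compute_vdef_true(bundle, r, spacing_mm)
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize variation records
#'
#' Groups records by (roi, quantity) and reports the count, mean and sample
#' standard deviation (n-1 denominator). No rounding is applied here;
#' rounding belongs to presentation. Groups of size one get `sd_mm = 0` and
#' are flagged.
#'
#' @param records tibble of variation records
#' @return tibble with columns `roi, quantity, n, mean_mm, sd_mm, n1_flag`
#' @export
summarize_records <- function(records) {
  if (nrow(records) == 0) stop("no records to summarize")
  records |>
    dplyr::group_by(.data$roi, .data$quantity) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mm = mean(.data$value_mm),
                     sd_mm = if (dplyr::n() > 1) sd(.data$value_mm) else 0,
                     n1_flag = dplyr::n() == 1,
                     .groups = "drop")
}
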