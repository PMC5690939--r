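#' Planar contour constructor
#'
#' A closed planar polygon at a fixed axial plane. Closure is implicit: the
#' last vertex connects back to the first, and a duplicated closing vertex
#' is dropped on construction. Coordinates are patient-based millimetres
#' (x = patient-left, y = patient-posterior, z = patient-superior); voxel
#' indices never appear in the data model because the two CT studies of a
#' propagation pair generally differ in field of view and slice thickness.
#'
#' @param z_mm axial plane coordinate (mm)
#' @param xy two-column numeric matrix of in-plane vertices (mm), ordered
#'   around the polygon
#' @return an object of class `planar_contour`
#' @export
planar_contour <- function(z_mm, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("xy must have two columns")
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n >= 2 && sqrt(sum((xy[n, ] - xy[1, ])^2)) < 1e-9) {
    xy <- xy[-n, , drop = FALSE] # normalize files that store the closing vertex
  }
  structure(list(z_mm = as.numeric(z_mm), xy = xy),
            class = "planar_contour")
}

#' Structure set constructor
#'
#' A named collection of regions of interest (ROIs), each a z-ordered stack
#' of [planar_contour] polygons, all in a shared patient-based mm frame.
#' Multiple disjoint polygons may share one z-plane (e.g., a split lobe).
#'
#' @param study_id character study label
#' @param rois named list; each element is a list of [planar_contour]
#' @return an object of class `structure_set`
#' @export
structure_set <- function(study_id, rois) {
  if (length(rois) > 0 &&
      (is.null(names(rois)) || any(names(rois) == "") ||
         anyDuplicated(names(rois)))) {
    stop("rois must be uniquely named")
  }
  rois <- lapply(rois, function(cl) {
    cl[order(vapply(cl, function(ct) ct$z_mm, numeric(1)))]
  })
  structure(list(study_id = as.character(study_id), rois = rois),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>", x$study_id, "\n")
  for (nm in names(x$rois)) {
    zs <- vapply(x$rois[[nm]], function(ct) ct$z_mm, numeric(1))
    nv <- sum(vapply(x$rois[[nm]], function(ct) nrow(ct$xy), integer(1)))
    cat(sprintf("  %-24s %3d contours, %5d vertices, z in [%.1f, %.1f] mm\n",
                nm, length(zs), nv, min(zs), max(zs)))
  }
  invisible(x)
}

#' ROI names of a structure set
#' @param ss a [structure_set]
#' @return character vector
#' @export
roi_names <- function(ss) names(ss$rois)

#' Validate a structure set
#'
#' Checks every invariant of the contour model and reports each breach,
#' located by ROI and plane: at least three vertices per polygon, no
#' coincident consecutive vertices (within 1e-9 mm), strictly ordered
#' z-planes within an ROI (ties allowed only for genuinely distinct
#' polygons sharing a plane), finite coordinates, and polygon simplicity
#' (no self-intersection). Reporting only; it never throws.
#'
#' @param ss a [structure_set]
#' @param check_simple run the O(n^2) self-intersection test (default TRUE)
#' @return a `validation_report`: list with tibbles `errors` and `warnings`,
#'   each with columns `roi`, `z_mm`, `message`
#' @export
validate_structure_set <- function(ss, check_simple = TRUE) {
  err <- list()
  add <- function(roi, z, msg) {
    err[[length(err) + 1L]] <<- tibble(roi = roi, z_mm = z, message = msg)
  }
  if (length(ss$rois) == 0) add(NA_character_, NA_real_, "no ROIs present")
  for (nm in sort(names(ss$rois))) {
    contours <- ss$rois[[nm]]
    if (length(contours) == 0) {
      add(nm, NA_real_, "ROI has no contours")
      next
    }
    for (ct in contours) {
      z <- ct$z_mm
      xy <- ct$xy
      if (!all(is.finite(xy)) || !is.finite(z)) {
        add(nm, z, "non-finite coordinates")
        next
      }
      if (nrow(xy) < 3) {
        add(nm, z, sprintf("polygon has %d vertices (minimum 3)", nrow(xy)))
        next
      }
      d <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2))
      if (any(d < 1e-9)) add(nm, z, "coincident consecutive vertices")
      if (check_simple && !.cpp_polygon_is_simple(xy, 1e-9)) {
        add(nm, z, "polygon is not simple (self-intersecting)")
      }
    }
  }
  errors <- if (length(err)) dplyr::bind_rows(err) else
    tibble(roi = character(), z_mm = numeric(), message = character())
  errors <- dplyr::arrange(errors, .data$roi, .data$z_mm, .data$message)
  structure(list(errors = errors,
                 warnings = tibble(roi = character(), z_mm = numeric(),
                                   message = character())),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", nrow(x$errors), "errors,",
      nrow(x$warnings), "warnings\n")
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}

#' Is a validation report clean?
#' @param report a `validation_report`
#' @return logical
#' @export
is_valid_report <- function(report) nrow(report$errors) == 0

.assert_valid <- function(ss, context = "structure set") {
  rep <- validate_structure_set(ss, check_simple = FALSE)
  if (!is_valid_report(rep)) {
    stop(sprintf("%s failed validation: %s (roi %s, z %s)", context,
                 rep$errors$message[1], rep$errors$roi[1],
                 format(rep$errors$z_mm[1])))
  }
  invisible(TRUE)
}

#' Write a structure set
#'
#' The JSON dialect is
#' `{"study_id": str, "rois": {name: [{"z": float, "xy": [[x, y], ...]}]}}`
#' with full float precision and sorted ROI keys, so repeated writes of the
#' same structure set are byte-identical.
#'
#' @param ss a valid [structure_set]
#' @param path output file path
#' @param format `"json"` (canonical)
#' @export
write_structure_set <- function(ss, path, format = c("json", "rtstruct")) {
  format <- match.arg(format)
  if (format == "rtstruct") {
    stop("unsupported format: DICOM RT-STRUCT writing is not provided; ",
         "use the JSON dialect")
  }
  if (length(ss$rois) == 0) stop("refusing to write: structure set has no ROIs")
  .assert_valid(ss)
  rois <- ss$rois[sort(names(ss$rois))]
  obj <- list(
    study_id = jsonlite::unbox(ss$study_id),
    rois = lapply(rois, function(cl) {
      lapply(cl, function(ct) {
        list(z = jsonlite::unbox(ct$z_mm), xy = ct$xy)
      })
    })
  )
  txt <- jsonlite::toJSON(obj, digits = NA, pretty = FALSE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Read a structure set
#'
#' @param path input file path
#' @param format `"json"` (canonical)
#' @return a [structure_set]
#' @export
read_structure_set <- function(path, format = c("json", "rtstruct")) {
  format <- match.arg(format)
  if (format == "rtstruct") {
    stop("unsupported format: DICOM RT-STRUCT reading is not provided; ",
         "use the JSON dialect")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("unparseable JSON in ", path, ": ",
                         conditionMessage(e))
                  })
  if (is.null(obj$study_id) || is.null(obj$rois)) {
    stop("malformed structure-set JSON: need fields study_id, rois")
  }
  rois <- lapply(obj$rois, function(cl) {
    lapply(cl, function(ct) {
      xy <- do.call(rbind, lapply(ct$xy, function(v) unlist(v)))
      planar_contour(ct$z, xy)
    })
  })
  ss <- structure_set(obj$study_id, rois)
  rep <- validate_structure_set(ss, check_simple = FALSE)
  if (!is_valid_report(rep)) {
    stop(sprintf("invalid structure set in %s: %s (roi %s, z %s)", path,
                 rep$errors$message[1], rep$errors$roi[1],
                 format(rep$errors$z_mm[1])))
  }
  ss
}
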