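#' Cubic B-spline displacement field constructor
#'
#' A smooth 3-D vector field parameterized by displacement coefficients on
#' a regular control lattice, interpolated with uniform cubic B-splines —
#' the standard free-form-deformation representation. Displacement is
#' forced to exactly zero outside an axis-aligned support box plus a smooth
#' taper band, so deformations stay local.
#'
#' @param origin_mm lattice corner (x, y, z), position of control point
#'   (1,1,1), in mm
#' @param grid_spacing_mm control-point spacing per axis (sx, sy, sz), mm
#' @param coefficients numeric array `c(nx, ny, nz, 3)` of displacement
#'   vectors on the lattice (mm); each dimension must be at least 4
#' @param support_box_mm list with `min` and `max` 3-vectors (mm); the field
#'   is zero outside this box plus the taper band
#' @param taper_mm width of the smooth roll-off band outside the box (mm)
#' @param focus optional list of local attenuation regions (see
#'   [focused_second_pass()])
#' @return an object of class `bspline_field`
#' @export
bspline_field <- function(origin_mm, grid_spacing_mm, coefficients,
                          support_box_mm, taper_mm = 0, focus = list()) {
  dm <- dim(coefficients)
  if (length(dm) != 4 || dm[4] != 3) {
    stop("coefficients must be an (nx, ny, nz, 3) array")
  }
  if (any(dm[1:3] < 4)) stop("lattice needs at least 4 control points per axis")
  if (any(grid_spacing_mm <= 0)) stop("grid spacing must be positive")
  if (!all(is.finite(coefficients))) stop("coefficients must be finite")
  if (taper_mm < 0) stop("taper width must be >= 0")
  structure(list(origin_mm = as.numeric(origin_mm),
                 grid_spacing_mm = as.numeric(grid_spacing_mm),
                 coefficients = coefficients,
                 support_box_mm = support_box_mm,
                 taper_mm = as.numeric(taper_mm),
                 focus = focus),
            class = "bspline_field")
}

# uniform cubic B-spline basis weights for local parameter t in [0,1);
# returns an n x 4 matrix for control offsets -1, 0, +1, +2
.bspline_basis <- function(t) {
  t2 <- t * t
  t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (4 - 6 * t2 + 3 * t3) / 6,
        (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
        t3 / 6)
}

# per-axis support weight: 1 inside [lo, hi], smoothstep roll-off over the
# taper band, 0 beyond it
.axis_weight <- function(x, lo, hi, taper) {
  if (taper <= 0) return(as.numeric(x >= lo & x <= hi))
  w <- rep(1, length(x))
  below <- x < lo
  above <- x > hi
  w[below] <- smoothstep(1 - (lo - x[below]) / taper)
  w[above] <- smoothstep(1 - (x[above] - hi) / taper)
  w
}

.support_weight <- function(points, box, taper) {
  .axis_weight(points[, 1], box$min[1], box$max[1], taper) *
    .axis_weight(points[, 2], box$min[2], box$max[2], taper) *
    .axis_weight(points[, 3], box$min[3], box$max[3], taper)
}

# multiplicative attenuation from focused second-pass regions
.focus_factor <- function(points, focus) {
  f <- rep(1, nrow(points))
  for (fc in focus) {
    w <- .support_weight(points, fc$box, fc$blend_mm)
    f <- f * (1 - fc$reduction * w)
  }
  f
}

#' Evaluate a displacement field at points
#'
#' Tensor-product cubic B-spline interpolation of the lattice coefficients,
#' multiplied by the support-box weight (and by any focused second-pass
#' attenuation). C2-smooth inside the support box, exactly zero outside the
#' box plus taper band, and fully deterministic.
#'
#' @param field a [bspline_field]
#' @param points n x 3 matrix of evaluation positions (mm)
#' @return n x 3 matrix of displacement vectors (mm)
#' @export
evaluate_field <- function(field, points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have three columns")
  n <- nrow(points)
  dm <- dim(field$coefficients)[1:3]
  disp <- matrix(0, n, 3)
  u <- sweep(sweep(points, 2, field$origin_mm), 2,
             field$grid_spacing_mm, "/")
  i0 <- floor(u)
  tloc <- u - i0
  # basis weights per axis
  Bx <- .bspline_basis(tloc[, 1])
  By <- .bspline_basis(tloc[, 2])
  Bz <- .bspline_basis(tloc[, 3])
  coef <- field$coefficients
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  cf <- matrix(coef, nx * ny * nz, 3)
  for (a in 1:4) {
    # support of the cubic basis: control indices i0-1 .. i0+2 (0-based)
    ia <- pmin(pmax(i0[, 1] + a - 2, 0), nx - 1) # clamp; taper zeroes outside
    for (b in 1:4) {
      ib <- pmin(pmax(i0[, 2] + b - 2, 0), ny - 1)
      wab <- Bx[, a] * By[, b]
      for (cc in 1:4) {
        ic <- pmin(pmax(i0[, 3] + cc - 2, 0), nz - 1)
        w <- wab * Bz[, cc]
        idx <- 1 + ia + nx * (ib + ny * ic)
        disp <- disp + w * cf[idx, , drop = FALSE]
      }
    }
  }
  w <- .support_weight(points, field$support_box_mm, field$taper_mm) *
    .focus_factor(points, field$focus)
  disp * w
}

#' Apply a displacement field to a structure set
#'
#' Every vertex is moved by its evaluated displacement. Because the data
#' model keeps contours planar, each displaced contour is re-projected onto
#' the plane `z = mean(displaced z)`; the largest projection distance is
#' recorded in the `"projection_max_mm"` attribute rather than silently
#' dropped (it is second-order small for smooth fields). Contours that
#' become non-simple are kept and counted in the `"nonsimple_count"`
#' attribute: the point-sampled distance statistic tolerates them.
#'
#' @param field a [bspline_field]
#' @param ss a valid [structure_set]
#' @param check_simple test displaced polygons for self-intersection
#'   (default FALSE; it is O(n^2) per contour)
#' @return the deformed [structure_set]
#' @export
apply_to_structure <- function(field, ss, check_simple = FALSE) {
  proj_max <- 0
  nonsimple <- 0L
  rois <- lapply(ss$rois, function(cl) {
    lapply(cl, function(ct) {
      P <- cbind(ct$xy, ct$z_mm)
      d <- evaluate_field(field, P)
      Q <- P + d
      zbar <- mean(Q[, 3])
      proj_max <<- max(proj_max, max(abs(Q[, 3] - zbar)))
      out <- planar_contour(zbar, Q[, 1:2, drop = FALSE])
      if (check_simple && !.cpp_polygon_is_simple(out$xy, 1e-9)) {
        nonsimple <<- nonsimple + 1L
      }
      out
    })
  })
  out <- structure_set(ss$study_id, rois)
  attr(out, "projection_max_mm") <- proj_max
  attr(out, "nonsimple_count") <- nonsimple
  out
}

#' Generate a seeded random smooth displacement field
#'
#' Coefficients are drawn i.i.d. Gaussian per component and then rescaled
#' globally so that the root-mean-square displacement *magnitude* over a
#' dense probe grid inside the support box equals `rms_amplitude_mm`
#' exactly (the rescale is linear, so it is exact by construction). The
#' same seed always reproduces the same field. This is the package's
#' stand-in for a deformable-registration residual: a smooth vector field
#' of known, controllable magnitude.
#'
#' @param rms_amplitude_mm target RMS displacement magnitude inside the
#'   support box (mm); 0 yields the zero field
#' @param correlation_length_mm control-lattice spacing (mm); larger values
#'   give smoother fields
#' @param support_box_mm list with `min` and `max` 3-vectors (mm)
#' @param seed integer seed
#' @param taper_mm roll-off band width (mm); defaults to the correlation
#'   length
#' @param probe_n probe points per axis for the RMS calibration
#' @return a [bspline_field]
#' @export
random_smooth_field <- function(rms_amplitude_mm, correlation_length_mm,
                                support_box_mm, seed,
                                taper_mm = correlation_length_mm,
                                probe_n = 8) {
  if (rms_amplitude_mm < 0) stop("rms_amplitude_mm must be >= 0")
  if (correlation_length_mm <= 0) stop("correlation_length_mm must be > 0")
  s <- correlation_length_mm
  lo <- support_box_mm$min - taper_mm
  hi <- support_box_mm$max + taper_mm
  # lattice covers box + taper with one extra control shell on each side
  dims <- pmax(ceiling((hi - lo) / s) + 6, 4)
  origin <- lo - 2 * s
  set.seed(seed)
  coef <- array(rnorm(prod(dims) * 3), dim = c(dims, 3))
  field <- bspline_field(origin, rep(s, 3), coef, support_box_mm, taper_mm)
  if (rms_amplitude_mm == 0) {
    field$coefficients[] <- 0
    return(field)
  }
  g <- lapply(1:3, function(k) {
    seq(support_box_mm$min[k], support_box_mm$max[k], length.out = probe_n)
  })
  probe <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  d <- evaluate_field(field, probe)
  rms <- sqrt(mean(rowSums(d^2)))
  field$coefficients <- field$coefficients * (rms_amplitude_mm / rms)
  field
}

#' Attenuate a field inside a focus region (second registration pass)
#'
#' Models a refinement registration pass restricted to one organ: the
#' displacement inside the focus ROI's bounding box is scaled by
#' `1 - reduction`, blending smoothly back to the unmodified field across a
#' band outside the box. The optimizer itself is never reproduced — only
#' its reported effect, a locally reduced residual error.
#'
#' @param field a [bspline_field]
#' @param focus_contours list of [planar_contour] (one ROI's stack), whose
#'   bounding box defines the focus region
#' @param reduction fraction in `[0, 1]` by which the local displacement is
#'   reduced (1 zeroes it)
#' @param blend_mm width of the smooth blend band (mm)
#' @param pad_mm padding added around the ROI bounding box (mm)
#' @return a new [bspline_field] with the focus region attached
#' @export
focused_second_pass <- function(field, focus_contours, reduction,
                                blend_mm = 5, pad_mm = 2) {
  if (length(focus_contours) == 0) stop("focus ROI is empty")
  if (reduction < 0 || reduction > 1) stop("reduction must be in [0, 1]")
  P <- do.call(rbind, lapply(focus_contours, function(ct) {
    cbind(ct$xy, ct$z_mm)
  }))
  box <- list(min = apply(P, 2, min) - pad_mm,
              max = apply(P, 2, max) + pad_mm)
  field$focus <- c(field$focus,
                   list(list(box = box, reduction = reduction,
                             blend_mm = blend_mm)))
  field
}

#' Serialize a displacement field to JSON
#' @param field a [bspline_field]
#' @param path output path
#' @export
write_field <- function(field, path) {
  obj <- list(origin_mm = field$origin_mm,
              grid_spacing_mm = field$grid_spacing_mm,
              dims = dim(field$coefficients),
              coefficients = as.numeric(field$coefficients),
              support_min_mm = field$support_box_mm$min,
              support_max_mm = field$support_box_mm$max,
              taper_mm = field$taper_mm,
              focus = lapply(field$focus, function(fc) {
                list(box_min = fc$box$min, box_max = fc$box$max,
                     reduction = fc$reduction, blend_mm = fc$blend_mm)
              }))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a displacement field from JSON
#' @param path input path
#' @return a [bspline_field]
#' @export
read_field <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  bspline_field(num(obj$origin_mm), num(obj$grid_spacing_mm),
                array(num(obj$coefficients), dim = num(obj$dims)),
                list(min = num(obj$support_min_mm),
                     max = num(obj$support_max_mm)),
                num(obj$taper_mm),
                focus = lapply(obj$focus, function(fc) {
                  list(box = list(min = num(fc$box_min), max = num(fc$box_max)),
                       reduction = num(fc$reduction),
                       blend_mm = num(fc$blend_mm))
                }))
}
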