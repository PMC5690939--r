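#' Phantom specification
#'
#' Analytic organ stand-ins used by the synthetic cohort generator:
#' ellipsoids (eyes, brainstem, bladder, prostate), tubes (cord, larynx,
#' optic nerves, rectum) and crescents (parotids).
#'
#' @param roi_name ROI label
#' @param shape `"ellipsoid"`, `"tube"` or `"crescent"`
#' @param size_mm named list of shape parameters, all in mm:
#'   ellipsoid `a, b, c` (semi-axes); tube `radius, length`;
#'   crescent `outer_radius, cutter_radius, cutter_offset, length`
#' @param center_mm 3-vector position (mm)
#' @param slice_thickness_mm z-plane spacing (mm), default 3 (the CT slice
#'   thickness of a typical planning scan)
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(roi_name, shape = c("ellipsoid", "tube", "crescent"),
                         size_mm, center_mm = c(0, 0, 0),
                         slice_thickness_mm = 3) {
  shape <- match.arg(shape)
  if (any(unlist(size_mm) <= 0)) stop("all shape lengths must be positive")
  if (slice_thickness_mm <= 0) stop("slice thickness must be positive")
  structure(list(roi_name = roi_name, shape = shape,
                 size_mm = size_mm, center_mm = as.numeric(center_mm),
                 slice_thickness_mm = slice_thickness_mm),
            class = "phantom_spec")
}

# in-plane polygon of one phantom slice; s in (0, 1] is the cross-section
# scale (ellipsoid pole narrowing), NULL if the slice misses the shape
.phantom_slice <- function(spec, z, max_arc = 0.5) {
  c0 <- spec$center_mm
  sz <- spec$size_mm
  switch(spec$shape,
    ellipsoid = {
      t <- (z - c0[3]) / sz$c
      if (abs(t) >= 1) return(NULL)
      s <- sqrt(1 - t^2)
      if (min(sz$a, sz$b) * s < 2) return(NULL) # avoid degenerate pole slivers
      ellipse_polygon(c0[1:2], sz$a * s, sz$b * s, max_arc)
    },
    tube = {
      if (abs(z - c0[3]) > sz$length / 2) return(NULL)
      circle_polygon(c0[1:2], sz$radius, max_arc)
    },
    crescent = {
      if (abs(z - c0[3]) > sz$length / 2) return(NULL)
      crescent_polygon(c0[1:2], sz$outer_radius, sz$cutter_radius,
                       sz$cutter_offset, max_arc)
    })
}

# crescent cross-section: disk of radius r1 minus an overlapping disk of
# radius r2 centered at (cx + d, cy); boundary is the outer arc outside the
# cutter followed by the cutter arc inside the outer circle (CW on the
# cutter), giving a simple CCW polygon
crescent_polygon <- function(center, r1, r2, d, max_arc = 0.5) {
  if (d <= abs(r1 - r2) || d >= r1 + r2) {
    stop("crescent circles must properly intersect: need |r1-r2| < d < r1+r2")
  }
  x0 <- (d^2 + r1^2 - r2^2) / (2 * d)
  y0 <- sqrt(max(r1^2 - x0^2, 0))
  th1 <- atan2(y0, x0)                 # outer-circle angle of upper crossing
  ph1 <- atan2(y0, x0 - d)             # cutter-circle angle of upper crossing
  n1 <- max(8, ceiling(r1 * (2 * pi - 2 * th1) / max_arc))
  th <- seq(th1, 2 * pi - th1, length.out = n1)
  outer <- cbind(center[1] + r1 * cos(th), center[2] + r1 * sin(th))
  n2 <- max(8, ceiling(r2 * (2 * pi - 2 * ph1) / max_arc))
  ph <- seq(-ph1, -(2 * pi - ph1), length.out = n2) # clockwise through pi
  cutter <- cbind(center[1] + d + r2 * cos(ph), center[2] + r2 * sin(ph))
  # crossings appear at the end of one arc and start of the next: drop dups
  xy <- rbind(outer, cutter[-1, , drop = FALSE])
  xy[-nrow(xy), , drop = FALSE]
}

#' Generate the noise-free contour stack of a phantom
#'
#' Slices the analytic shape into planar polygons on a z-grid aligned to
#' the phantom centre with the specified slice thickness; vertex arc
#' spacing is at most `max_arc` (default 0.5 mm).
#'
#' @param spec a [phantom_spec]
#' @param max_arc maximum vertex arc spacing (mm)
#' @return list of [planar_contour] (one ROI's stack)
#' @export
generate_phantom_truth <- function(spec, max_arc = 0.5) {
  dz <- spec$slice_thickness_mm
  cz <- spec$center_mm[3]
  half <- switch(spec$shape,
                 ellipsoid = spec$size_mm$c,
                 tube = spec$size_mm$length / 2,
                 crescent = spec$size_mm$length / 2)
  ks <- seq(-ceiling(half / dz), ceiling(half / dz))
  contours <- list()
  for (k in ks) {
    z <- cz + k * dz
    xy <- .phantom_slice(spec, z, max_arc)
    if (!is.null(xy)) {
      contours[[length(contours) + 1L]] <- planar_contour(z, polygon_ccw(xy))
    }
  }
  if (length(contours) < 3) {
    stop("phantom '", spec$roi_name, "' intersects fewer than 3 z-planes; ",
         "enlarge the shape or reduce slice thickness")
  }
  contours
}

# assemble a full structure set from phantom specs
.phantom_structure_set <- function(specs, study_id, max_arc = 0.5) {
  rois <- lapply(specs, generate_phantom_truth, max_arc = max_arc)
  names(rois) <- vapply(specs, function(s) s$roi_name, character(1))
  structure_set(study_id, rois)
}

#' Noise specification for the synthetic cohort
#'
#' Parameterizes the three uncertainty sources whose magnitudes the
#' analysis measures: a persistent smooth bias field per observer
#' (interobserver), smooth per-session delineation noise (intraobserver),
#' and a residual smooth deformation left by contour propagation.
#'
#' @param sigma_inter_mm pointwise SD of each observer's persistent bias
#'   field (mm)
#' @param sigma_intra_mm pointwise SD of per-session delineation noise (mm)
#' @param sigma_def_mm RMS magnitude of the residual deformation field (mm)
#' @param correlation_length_mm smoothness of all boundary noise fields (mm)
#' @param second_pass_reduction fractional local error reduction of the
#'   focused second registration pass, in `[0, 1]`
#' @param seed master integer seed; every random stream in the cohort is
#'   derived from it via [seed_stream()]
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(sigma_inter_mm, sigma_intra_mm, sigma_def_mm,
                       correlation_length_mm = 20,
                       second_pass_reduction = 0.15, seed = 1) {
  if (any(c(sigma_inter_mm, sigma_intra_mm, sigma_def_mm) < 0)) {
    stop("noise SDs must be >= 0")
  }
  if (correlation_length_mm <= 0) stop("correlation length must be > 0")
  if (second_pass_reduction < 0 || second_pass_reduction > 1) {
    stop("second_pass_reduction must be in [0, 1]")
  }
  structure(list(sigma_inter_mm = sigma_inter_mm,
                 sigma_intra_mm = sigma_intra_mm,
                 sigma_def_mm = sigma_def_mm,
                 correlation_length_mm = correlation_length_mm,
                 second_pass_reduction = second_pass_reduction,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate one delineation session
#'
#' Displaces every boundary vertex along its local in-plane outward normal
#' by the observer's persistent bias field plus fresh smooth session noise,
#' emulating a human contouring act with spatially coherent error. In-plane
#' displacement keeps contours exactly planar.
#'
#' @param truth a valid [structure_set] (the noise-free phantom)
#' @param bias_field a `smooth_field` (the observer's persistent bias), or
#'   NULL for none
#' @param sigma_session_mm pointwise SD of the session noise (mm)
#' @param correlation_length_mm session-noise smoothness (mm)
#' @param seed integer seed for the session noise
#' @param max_shrink largest allowed inward displacement as a fraction of a
#'   vertex's distance to the slice centroid (default 0.6); protects thin
#'   structures (e.g., optic-nerve calibre tubes) from collapsing under
#'   noise whose SD rivals their radius, emulating the fact that human
#'   observers never contour an organ away entirely. Only the extreme
#'   inward tail of the noise distribution is affected.
#' @return a [structure_set]
#' @export
simulate_delineation <- function(truth, bias_field, sigma_session_mm,
                                 correlation_length_mm = 20, seed = 1,
                                 max_shrink = 0.6) {
  session <- if (sigma_session_mm > 0) {
    smooth_scalar_field(sigma_session_mm, correlation_length_mm, seed)
  } else {
    zero_scalar_field()
  }
  if (is.null(bias_field)) bias_field <- zero_scalar_field()
  rois <- lapply(names(truth$rois), function(nm) {
    lapply(truth$rois[[nm]], function(ct) {
      xy <- ct$xy
      P <- cbind(xy, ct$z_mm)
      disp <- bias_field(P) + session(P)
      ctr <- colMeans(xy)
      rad <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
      disp <- pmax(disp, -max_shrink * rad)
      vn <- polygon_vertex_normals(xy)
      out <- xy + vn * disp
      if (abs(polygon_area_signed(out)) < 1) {
        stop(sprintf(
          "delineation noise collapsed roi '%s' at z = %.2f mm (area < 1 mm^2)",
          nm, ct$z_mm))
      }
      planar_contour(ct$z_mm, out)
    })
  })
  names(rois) <- names(truth$rois)
  structure_set(truth$study_id, rois)
}

.structure_bbox <- function(ss, pad = 0) {
  P <- do.call(rbind, lapply(ss$rois, function(cl) {
    do.call(rbind, lapply(cl, function(ct) cbind(ct$xy, ct$z_mm)))
  }))
  list(min = apply(P, 2, min) - pad, max = apply(P, 2, max) + pad)
}

.subset_structure <- function(ss, rois) {
  structure_set(ss$study_id, ss$rois[intersect(names(ss$rois), rois)])
}

#' Simulate a seeded cohort realizing the two-CT contour schema
#'
#' For each patient, generates a CT1 phantom truth (with per-patient
#' position and size jitter so persistent observer bias fields are sampled
#' at different anatomy across patients), warps it by a random smooth
#' anatomical-change field into the CT2 truth, and produces the eight
#' contour roles:
#' \describe{
#'   \item{ROI11, ROI21}{observer 1 / 2 delineations on CT1}
#'   \item{ROI12, ROI22}{observer delineations on CT2 (the forward-warped
#'     CT1-frame delineations, so the anatomical warp has an exact inverse
#'     by construction)}
#'   \item{ROI1D, ROI2D}{CT2 contours propagated back to CT1: the exact
#'     inverse composed with a fresh residual field of RMS `sigma_def_mm`
#'     — the injected, known registration error}
#'   \item{ROI1A, ROI2A}{recontouring sessions on CT1 for the recontour
#'     subset}
#' }
#' Also stored per patient: `ROI1P`/`ROI2P`, the residual-free propagated
#' contours (ground truth for parameter-recovery tests), and, when a
#' second-pass plan is given, `ROI1D2`/`ROI2D2` with the residual locally
#' attenuated by `second_pass_reduction` inside the focus ROI.
#'
#' @param phantoms list of [phantom_spec]
#' @param noise a [noise_spec]
#' @param n_patients number of patients
#' @param n_recontour size of the recontour subset (first `n_recontour`
#'   patients), default 5
#' @param second_pass named list `roi -> number of patients` receiving a
#'   focused second registration pass for that ROI (default none)
#' @param missing_rois named list `roi -> patient indices` for which the
#'   ROI is absent from all contour roles (emulates, e.g., surgically
#'   removed organs); default none
#' @param jitter_mm half-width of the uniform per-patient centre jitter
#' @param size_jitter fractional half-width of per-patient size jitter
#' @param anatomy_rms_mm RMS magnitude of the CT1-to-CT2 anatomical-change
#'   field (mm)
#' @param anatomy_corr_mm correlation length of the anatomical field (mm)
#' @param max_arc phantom vertex arc spacing (mm)
#' @return an object of class `cohort_bundle`
#' @export
simulate_cohort <- function(phantoms, noise, n_patients,
                            n_recontour = 5, second_pass = list(),
                            missing_rois = list(),
                            jitter_mm = 25, size_jitter = 0.1,
                            anatomy_rms_mm = 5, anatomy_corr_mm = 40,
                            max_arc = 0.5) {
  stopifnot(inherits(noise, "noise_spec"))
  if (n_recontour > n_patients) stop("n_recontour must be <= n_patients")
  master <- noise$seed
  ell <- noise$correlation_length_mm

  bias <- lapply(1:2, function(i) {
    if (noise$sigma_inter_mm > 0) {
      smooth_scalar_field(noise$sigma_inter_mm, ell,
                          seed_stream(master, "bias", i))
    } else {
      zero_scalar_field()
    }
  })

  recontour_ids <- seq_len(n_recontour)
  second_pass_ids <- lapply(second_pass, function(k) seq_len(min(k, n_patients)))

  patients <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    set.seed(seed_stream(master, "geom", p))
    specs <- lapply(phantoms, function(sp) {
      sp$center_mm <- sp$center_mm + runif(3, -jitter_mm, jitter_mm)
      sp$size_mm <- lapply(sp$size_mm, function(v) {
        v * (1 + runif(1, -size_jitter, size_jitter))
      })
      sp
    })
    drop <- names(missing_rois)[vapply(missing_rois, function(ids) {
      p %in% ids
    }, logical(1))]
    truth_full <- .phantom_structure_set(specs, sprintf("P%02d_CT1", p),
                                         max_arc)
    truth1 <- if (length(drop)) {
      structure_set(truth_full$study_id,
                    truth_full$rois[setdiff(names(truth_full$rois), drop)])
    } else {
      truth_full
    }

    box <- .structure_bbox(truth_full, pad = 15)
    anat <- random_smooth_field(anatomy_rms_mm, anatomy_corr_mm, box,
                                seed_stream(master, "anat", p))
    resid <- random_smooth_field(noise$sigma_def_mm, ell, box,
                                 seed_stream(master, "resid", p))

    roles <- list()
    pre <- list()
    for (i in 1:2) {
      roles[[paste0("ROI", i, "1")]] <- simulate_delineation(
        truth1, bias[[i]], noise$sigma_intra_mm, ell,
        seed_stream(master, "sess1", p, i))
      pre[[i]] <- simulate_delineation(
        truth1, bias[[i]], noise$sigma_intra_mm, ell,
        seed_stream(master, "sess2", p, i))
      roles[[paste0("ROI", i, "2")]] <- apply_to_structure(anat, pre[[i]])
      roles[[paste0("ROI", i, "D")]] <- apply_to_structure(resid, pre[[i]])
      roles[[paste0("ROI", i, "P")]] <- pre[[i]]
      if (p %in% recontour_ids) {
        roles[[paste0("ROI", i, "A")]] <- simulate_delineation(
          truth1, bias[[i]], noise$sigma_intra_mm, ell,
          seed_stream(master, "sess3", p, i))
      }
    }
    focus_here <- names(second_pass_ids)[vapply(second_pass_ids, function(ids) {
      p %in% ids
    }, logical(1))]
    focus_here <- intersect(focus_here, names(truth1$rois))
    if (length(focus_here)) {
      r2 <- resid
      for (fr in focus_here) {
        r2 <- focused_second_pass(r2, truth1$rois[[fr]],
                                  noise$second_pass_reduction)
      }
      for (i in 1:2) {
        roles[[paste0("ROI", i, "D2")]] <- apply_to_structure(
          r2, .subset_structure(pre[[i]], focus_here))
      }
    }
    patients[[p]] <- list(id = sprintf("P%02d", p),
                          truth_ct1 = truth1,
                          truth_ct2 = apply_to_structure(anat, truth1),
                          roles = roles)
  }

  structure(list(patients = patients,
                 phantoms = phantoms,
                 noise = noise,
                 recontour_ids = recontour_ids,
                 second_pass_ids = second_pass_ids,
                 missing_rois = missing_rois),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", length(x$patients), "patients,",
      length(x$phantoms), "ROIs; recontour subset",
      length(x$recontour_ids), "\n")
  invisible(x)
}

#' Head-and-neck cohort preset
#'
#' Ten organ phantoms matching the structure of the head-and-neck study
#' arm: 30 patients, two observers, recontour subset of 5.
#'
#' @return list with elements `phantoms`, `n_patients`, `n_recontour`, and
#'   default `noise`
#' @export
preset_head_neck <- function() {
  ph <- list(
    phantom_spec("brainstem", "ellipsoid", list(a = 11, b = 13, c = 22),
                 c(0, -35, 60)),
    phantom_spec("cord", "tube", list(radius = 6, length = 110),
                 c(0, -50, -40)),
    phantom_spec("anterior_oral_cavity", "ellipsoid",
                 list(a = 24, b = 20, c = 14), c(0, 25, 25)),
    phantom_spec("larynx", "tube", list(radius = 16, length = 45),
                 c(0, 10, -15)),
    phantom_spec("parotid_l", "crescent",
                 list(outer_radius = 16, cutter_radius = 13,
                      cutter_offset = 14, length = 40), c(48, -5, 20)),
    phantom_spec("parotid_r", "crescent",
                 list(outer_radius = 16, cutter_radius = 13,
                      cutter_offset = 14, length = 40), c(-48, -5, 20)),
    phantom_spec("optic_nerve_l", "tube", list(radius = 2.5, length = 28),
                 c(14, 5, 68)),
    phantom_spec("optic_nerve_r", "tube", list(radius = 2.5, length = 28),
                 c(-14, 5, 68)),
    phantom_spec("eye_l", "ellipsoid", list(a = 12, b = 12, c = 12),
                 c(32, 25, 70)),
    phantom_spec("eye_r", "ellipsoid", list(a = 12, b = 12, c = 12),
                 c(-32, 25, 70))
  )
  list(phantoms = ph, n_patients = 30, n_recontour = 5,
       noise = noise_spec(sigma_inter_mm = 1.8, sigma_intra_mm = 1.0,
                          sigma_def_mm = 2.2))
}

#' Male-pelvis cohort preset
#'
#' Three organ phantoms matching the structure of the pelvic study arm:
#' 20 patients, recontour subset of 5, focused second registration passes
#' for bladder (7 patients) and rectum (4 patients).
#'
#' @return list with elements `phantoms`, `n_patients`, `n_recontour`,
#'   `second_pass`, and default `noise`
#' @export
preset_pelvis <- function() {
  ph <- list(
    phantom_spec("prostate", "ellipsoid", list(a = 23, b = 20, c = 19),
                 c(0, 10, 0)),
    phantom_spec("bladder", "ellipsoid", list(a = 35, b = 32, c = 30),
                 c(0, 45, 35)),
    phantom_spec("rectum", "tube", list(radius = 13, length = 58),
                 c(0, -30, 0))
  )
  list(phantoms = ph, n_patients = 20, n_recontour = 5,
       second_pass = list(bladder = 7, rectum = 4),
       noise = noise_spec(sigma_inter_mm = 2.0, sigma_intra_mm = 1.5,
                          sigma_def_mm = 2.8))
}

#' Write a cohort bundle to a directory tree
#'
#' One JSON structure set per patient per contour role, plus a YAML
#' manifest recording the phantom and noise specifications, the seeds, and
#' the subset bookkeeping.
#'
#' @param bundle a `cohort_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pat in bundle$patients) {
    pdir <- file.path(dir, pat$id)
    dir.create(pdir, showWarnings = FALSE)
    for (role in names(pat$roles)) {
      if (length(pat$roles[[role]]$rois) == 0) next # fully missing ROI set
      write_structure_set(pat$roles[[role]],
                          file.path(pdir, paste0(role, ".json")))
    }
  }
  manifest <- list(
    n_patients = length(bundle$patients),
    recontour_ids = bundle$recontour_ids,
    second_pass_ids = bundle$second_pass_ids,
    noise = unclass(bundle$noise),
    phantoms = lapply(bundle$phantoms, function(sp) {
      list(roi = sp$roi_name, shape = sp$shape, size_mm = sp$size_mm,
           center_mm = sp$center_mm,
           slice_thickness_mm = sp$slice_thickness_mm)
    })
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
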