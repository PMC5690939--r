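test_that("zero and constant coefficient fields behave analytically", {
  box <- default_box(50)
  coef0 <- array(0, c(6, 6, 6, 3))
  f0 <- bspline_field(c(-60, -60, -60), c(25, 25, 25), coef0, box)
  pts <- matrix(runif(60, -40, 40), ncol = 3)
  expect_true(all(evaluate_field(f0, pts) == 0))

  coef1 <- coef0
  coef1[, , , 1] <- 1 # partition of unity: basis sums to 1 in the interior
  f1 <- bspline_field(c(-60, -60, -60), c(25, 25, 25), coef1, box)
  d <- evaluate_field(f1, pts)
  expect_equal(d[, 1], rep(1, nrow(pts)), tolerance = 1e-12)
  expect_equal(max(abs(d[, 2:3])), 0)
})

test_that("lattice interpolation matches a naive 64-term basis sum", {
  naive_basis <- function(t, k) {
    # cubic B-spline blending functions, offsets k = -1..2
    switch(as.character(k),
           "-1" = (1 - t)^3 / 6,
           "0" = (3 * t^3 - 6 * t^2 + 4) / 6,
           "1" = (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
           "2" = t^3 / 6)
  }
  box <- default_box(40)
  set.seed(13)
  dims <- c(12, 13, 14)
  coef <- array(rnorm(prod(dims) * 3), c(dims, 3))
  origin <- c(-120, -120, -120)
  sp <- c(20, 20, 18)
  f <- bspline_field(origin, sp, coef, box, taper_mm = 0)
  pts <- matrix(runif(300, -35, 35), ncol = 3)
  got <- evaluate_field(f, pts)
  for (r in sample(nrow(pts), 20)) {
    u <- (pts[r, ] - origin) / sp
    i0 <- floor(u); t <- u - i0
    want <- c(0, 0, 0)
    for (a in -1:2) for (b in -1:2) for (cc in -1:2) {
      w <- naive_basis(t[1], a) * naive_basis(t[2], b) * naive_basis(t[3], cc)
      want <- want + w * coef[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1, ]
    }
    expect_equal(got[r, ], want, tolerance = 1e-12)
  }
})

test_that("displacement vanishes outside support and scales linearly", {
  box <- default_box(30)
  f <- random_smooth_field(2, 15, box, seed = 31)
  far <- matrix(c(100, 0, 0, 0, -90, 3, 70, 70, 70), ncol = 3, byrow = TRUE)
  expect_true(all(evaluate_field(f, far) == 0))

  pts <- matrix(runif(90, -25, 25), ncol = 3)
  d1 <- evaluate_field(f, pts)
  f3 <- f
  f3$coefficients <- f$coefficients * 3
  expect_equal(evaluate_field(f3, pts), 3 * d1, tolerance = 1e-12)
})

test_that("random fields hit their target RMS and are seed-deterministic", {
  box <- default_box(40)
  f <- random_smooth_field(2.0, 20, box, seed = 7)
  g <- random_smooth_field(2.0, 20, box, seed = 7)
  expect_identical(f$coefficients, g$coefficients)
  grid <- as.matrix(expand.grid(seq(-40, 40, length.out = 8),
                                seq(-40, 40, length.out = 8),
                                seq(-40, 40, length.out = 8)))
  rms <- sqrt(mean(rowSums(evaluate_field(f, grid)^2)))
  expect_gte(rms, 1.98)
  expect_lte(rms, 2.02)

  z <- random_smooth_field(0, 20, box, seed = 7)
  expect_true(all(z$coefficients == 0))
})

test_that("applying fields to structures preserves structure semantics", {
  ss <- tube_truth_ss(radius = 10, length = 30)
  box <- default_box(60)
  zero <- random_smooth_field(0, 20, box, seed = 1)
  same <- apply_to_structure(zero, ss)
  expect_equal(same$rois$tube[[1]]$xy, ss$rois$tube[[1]]$xy)
  expect_equal(vapply(same$rois$tube, `[[`, numeric(1), "z_mm"),
               vapply(ss$rois$tube, `[[`, numeric(1), "z_mm"))

  # pure translation by (0, 0, 3): constant coefficients, wide support
  coef <- array(0, c(8, 8, 8, 3))
  coef[, , , 3] <- 3
  tr <- bspline_field(c(-120, -120, -120), c(35, 35, 35), coef,
                      default_box(80))
  up <- apply_to_structure(tr, ss)
  expect_equal(vapply(up$rois$tube, `[[`, numeric(1), "z_mm"),
               vapply(ss$rois$tube, `[[`, numeric(1), "z_mm") + 3,
               tolerance = 1e-9)
  expect_equal(up$rois$tube[[1]]$xy, ss$rois$tube[[1]]$xy, tolerance = 1e-9)
  expect_lt(attr(up, "projection_max_mm"), 1e-9)
})

test_that("a known radial displacement is recovered by the distance statistic", {
  # sphere phantom pushed radially outward by a constant amount: the mean
  # surface distance to the original must equal that amount
  spec <- phantom_spec("s", "ellipsoid", list(a = 25, b = 25, c = 25))
  truth <- structure_set("s", list(s = generate_phantom_truth(spec)))
  pushed <- structure_set("s", list(s = lapply(truth$rois$s, function(ct) {
    P <- cbind(ct$xy, ct$z_mm)
    r <- sqrt(rowSums(P^2))
    Q <- P * (1 + 2 / r)  # radial push of 2 mm
    planar_contour(mean(Q[, 3]), Q[, 1:2])
  })))
  d <- directed_mean_surface_distance(sample_surface(truth, "s", 0.5),
                                      sample_surface(pushed, "s", 0.5))
  expect_equal(d$mean_mm, 2.0, tolerance = 0.03)
})

test_that("focused second pass attenuates only the focus region", {
  box <- default_box(60)
  f <- random_smooth_field(2.0, 20, box, seed = 17)
  focus <- generate_phantom_truth(
    phantom_spec("f", "tube", list(radius = 10, length = 20)))

  unchanged <- focused_second_pass(f, focus, reduction = 0)
  pts <- matrix(runif(120, -8, 8), ncol = 3)
  expect_equal(evaluate_field(unchanged, pts), evaluate_field(f, pts))

  zeroed <- focused_second_pass(f, focus, reduction = 1)
  expect_true(all(abs(evaluate_field(zeroed, pts)) < 1e-12))

  part <- focused_second_pass(f, focus, reduction = 0.2)
  d_in <- evaluate_field(part, pts)
  expect_equal(sqrt(mean(rowSums(d_in^2))) /
                 sqrt(mean(rowSums(evaluate_field(f, pts)^2))),
               0.8, tolerance = 0.02)
  # far from the focus box (beyond blend band) the field is untouched
  far <- matrix(runif(60, 35, 55), ncol = 3)
  expect_equal(evaluate_field(part, far), evaluate_field(f, far))
  expect_error(focused_second_pass(f, list(), 0.5), "empty")
})

test_that("field JSON serialization round-trips", {
  box <- default_box(30)
  f <- random_smooth_field(1.5, 15, box, seed = 5)
  f <- focused_second_pass(f, generate_phantom_truth(
    phantom_spec("f", "tube", list(radius = 6, length = 15))), 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_field(f, path)
  g <- read_field(path)
  pts <- matrix(runif(60, -25, 25), ncol = 3)
  expect_equal(evaluate_field(g, pts), evaluate_field(f, pts),
               tolerance = 1e-12)
})
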