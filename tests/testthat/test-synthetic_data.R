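test_that("phantom slicing matches analytic cross-sections", {
  sph <- generate_phantom_truth(
    phantom_spec("s", "ellipsoid", list(a = 10, b = 10, c = 10)))
  for (ct in sph) {
    r_expect <- 10 * sqrt(1 - (ct$z_mm / 10)^2)
    r_got <- sqrt(rowSums(ct$xy^2))
    expect_lt(max(abs(r_got - r_expect)), 1e-6)
  }

  tube <- generate_phantom_truth(
    phantom_spec("t", "tube", list(radius = 5, length = 60)))
  first <- tube[[1]]$xy
  for (ct in tube) expect_equal(ct$xy, first)
  expect_equal(length(tube), 21) # 60 mm / 3 mm + end planes

  cres <- generate_phantom_truth(
    phantom_spec("c", "crescent",
                 list(outer_radius = 16, cutter_radius = 13,
                      cutter_offset = 14, length = 24)))
  ss <- structure_set("c", list(c = cres))
  expect_true(is_valid_report(validate_structure_set(ss)))
  # crescent area below the full disk but positive
  areas <- vapply(cres, function(ct) {
    xy <- ct$xy
    nxt <- xy[c(2:nrow(xy), 1), ]
    abs(sum(xy[, 1] * nxt[, 2] - nxt[, 1] * xy[, 2]) / 2)
  }, numeric(1))
  expect_true(all(areas > 10 & areas < pi * 16^2))

  expect_error(generate_phantom_truth(
    phantom_spec("tiny", "tube", list(radius = 4, length = 2))),
    "fewer than 3")
})

test_that("delineation is exact at zero noise and seed-deterministic", {
  truth <- tube_truth_ss(radius = 20, length = 30)
  clean <- simulate_delineation(truth, NULL, 0, seed = 1)
  expect_equal(clean$rois$tube[[1]]$xy, truth$rois$tube[[1]]$xy)

  a <- simulate_delineation(truth, NULL, 1.2, seed = 7)
  b <- simulate_delineation(truth, NULL, 1.2, seed = 7)
  expect_identical(a$rois, b$rois)
  c <- simulate_delineation(truth, NULL, 1.2, seed = 8)
  expect_false(identical(a$rois, c$rois))
})

test_that("delineation noise obeys the half-normal flat-limit calibration", {
  truth <- tube_truth_ss(radius = 30, length = 60)
  # short correlation length so the boundary averages many patches
  noisy <- simulate_delineation(truth, NULL, 1.0,
                                correlation_length_mm = 8, seed = 11)
  d <- directed_mean_surface_distance(sample_surface(truth, "tube"),
                                      sample_surface(noisy, "tube"))
  expect_gt(d$n_primary, 1000)
  expect_equal(d$mean_mm, sqrt(2 / pi), tolerance = 0.10)
})

test_that("noise sources map onto their measured quantities", {
  # only interobserver bias: VIO departs, VIA and VT stay at zero
  inter_only <- tube_cohort(6, noise_spec(2.0, 0, 0, seed = 21),
                            n_recontour = 3)
  s1 <- summarize_records(compute_all_records(inter_only))
  get <- function(s, q) s$mean_mm[s$quantity == q]
  expect_gt(get(s1, "VIO"), 1.0)
  expect_lt(get(s1, "VIA"), 0.05)
  expect_lt(get(s1, "VT"), 0.05)

  # only deformation residual: VT departs, VIO and VIA stay at zero
  def_only <- tube_cohort(6, noise_spec(0, 0, 2.0, seed = 22),
                          n_recontour = 3)
  s2 <- summarize_records(compute_all_records(def_only))
  expect_gt(get(s2, "VT"), 0.4)
  expect_lt(get(s2, "VIO"), 0.05)
  expect_lt(get(s2, "VIA"), 0.05)

  # only session noise: VIA departs (and, structurally, VT and VIO carry
  # session noise too -- total variation contains intraobserver variation)
  intra_only <- tube_cohort(6, noise_spec(0, 1.0, 0, seed = 23),
                            n_recontour = 3)
  s3 <- summarize_records(compute_all_records(intra_only))
  expect_gt(get(s3, "VIA"), 0.4)
  expect_equal(get(s3, "VT"), get(s3, "VIA"), tolerance = 0.25)
})

test_that("pure interobserver bias reproduces the difference-field mean", {
  # two independent bias fields of SD sigma differ by a field of SD
  # sigma*sqrt(2); the measured mean distance is its half-normal mean
  bundle <- tube_cohort(20, noise_spec(2.0, 0, 0, seed = 31),
                        n_recontour = 5)
  vio <- compute_vio(bundle, "tube")
  expect_equal(mean(vio$value_mm), 2.0 * sqrt(2) * sqrt(2 / pi),
               tolerance = 0.15)
})

test_that("cohorts are deterministic and realize the contour schema", {
  ns <- noise_spec(1.0, 0.8, 1.5, seed = 41)
  b1 <- tube_cohort(3, ns, n_recontour = 2)
  b2 <- tube_cohort(3, ns, n_recontour = 2)
  expect_equal(b1, b2)

  pat <- b1$patients[[1]]
  expect_setequal(
    names(pat$roles),
    c("ROI11", "ROI21", "ROI12", "ROI22", "ROI1D", "ROI2D",
      "ROI1P", "ROI2P", "ROI1A", "ROI2A"))
  # recontour sessions only exist for the subset
  expect_null(b1$patients[[3]]$roles$ROI1A)

  # zero noise: observers and propagation reproduce the truth exactly
  b0 <- tube_cohort(2, noise_spec(0, 0, 0, seed = 42), n_recontour = 1)
  p0 <- b0$patients[[1]]
  expect_equal(p0$roles$ROI11$rois, p0$roles$ROI21$rois)
  expect_equal(p0$roles$ROI11$rois, p0$roles$ROI1A$rois)
  expect_equal(p0$roles$ROI11$rois, p0$truth_ct1$rois)
  expect_equal(p0$roles$ROI1D$rois, p0$roles$ROI11$rois)
})

test_that("cohort JSON round-trip preserves every contour", {
  ns <- noise_spec(1.0, 0.5, 1.0, seed = 51)
  b <- tube_cohort(2, ns, n_recontour = 1)
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$patients), 2)
  expect_setequal(names(back$patients[[1]]$roles),
                  names(b$patients[[1]]$roles))
  a <- b$patients[[1]]$roles$ROI1D$rois$tube[[3]]
  z <- back$patients[[1]]$roles$ROI1D$rois$tube[[3]]
  expect_equal(z$z_mm, a$z_mm, tolerance = 1e-9)
  expect_equal(z$xy, a$xy, tolerance = 1e-9)
  expect_equal(back$noise$sigma_def_mm, 1.0)
})
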