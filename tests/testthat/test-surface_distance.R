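test_that("perimeter sampling conserves arc length and vertex planes", {
  sq <- unit_square_ss(z = 2.5)
  cl <- sample_surface(sq, "square", 1.0)
  expect_equal(nrow(cl$points), 4)
  expect_true(all(cl$points[, 3] == 2.5))
  # total points x step ~ perimeter
  expect_equal(nrow(cl$points) * 1.0, 4)

  circ <- circle_ss(radius = 10, n = 100)
  ncirc <- nrow(sample_surface(circ, "circ", 0.5)$points)
  expect_lte(abs(ncirc - ceiling(2 * pi * 10 / 0.5)), 1)

  two_plane <- structure_set("tp", list(r = list(
    planar_contour(-3, rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))),
    planar_contour(9, rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))))))
  cl2 <- sample_surface(two_plane, "r", 0.5)
  expect_setequal(unique(cl2$points[, 3]), c(-3, 9))
  expect_error(sample_surface(two_plane, "missing", 0.5), "not present")
})

test_that("directed distance matches analytic limits", {
  a <- sphere_cloud(20, 20000, seed = 3)
  b <- sphere_cloud(22, 20000, seed = 4)
  res <- directed_mean_surface_distance(a, b)
  expect_equal(res$mean_mm, 2.0, tolerance = 0.05 / 2.0)
  expect_equal(directed_mean_surface_distance(a, a)$mean_mm, 0)
  expect_equal(directed_mean_surface_distance(a, a)$max_mm, 0)
})

test_that("accelerated search equals the all-pairs oracle exactly", {
  for (seed in 1:5) {
    p <- random_cloud(50, seed)
    s <- random_cloud(80, seed + 100)
    fast <- directed_mean_surface_distance(p, s)
    slow <- brute_force_nearest(p, s)
    expect_equal(fast$mean_mm, slow$mean_mm, tolerance = 1e-12)
    expect_equal(fast$max_mm, slow$max_mm, tolerance = 1e-12)
    expect_identical(fast$n_primary, 50L)
  }
})

test_that("brute-force reference handles degenerate cases and guards size", {
  one <- surface_cloud(matrix(c(0, 0, 0), 1))
  other <- surface_cloud(matrix(c(3, 4, 0), 1))
  res <- brute_force_nearest(one, other)
  expect_equal(res$mean_mm, 5)
  expect_equal(res$max_mm, 5)

  tri <- surface_cloud(cbind(0:2, 0, 0))
  tri_up <- surface_cloud(cbind(0:2, 0, 1))
  expect_equal(brute_force_nearest(tri, tri_up)$mean_mm, 1)

  big <- surface_cloud(matrix(0, 10001, 3) + runif(30003))
  expect_error(brute_force_nearest(big, one), "guard")
})

test_that("symmetric distance is the mean of the two directed means", {
  # a point against a segment is maximally asymmetric
  pt <- surface_cloud(matrix(c(0, 0, 0), 1))
  seg <- surface_cloud(cbind(seq(0, 10, 0.1), 0, 0))
  ab <- directed_mean_surface_distance(pt, seg)$mean_mm
  ba <- directed_mean_surface_distance(seg, pt)$mean_mm
  expect_equal(ab, 0)
  expect_gt(ba, 4)
  sym <- symmetric_mean_surface_distance(pt, seg)
  expect_equal(sym$mean_mm, (ab + ba) / 2)
  expect_equal(sym$direction, "symmetric")

  p <- random_cloud(60, 7); s <- random_cloud(90, 8)
  expect_equal(symmetric_mean_surface_distance(p, s)$mean_mm,
               (brute_force_nearest(p, s)$mean_mm +
                  brute_force_nearest(s, p)$mean_mm) / 2,
               tolerance = 1e-12)
})

test_that("the statistic is invariant under rigid motion", {
  p <- random_cloud(200, 21)
  s <- random_cloud(300, 22)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -3, 11)
  move <- function(cl) surface_cloud(sweep(cl$points %*% t(R), 2, tr, "+"))
  d0 <- directed_mean_surface_distance(p, s)$mean_mm
  d1 <- directed_mean_surface_distance(move(p), move(s))$mean_mm
  expect_lt(abs(d0 - d1), 1e-9)
})

test_that("halving the sampling step moves the statistic by < 2%", {
  a <- structure_set("a", list(r = generate_phantom_truth(
    phantom_spec("r", "ellipsoid", list(a = 20, b = 18, c = 16)))))
  b <- structure_set("b", list(r = generate_phantom_truth(
    phantom_spec("r", "ellipsoid", list(a = 22, b = 20, c = 18)))))
  d1 <- directed_mean_surface_distance(sample_surface(a, "r", 1.0),
                                       sample_surface(b, "r", 1.0))$mean_mm
  d2 <- directed_mean_surface_distance(sample_surface(a, "r", 0.5),
                                       sample_surface(b, "r", 0.5))$mean_mm
  expect_lt(abs(d1 - d2) / d2, 0.02)
})

test_that("flat-limit: Gaussian normal offsets give mean sigma*sqrt(2/pi)", {
  # 100 x 100 grid at 1 mm pitch; offsets small against the pitch so each
  # point's nearest displaced neighbour is its own image
  g <- as.matrix(expand.grid(x = 1:100, y = 1:100))
  sigma <- 0.25
  set.seed(99)
  z <- rnorm(nrow(g), sd = sigma)
  plane <- surface_cloud(cbind(g, 0))
  displaced <- surface_cloud(cbind(g, z))
  res <- directed_mean_surface_distance(plane, displaced)
  expect_equal(res$mean_mm, sigma * sqrt(2 / pi),
               tolerance = 0.05)
})
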