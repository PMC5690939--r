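# Small geometric fixtures shared across test files; everything is built in
# code so the suite carries no data files.

unit_square_ss <- function(z = 0) {
  structure_set("sq", list(
    square = list(planar_contour(z, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  ))
}

circle_ss <- function(radius = 10, n = 100, z = 0, name = "circ") {
  th <- 2 * pi * (seq_len(n) - 1) / n
  xy <- cbind(radius * cos(th), radius * sin(th))
  rois <- list(list(planar_contour(z, xy)))
  names(rois) <- name
  structure_set("circ_study", rois)
}

tube_truth_ss <- function(radius = 30, length = 60, center = c(0, 0, 0),
                          study_id = "tube") {
  spec <- phantom_spec("tube", "tube",
                       list(radius = radius, length = length), center)
  structure_set(study_id, list(tube = generate_phantom_truth(spec)))
}

random_cloud <- function(n, seed, scale = 10) {
  set.seed(seed)
  surface_cloud(matrix(rnorm(3 * n, sd = scale), ncol = 3))
}

# uniformly sampled sphere point cloud
sphere_cloud <- function(radius, n, seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  ph <- acos(runif(n, -1, 1))
  surface_cloud(cbind(radius * sin(ph) * cos(th),
                      radius * sin(ph) * sin(th),
                      radius * cos(ph)))
}

default_box <- function(half = 50) {
  list(min = rep(-half, 3), max = rep(half, 3))
}

# single-organ cohort used by the recovery tests: one large tube so the
# flat-limit noise calibrations apply
tube_cohort <- function(n_patients, noise, n_recontour = 5, ...) {
  spec <- phantom_spec("tube", "tube", list(radius = 28, length = 64))
  simulate_cohort(list(spec), noise, n_patients = n_patients,
                  n_recontour = n_recontour, ...)
}
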