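# Smooth scalar Gaussian random fields via random Fourier features.
#
# f(x) = sigma * sqrt(2/M) * sum_k cos(w_k . x + phi_k),
# w_k ~ N(0, I / ell^2), phi_k ~ U(0, 2*pi)
#
# Each cosine term has variance exactly 1/2 over the phase, so the pointwise
# SD is exactly sigma, and the covariance is the squared-exponential kernel
# sigma^2 * exp(-|dx|^2 / (2 ell^2)) in the limit of many features. With the
# default 128 features the field is close enough to Gaussian that half-normal
# moment calibrations hold to a few percent. Used for observer bias fields
# and per-session delineation noise along contour boundaries.

#' Create a smooth scalar random field
#'
#' @param sigma_mm pointwise standard deviation of the field value (mm)
#' @param correlation_length_mm kernel length scale (mm)
#' @param seed integer seed
#' @param n_features number of random Fourier features
#' @return an object of class `smooth_field`: call it on an n x 3 matrix of
#'   points to get n field values
#' @export
smooth_scalar_field <- function(sigma_mm, correlation_length_mm, seed,
                                n_features = 128) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (correlation_length_mm <= 0) stop("correlation_length_mm must be > 0")
  set.seed(seed)
  W <- matrix(rnorm(3 * n_features, sd = 1 / correlation_length_mm),
              nrow = 3)
  phi <- runif(n_features, 0, 2 * pi)
  f <- function(points) {
    points <- as.matrix(points)
    if (sigma_mm == 0) return(rep(0, nrow(points)))
    proj <- points %*% W
    proj <- sweep(proj, 2, phi, "+")
    sigma_mm * sqrt(2 / n_features) * rowSums(cos(proj))
  }
  class(f) <- c("smooth_field", "function")
  attr(f, "sigma_mm") <- sigma_mm
  attr(f, "correlation_length_mm") <- correlation_length_mm
  attr(f, "seed") <- seed
  f
}

#' A field that is identically zero
#' @return a `smooth_field` returning 0 everywhere
#' @export
zero_scalar_field <- function() {
  f <- function(points) rep(0, nrow(as.matrix(points)))
  class(f) <- c("smooth_field", "function")
  attr(f, "sigma_mm") <- 0
  f
}
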