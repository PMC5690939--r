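#' Derive a child seed from a master seed and a key path
#'
#' Deterministic stream splitting: every random draw in the package derives
#' its own seed from one master seed plus a sequence of integer/character
#' keys, so that components can be regenerated independently and a cohort is
#' reproduced byte-for-byte from its master seed.
#'
#' Uses a multiplicative fold modulo a prime below 2^31; characters are
#' folded via their byte values.
#'
#' @param master integer master seed
#' @param ... integer or character keys identifying the stream
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
seed_stream <- function(master, ...) {
  keys <- list(...)
  m <- 2147483629 # prime < 2^31
  h <- (as.numeric(master) %% m)
  fold <- function(h, k) (h * 69069 + k + 1) %% m
  for (key in keys) {
    if (is.character(key)) {
      for (b in utf8ToInt(key)) h <- fold(h, b)
    } else {
      h <- fold(h, as.numeric(key))
    }
  }
  as.integer(h %% (2^31 - 2)) + 1L
}

#' Round half away from zero
#'
#' Presentation rounding used for all table-shaped outputs: 0.05 rounds to
#' 0.1 (unlike base [round()], which rounds half to even).
#'
#' @param x numeric vector
#' @param digits number of decimal digits
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# smoothstep ramp: 0 at t<=0, 1 at t>=1, C1 in between
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
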