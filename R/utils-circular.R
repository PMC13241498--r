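#' Wrap angles into [0, 2*pi)
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector with every finite value mapped to `[0, 2*pi)`.
#' @export
#' @examples
#' wrap_phase(c(-pi / 2, 3 * pi))
wrap_phase <- function(x) {
  x %% (2 * pi)
}

#' Signed circular distance between two angles
#'
#' Returns the difference `a - b` wrapped into `(-pi, pi]`.
#'
#' @param a,b Numeric vectors of angles in radians (recycled).
#' @return Numeric vector of signed angular differences.
#' @export
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Circular mean of a set of angles
#'
#' Argument of the mean resultant vector, mapped to `[0, 2*pi)`.
#' `NA` values are dropped.
#'
#' @param x Numeric vector of angles in radians.
#' @return A single angle in `[0, 2*pi)`, or `NA` if no finite input.
#' @export
circ_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  wrap_phase(atan2(mean(sin(x)), mean(cos(x))))
}

#' Mean resultant length of a set of angles
#'
#' @param x Numeric vector of angles in radians; `NA` dropped.
#' @return Scalar in `[0, 1]`.
#' @export
resultant_length <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean(cos(x))^2 + mean(sin(x))^2)
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher (1979) rejection sampler. The von Mises distribution is the
#' canonical unimodal circular distribution; its mean resultant length is
#' `besselI(kappa, 1) / besselI(kappa, 0)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration, `>= 0`. `kappa = 0` gives the circular
#'   uniform distribution.
#' @return Numeric vector of `n` angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_phase(out)
}

#' Von Mises mean resultant length
#'
#' The population resultant length `I1(kappa)/I0(kappa)`; its square is the
#' expected pairwise phase consistency of von Mises phases.
#'
#' @param kappa Concentration parameter, `>= 0`.
#' @return Scalar in `[0, 1)`.
#' @export
von_mises_resultant <- function(kappa) {
  stopifnot(all(kappa >= 0))
  ifelse(kappa == 0, 0, besselI(kappa, 1) / besselI(kappa, 0))
}
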