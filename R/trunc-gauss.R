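# Truncated-Gaussian integrals underlying the cavity self-consistency
# equations. All moments of the steady-state abundance laws reduce to
#
#   w_n(Delta) = int_{-Delta}^{Inf} dx/sqrt(2*pi) (x + Delta)^n exp(-x^2/2),
#
# evaluated here in closed form via the standard normal density/CDF.

# |Delta| beyond this is saturated to double precision; see w_integral().
.DELTA_CLIP <- 40

#' Truncated-Gaussian integrals w_n
#'
#' Computes \eqn{w_n(\Delta) = \int_{-\Delta}^{\infty} \frac{dx}{\sqrt{2\pi}}
#' (x+\Delta)^n e^{-x^2/2}} for orders \eqn{n \in \{0, 1, 2\}}, the three
#' integrals from which all moments of a truncated-Gaussian abundance law
#' \eqn{\max(0, (a + c z)/b)} are built. Closed forms are used:
#' \eqn{w_0 = \Phi(\Delta)}, \eqn{w_1 = \phi(\Delta) + \Delta\Phi(\Delta)},
#' \eqn{w_2 = (1+\Delta^2)\Phi(\Delta) + \Delta\phi(\Delta)}.
#'
#' \code{delta} is clipped to \eqn{[-40, 40]} before evaluation: beyond that
#' range the integrals are 0 or saturated to full support at double
#' precision, and the clip keeps downstream root finding free of
#' overflow/NaN.
#'
#' @param n Integer order, one of 0, 1, 2. \eqn{w_0} is the survival
#'   probability (standard normal CDF at \eqn{\Delta}); \eqn{w_1}, \eqn{w_2}
#'   give first and second moments.
#' @param delta Numeric vector of dimensionless arguments
#'   (\eqn{\Delta = g_{\mathrm{eff}}/\sigma_{g_{\mathrm{eff}}}} for some
#'   trophic level).
#' @return Numeric vector the length of \code{delta}; nonnegative, with
#'   \eqn{w_0 \in [0, 1]}, and each \eqn{w_n} non-decreasing in \code{delta}.
#' @examples
#' w_integral(0, 0)      # 0.5
#' w_integral(1, 0)      # 1/sqrt(2*pi)
#' w_integral(2, -Inf)   # 0
#' @export
w_integral <- function(n, delta) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != round(n) ||
      !(n %in% c(0, 1, 2))) {
    stop("unsupported order: w_integral is defined for n in {0, 1, 2}",
         call. = FALSE)
  }
  d <- pmin(pmax(delta, -.DELTA_CLIP), .DELTA_CLIP)
  v <- switch(as.character(n),
    "0" = stats::pnorm(d),
    "1" = stats::dnorm(d) + d * stats::pnorm(d),
    "2" = (1 + d^2) * stats::pnorm(d) + d * stats::dnorm(d)
  )
  # deep in the left tail the closed forms cancel to within rounding of 0
  pmax(v, 0)
}

#' Moments of a rectified Gaussian ratio
#'
#' The j-th moment of \eqn{y = \max(0, (a + c z)/b)} with \eqn{z} standard
#' normal: \eqn{\langle y^j \rangle = (c/b)^j w_j(a/c)}. This is the
#' single-species abundance law at each trophic level, with \eqn{a} the mean
#' effective growth rate, \eqn{c} its standard deviation and \eqn{b} the
#' emergent self-competition coefficient.
#'
#' @param j Integer moment order in \{0, 1, 2\}.
#' @param a Numeric, location (mean effective growth rate).
#' @param b Positive numeric, scale divisor (competition coefficient).
#' @param c Positive numeric, Gaussian standard deviation.
#' @return Nonnegative numeric. For \code{j = 0} this is the survival
#'   probability \eqn{\Phi(a/c)}, independent of \code{b}.
#' @examples
#' truncated_moment(1, 0, 1, 1)  # half-normal mean 1/sqrt(2*pi)
#' truncated_moment(0, 1, 5, 2)  # pnorm(0.5)
#' @export
truncated_moment <- function(j, a, b, c) {
  if (any(b <= 0)) stop("domain error: b must be > 0", call. = FALSE)
  if (any(c <= 0)) stop("domain error: c must be > 0", call. = FALSE)
  (c / b)^j * w_integral(j, a / c)
}
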