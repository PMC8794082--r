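#' Log normalising constant of the von Mises-Fisher distribution
#'
#' Computes \eqn{\log C_m(\kappa)} for the m-dimensional von Mises-Fisher
#' density \eqn{f(x \mid \mu, \kappa) = C_m(\kappa) e^{\kappa \mu' x}},
#' where
#' \deqn{C_m(\kappa) = \frac{\kappa^{m/2-1}}{(2\pi)^{m/2} I_{m/2-1}(\kappa)}}
#' and \eqn{I_\nu} is the modified Bessel function of the first kind.
#' Exponentially scaled Bessel evaluation keeps the result finite for
#' large \eqn{\kappa} (naive \eqn{I_{3.5}(500)} overflows double
#' precision). At \eqn{\kappa = 0} the continuity limit is returned: the
#' log reciprocal surface area of the (m-1)-sphere.
#'
#' @param m dimension (number of traits), integer >= 2.
#' @param kappa non-negative concentration(s); vectorised.
#' @return numeric vector of \eqn{\log C_m(\kappa)}.
#' @examples
#' vmfLogConst(2, 0)   # log(1 / (2 * pi))
#' vmfLogConst(3, 1)   # log(1 / (4 * pi * sinh(1)))
#' @export
vmfLogConst <- function(m, kappa) {
  if (length(m) != 1L || m < 2 || m != round(m))
    stop("'m' must be a single integer >= 2")
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("'kappa' must be non-negative and finite")
  nu <- m / 2 - 1
  out <- numeric(length(kappa))
  zero <- kappa == 0
  # kappa -> 0 limit: uniform density 1 / A_{m-1}, A = 2 pi^{m/2} / Gamma(m/2)
  out[zero] <- lgamma(m / 2) - log(2) - (m / 2) * log(pi)
  if (any(!zero)) {
    k <- kappa[!zero]
    logI <- log(besselI(k, nu, expon.scaled = TRUE)) + k
    out[!zero] <- nu * log(k) - (m / 2) * log(2 * pi) - logI
  }
  out
}

#' Log density of the von Mises-Fisher distribution
#'
#' Evaluates \eqn{\log f(x \mid \mu, \kappa) = \log C_m(\kappa) +
#' \kappa \mu' x} for a unit vector \code{x}.
#'
#' @param x numeric unit vector (or matrix with unit rows).
#' @param params a \linkS4class{VMFParams} object.
#' @return numeric log density (one value per row of \code{x}).
#' @examples
#' vmfLogDensity(c(0, 1), VMFParams(c(1, 0), 0))  # uniform on the circle
#' @export
vmfLogDensity <- function(x, params) {
  stopifnot(is(params, "VMFParams"))
  validObject(params)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(params@mu))
    stop("dimension of 'x' does not match 'mu'")
  nrm <- sqrt(rowSums(x^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("'x' must be a unit vector")
  drop(vmfLogConst(ncol(x), params@kappa) +
         params@kappa * (x %*% params@mu))
}

#' Bessel function ratio A_m(kappa)
#'
#' \eqn{A_m(\kappa) = I_{m/2}(\kappa) / I_{m/2-1}(\kappa)}, the mean
#' resultant length of a vMF distribution with concentration
#' \eqn{\kappa} in m dimensions. Strictly increasing in \eqn{\kappa} with
#' values in (0, 1).
#'
#' @param m dimension, integer >= 2.
#' @param kappa positive concentration(s); vectorised.
#' @return numeric vector in (0, 1).
#' @examples
#' besselRatio(3, 1)  # coth(1) - 1/1
#' @export
besselRatio <- function(m, kappa) {
  if (length(m) != 1L || m < 2 || m != round(m))
    stop("'m' must be a single integer >= 2")
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  besselI(kappa, m / 2, expon.scaled = TRUE) /
    besselI(kappa, m / 2 - 1, expon.scaled = TRUE)
}

#' Estimate the vMF concentration from the mean resultant length
#'
#' Inverts \eqn{A_m(\kappa) = \bar r} using the closed-form approximation
#' of Banerjee et al.,
#' \deqn{\hat\kappa = \frac{\bar r m - \bar r^3}{1 - \bar r^2},}
#' capped at \code{kappaCap}. Mean resultant lengths very close to 1
#' correspond to near-degenerate concentrations; callers clip
#' \eqn{\bar r} below 1 and the cap makes the distinction immaterial.
#' With \code{method = "newton"} the approximation is refined by a few
#' Newton steps on \eqn{A_m(\kappa) - \bar r}.
#'
#' @param rBar mean resultant length(s) in [0, 1); vectorised.
#' @param m dimension, integer >= 2.
#' @param kappaCap upper bound for the estimate (default 500).
#' @param method "banerjee" (default) or "newton".
#' @return non-negative concentration estimate(s), at most \code{kappaCap}.
#' @examples
#' estimateKappa(0.5, 2)  # (0.5 * 2 - 0.125) / (1 - 0.25)
#' @export
estimateKappa <- function(rBar, m, kappaCap = 500,
                          method = c("banerjee", "newton")) {
  method <- match.arg(method)
  if (length(m) != 1L || m < 2 || m != round(m))
    stop("'m' must be a single integer >= 2")
  if (any(!is.finite(rBar)) || any(rBar < 0) || any(rBar >= 1))
    stop("'rBar' must lie in [0, 1); clip values near 1 before calling")
  k <- (rBar * m - rBar^3) / (1 - rBar^2)
  if (method == "newton") {
    for (i in seq_along(k)) {
      if (k[i] <= 0 || k[i] >= kappaCap) next
      for (it in 1:25) {
        a <- besselRatio(m, k[i])
        # A'(k) = 1 - A^2 - (m-1)/k * A
        da <- 1 - a^2 - (m - 1) / k[i] * a
        step <- (a - rBar[i]) / da
        k[i] <- k[i] - step
        if (k[i] <= 0) { k[i] <- 1e-8 }
        if (abs(step) < 1e-10 * (1 + k[i])) break
      }
    }
  }
  pmin(pmax(k, 0), kappaCap)
}
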