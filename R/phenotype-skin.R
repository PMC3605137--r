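## Skin-color phenotype: melanin index from 650 nm reflectance, robust
## panel summary, square-root (MM) transform.

#' Melanin index from reflectance
#'
#' \code{M = 100 * log10(1 / reflectance)} with reflectance at 650 nm
#' expressed as a fraction in (0, 1]. Strictly decreasing in reflectance;
#' full reflectance maps to 0.
#'
#' @param reflectance Numeric vector of reflectance fractions in (0, 1].
#' @return Melanin-index values (same length).
#' @export
mIndex <- function(reflectance) {
  if (any(!is.finite(reflectance)) ||
      any(reflectance <= 0 | reflectance > 1))
    stop("reflectance must lie in (0, 1]", call. = FALSE)
  100 * log10(1 / reflectance)
}

#' Huber M-estimator of location
#'
#' Iteratively reweighted location estimate with Huber's psi, tuning constant
#' \code{k} (default 1.345, 95% Gaussian efficiency) on the MAD scale.
#' Delegates to \code{MASS::huber}; when the MAD is zero (so the scale cannot
#' be estimated) the estimate falls back to the median and the result carries
#' attribute \code{"fallback" = TRUE}.
#'
#' @param x Numeric vector.
#' @param k Tuning constant.
#' @param tol Convergence tolerance for the IRLS iteration.
#' @return Scalar location estimate.
#' @export
huberLocation <- function(x, k = 1.345, tol = 1e-8) {
  if (mad(x) == 0) {
    est <- median(x)
    attr(est, "fallback") <- TRUE
    return(est)
  }
  MASS::huber(x, k = k, tol = tol)$mu
}

#' MM index from a six-reading melanin panel
#'
#' The square root of the Huber-robust mean of the six melanin-index
#' readings taken per individual (three per arm). The square-root transform
#' makes the cohort distribution closer to normal.
#'
#' @param panel Numeric vector of six M values, or an n x 6 matrix (one row
#'   per individual).
#' @param k,tol Passed to \code{\link{huberLocation}}.
#' @return Scalar MM value, or a vector of n MM values for matrix input.
#' @export
mmIndex <- function(panel, k = 1.345, tol = 1e-8) {
  if (is.matrix(panel)) {
    if (ncol(panel) != 6L) stop("panel must have six readings per individual",
                                call. = FALSE)
    return(apply(panel, 1, mmIndex, k = k, tol = tol))
  }
  if (length(panel) != 6L || any(!is.finite(panel)))
    stop("panel must be exactly six finite M values", call. = FALSE)
  loc <- huberLocation(panel, k = k, tol = tol)
  if (loc < 0) stop("robust mean of the panel is negative", call. = FALSE)
  sqrt(as.numeric(loc))
}

#' MM index straight from a reflectance panel
#'
#' @param reflectance n x 6 matrix (or length-6 vector) of reflectance
#'   fractions.
#' @param ... Passed to \code{\link{mmIndex}}.
#' @return MM values.
#' @export
mmFromReflectance <- function(reflectance, ...) {
  M <- mIndex(reflectance)
  if (is.matrix(reflectance)) {
    M <- matrix(M, nrow(reflectance), ncol(reflectance))
    mmIndex(M, ...)
  } else {
    mmIndex(M, ...)
  }
}
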