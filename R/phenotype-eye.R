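## Eye-color phenotype: normalized iris RGB, principal-curve fit in the
## (green, blue) plane, and the arc-length T index.

#' Normalized median RGB of an iris pixel set
#'
#' Per-channel median over all pixels first, then normalization so the three
#' channels sum to one. Invariant to a common exposure (scale) factor.
#'
#' @param pixels Numeric matrix (m x 3) of R, G, B pixel values.
#' @return Named numeric vector c(r, g, b) summing to 1.
#' @export
medianRGB <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  if (ncol(pixels) != 3L) stop("pixels must have three channels", call. = FALSE)
  med <- apply(pixels, 2, median)
  s <- sum(med)
  if (s <= 0) stop("all-black pixel set: channel medians sum to zero",
                   call. = FALSE)
  out <- med / s
  names(out) <- c("r", "g", "b")
  out
}

## Project points (n x 2) onto a polyline given by vertices (m x 2) with
## cumulative arc-length arc (length m). Ties broken toward smaller
## arc-length because only strictly smaller distances replace the running
## minimum. Returns lambda (arc-length coordinate), squared distance and the
## projected coordinates.
projectToPolyline <- function(points, vertices, arc) {
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(points)
  best <- rep(Inf, n)
  lambda <- numeric(n)
  proj <- matrix(0, n, 2)
  for (s in seq_len(nrow(vertices) - 1L)) {
    v1 <- vertices[s, ]; v2 <- vertices[s + 1L, ]
    d <- v2 - v1
    len2 <- sum(d^2)
    t <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, ((points[, 1] - v1[1]) * d[1] +
                       (points[, 2] - v1[2]) * d[2]) / len2))
    px <- v1[1] + t * d[1]; py <- v1[2] + t * d[2]
    dist2 <- (points[, 1] - px)^2 + (points[, 2] - py)^2
    upd <- dist2 < best - 1e-15
    if (any(upd)) {
      best[upd] <- dist2[upd]
      lambda[upd] <- arc[s] + t[upd] * sqrt(len2)
      proj[upd, 1] <- px[upd]; proj[upd, 2] <- py[upd]
    }
  }
  list(lambda = lambda, dist2 = best, proj = proj)
}

cumArcLength <- function(v) {
  if (nrow(v) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(v)^2))))
}

#' Fit a principal curve in the (green, blue) plane
#'
#' Hastie-Stuetzle iteration: points are projected onto the current curve,
#' each coordinate is smoothed against the arc-length parameter (LOWESS with
#' span \code{span}), and the curve is reparametrized by arc-length, starting
#' from the first-principal-component line and stopping when the mean squared
#' projection distance changes by less than \code{tol}. The fitted curve is
#' oriented so that the endpoint with the higher blue coordinate (the
#' lightest eye color) sits at arc-length 0.
#'
#' @param points Numeric matrix (n x 2) of normalized (green, blue)
#'   coordinates; at least 10 distinct points.
#' @param span LOWESS span (fraction of points in each local fit).
#' @param maxIter Maximum number of projection/smoothing iterations.
#' @param tol Convergence tolerance on the change in mean squared projection
#'   distance.
#' @return A \code{\link{PrincipalCurve}}; non-convergence returns the best
#'   iterate with a warning.
#' @export
fitPrincipalCurve <- function(points, span = 0.3, maxIter = 50, tol = 1e-6) {
  points <- matrix(as.numeric(as.matrix(points)), ncol = 2)
  if (nrow(points) < 10L) stop("need at least 10 points", call. = FALSE)
  if (all(points[, 1] == points[1, 1]) && all(points[, 2] == points[1, 2]))
    stop("points must not all be identical", call. = FALSE)

  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  v <- svd(cen, nu = 0, nv = 1)$v[, 1]
  lambda <- drop(cen %*% v)

  makeCurve <- function(lambda) {
    ord <- order(lambda)
    lx <- lambda[ord]
    fx <- lowess(lx, points[ord, 1], f = span, iter = 0)
    fy <- lowess(lx, points[ord, 2], f = span, iter = 0)
    keep <- !duplicated(fx$x)
    v <- cbind(fx$y[keep], fy$y[keep])
    # drop consecutive duplicate vertices (flat smoother segments)
    if (nrow(v) > 1) {
      dup <- c(FALSE, rowSums(abs(diff(v))) < 1e-14)
      v <- v[!dup, , drop = FALSE]
    }
    v
  }

  # degenerate but legal: collinear clouds give an exact line immediately
  msd <- Inf
  converged <- FALSE
  iter <- 0L
  vertices <- cbind(ctr[1] + range(lambda)[c(1, 2)] * v[1],
                    ctr[2] + range(lambda)[c(1, 2)] * v[2])
  arc <- cumArcLength(vertices)

  while (iter < maxIter) {
    iter <- iter + 1L
    newV <- makeCurve(lambda)
    if (nrow(newV) < 2) break
    newArc <- cumArcLength(newV)
    pr <- projectToPolyline(points, newV, newArc)
    newMsd <- mean(pr$dist2)
    vertices <- newV; arc <- newArc; lambda <- pr$lambda
    if (is.finite(msd) && abs(msd - newMsd) < tol) {
      msd <- newMsd
      converged <- TRUE
      break
    }
    msd <- newMsd
  }
  if (!converged)
    warning("principal curve did not converge; returning best iterate")

  # orient: arc-length 0 at the lightest (highest blue fraction) end
  if (vertices[1, 2] < vertices[nrow(vertices), 2]) {
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
    arc <- cumArcLength(vertices)
  }
  new("PrincipalCurve", vertices = vertices, arcLength = arc,
      converged = converged, iterations = iter,
      meanSqDist = as.numeric(msd))
}

#' T index: arc-length position along the principal curve
#'
#' Each point in the normalized (green, blue) plane is projected onto its
#' nearest position on the fitted curve; the T index is the cumulative
#' arc-length of that position from the lightest-color end of the curve.
#' Working values of 0-0.15 correspond roughly to blue/green and 0.15-0.4 to
#' brown eye color.
#'
#' @param points Numeric matrix (n x 2) of (green, blue) coordinates, or a
#'   single length-2 vector.
#' @param curve A fitted \code{\link{PrincipalCurve}}.
#' @return Numeric vector of arc-length values in [0, total curve length].
#' @export
tIndex <- function(points, curve) {
  stopifnot(is(curve, "PrincipalCurve"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  projectToPolyline(as.matrix(points)[, 1:2, drop = FALSE],
                    curve@vertices, curve@arcLength)$lambda
}
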