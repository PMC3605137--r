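## Synthetic iris photographs and circular-edge iris segmentation.
##
## Images are numeric arrays height x width x 3 with values in [0, 1];
## pixel (row, col) has center coordinates (x = col, y = row).

#' Iris color ladder from light blue to dark brown
#'
#' Interpolates raw RGB colors along a darkness parameter s in [0, 1] through
#' anchor colors chosen so that, after median-RGB normalization, the ladder
#' traces an arc in the (green, blue) plane whose length sits inside the
#' working T-index range (roughly 0-0.4, light blue at 0).
#'
#' @param s Darkness parameter values in [0, 1] (0 = lightest blue,
#'   1 = darkest brown).
#' @return Matrix length(s) x 3 of RGB values in [0, 1].
#' @export
irisColorLadder <- function(s) {
  if (any(s < 0 | s > 1)) stop("'s' must lie in [0, 1]", call. = FALSE)
  anchors <- rbind(
    c(0.47, 0.60, 0.80),   # light blue
    c(0.42, 0.52, 0.55),   # blue-green
    c(0.52, 0.52, 0.35),   # hazel
    c(0.45, 0.33, 0.20),   # light brown
    c(0.31, 0.195, 0.115), # medium brown
    c(0.18, 0.105, 0.055)  # dark brown
  )
  at <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  out <- sapply(1:3, function(ch) approx(at, anchors[, ch], xout = s)$y)
  matrix(out, ncol = 3)
}

#' Render a synthetic iris photograph
#'
#' Concentric near-black pupil, iris annulus at a base RGB color with
#' additive Gaussian pixel noise, and a light sclera background. The true
#' pupil center is returned as the landmark.
#'
#' @param width,height Image dimensions in pixels.
#' @param pupilCenter Length-2 (x, y) pupil center; default image center.
#' @param pupilRadius,irisRadius Radii in pixels; must satisfy
#'   \code{pupilRadius < irisRadius < min(width, height) / 2}.
#' @param irisRGB Length-3 base iris color in [0, 1].
#' @param scleraRGB,pupilRGB Background and pupil colors.
#' @param noiseSD SD of additive Gaussian noise (on the [0, 1] scale),
#'   applied to every pixel and clipped back to [0, 1].
#' @param seed Optional integer seed.
#' @return List with \code{image} (height x width x 3 array),
#'   \code{pupilCenter}, and the radii.
#' @export
synthIrisImage <- function(width = 120, height = 120, pupilCenter = NULL,
                           pupilRadius = 14, irisRadius = 40,
                           irisRGB = c(0.45, 0.33, 0.20),
                           scleraRGB = c(0.96, 0.94, 0.92),
                           pupilRGB = c(0.04, 0.04, 0.04),
                           noiseSD = 0, seed = NULL) {
  if (!(pupilRadius < irisRadius && irisRadius < min(width, height) / 2))
    stop("radii must satisfy pupilRadius < irisRadius < min(dims)/2",
         call. = FALSE)
  pupilCenter <- pupilCenter %||% c(width / 2, height / 2)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  r <- sqrt((xs - pupilCenter[1])^2 + (ys - pupilCenter[2])^2)
  img <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    plane <- matrix(scleraRGB[ch], height, width)
    plane[r <= irisRadius] <- irisRGB[ch]
    plane[r <= pupilRadius] <- pupilRGB[ch]
    img[, , ch] <- plane
  }
  if (noiseSD > 0)
    img <- withSeed(seed, {
      x <- img + array(rnorm(length(img), 0, noiseSD), dim(img))
      x[x < 0] <- 0
      x[x > 1] <- 1
      x
    })
  list(image = img, pupilCenter = pupilCenter,
       pupilRadius = pupilRadius, irisRadius = irisRadius)
}

## Mean-channel intensity sampled (nearest pixel) on a circle of radius r
## around center; NA for samples falling outside the image.
.radialProfile <- function(intensity, center, radii, nAngles = 90) {
  theta <- seq(0, 2 * pi, length.out = nAngles + 1)[-1]
  h <- nrow(intensity); w <- ncol(intensity)
  vapply(radii, function(r) {
    x <- round(center[1] + r * cos(theta))
    y <- round(center[2] + r * sin(theta))
    ok <- x >= 1 & x <= w & y >= 1 & y <= h
    if (!any(ok)) return(NA_real_)
    mean(intensity[cbind(y[ok], x[ok])])
  }, numeric(1))
}

#' Segment the iris annulus by circular edge detection
#'
#' Starting from a pupil landmark, the mean RGB intensity is averaged around
#' circles of increasing radius; the inner (pupil-iris) and outer
#' (iris-sclera) boundaries are the two strongest radial-gradient maxima. If
#' fewer than two gradient maxima exceed \code{minGradient} the individual is
#' flagged with a failure status rather than dropped.
#'
#' @param image Numeric array height x width x 3 in [0, 1].
#' @param landmark Length-2 (x, y) pupil landmark (must lie inside the
#'   image).
#' @param rMax Maximum search radius (default: largest radius fully inside
#'   the image from the landmark).
#' @param nAngles Number of angular samples per circle.
#' @param minGradient Minimum absolute intensity step (per pixel of radius)
#'   for a circular edge.
#' @return List with \code{status} ("ok" or "failed"), \code{inner} and
#'   \code{outer} radii, and \code{pixels} (m x 3 matrix of annulus RGB
#'   values; NULL on failure).
#' @export
extractIris <- function(image, landmark, rMax = NULL, nAngles = 120,
                        minGradient = 0.04) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (landmark[1] < 1 || landmark[1] > w || landmark[2] < 1 || landmark[2] > h)
    stop("landmark must lie inside the image", call. = FALSE)
  rMax <- rMax %||% floor(min(landmark[1] - 1, w - landmark[1],
                              landmark[2] - 1, h - landmark[2]))
  if (is.null(rMax) || rMax < 4)
    return(list(status = "failed", inner = NA, outer = NA, pixels = NULL))
  intensity <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  radii <- seq_len(rMax)
  prof <- .radialProfile(intensity, landmark, radii, nAngles)
  grad <- abs(diff(prof))           # step from radius r to r + 1
  grad[is.na(grad)] <- 0
  # local maxima of the gradient profile above threshold
  isMax <- grad >= minGradient &
    grad >= c(-Inf, grad[-length(grad)]) &
    grad >= c(grad[-1], -Inf)
  cand <- which(isMax)
  # collapse adjacent candidates to the strongest of each run
  if (length(cand) > 1) {
    runs <- cumsum(c(1, diff(cand) > 2))
    cand <- vapply(split(cand, runs),
                   function(ix) ix[which.max(grad[ix])], integer(1))
  }
  if (length(cand) < 2)
    return(list(status = "failed", inner = NA, outer = NA, pixels = NULL))
  top2 <- sort(cand[order(grad[cand], decreasing = TRUE)][1:2])
  inner <- top2[1] + 0.5   # edge lies between radius r and r + 1
  outer <- top2[2] + 0.5
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  r <- sqrt((xs - landmark[1])^2 + (ys - landmark[2])^2)
  inAnnulus <- r > inner & r < outer
  pixels <- cbind(image[, , 1][inAnnulus],
                  image[, , 2][inAnnulus],
                  image[, , 3][inAnnulus])
  list(status = "ok", inner = inner, outer = outer, pixels = pixels)
}

#' Write / read an iris image as PNG
#'
#' @param image Numeric array height x width x 3 in [0, 1].
#' @param path File path.
#' @return \code{readIrisPNG} returns the image array.
#' @export
writeIrisPNG <- function(image, path) {
  png::writePNG(image, target = path)
  invisible(path)
}

#' @rdname writeIrisPNG
#' @export
readIrisPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
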