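## Independent oracles and small fixture builders used across the suite.

## High-precision Huber IRLS location, written independently of
## MASS::huber: fixed MAD scale, psi truncation at k, iterated to eps.
oracleHuber <- function(x, k = 1.345, eps = 1e-12, maxit = 500) {
  s <- mad(x)
  mu <- median(x)
  for (i in seq_len(maxit)) {
    z <- pmin(k * s, pmax(-k * s, x - mu))
    muNew <- mu + mean(z)
    if (abs(muNew - mu) < eps * s) return(muNew)
    mu <- muNew
  }
  mu
}

## Closed-form OLS via normal equations.
oracleOLS <- function(X, y) {
  X <- cbind(1, X)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  t <- b / se
  list(beta = drop(b), se = se, p = 2 * pt(abs(t), df, lower.tail = FALSE),
       rss = sum(res^2))
}

## Moments of the truncated Beta ancestry distribution by numeric
## integration (independent of the rejection sampler).
truncBetaMoments <- function(mean = 0.58, sd = 0.12,
                             lower = 0.235, upper = 0.879) {
  nu <- mean * (1 - mean) / sd^2 - 1
  a <- mean * nu; b <- (1 - mean) * nu
  Z <- pbeta(upper, a, b) - pbeta(lower, a, b)
  m1 <- integrate(function(x) x * dbeta(x, a, b) / Z, lower, upper)$value
  m2 <- integrate(function(x) x^2 * dbeta(x, a, b) / Z, lower, upper)$value
  c(mean = m1, var = m2 - m1^2)
}

## Small deterministic genotype/phenotype table used by the PAV tests.
toyPavTable <- function() {
  G <- cbind(L1 = c(0, 1, 2, 0, 1, 2),
             L2 = c(0, 0, 1, 1, 2, 2))
  Y <- c(7.0, 6.8, 6.1, 7.2, 6.4, 5.9)
  list(G = G, Y = Y)
}

## Points on the iris color ladder in the normalized (green, blue) plane.
ladderGB <- function(s) {
  rgb <- irisColorLadder(s)
  t(apply(rgb, 1, function(x) (x / sum(x))[2:3]))
}

## Jittered calibration cloud along the color ladder.
ladderCloud <- function(k = 30, per = 12, noise = 0.004, seed = 1) {
  pts <- ladderGB(seq(0, 1, length.out = k))
  withr::with_seed(seed, pts[rep(seq_len(k), each = per), ] +
                     matrix(rnorm(k * per * 2, 0, noise), ncol = 2))
}

## Squared projection distances of points onto a fitted curve.
tIndexResid <- function(points, curve) {
  admixcolor:::projectToPolyline(points, curveVertices(curve),
                                 curve@arcLength)$dist2
}
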