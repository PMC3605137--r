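## Power simulation under admixture stratification, and effect-size unit
## conversions between the MM (square-root melanin) and melanin scales.

#' Simulation-based power to detect a candidate pigmentation locus
#'
#' Each replicate draws genome-wide ancestry from the calibrated cohort
#' distribution, per-locus local ancestry Binomial(2, 1 - q), a candidate
#' genotype with ancestral derived-allele frequencies \code{fAfr}/\code{fEur}
#' (defaults 0.1/0.9), and an SLC24A5-like genotype with frequencies
#' (1.00, 0.01). The phenotype follows the fitted linear model
#' (coefficient -4.247 on European ancestry, -0.3459 per SLC24A5 derived
#' allele, \code{-effect} per candidate allele) with residual noise
#' calibrated so the total variance is 0.85^2. The candidate coefficient is
#' then tested by linear regression; power is the fraction of replicates
#' with p below \code{alpha}.
#'
#' The default test adjusts for the two strongest predictors of the
#' phenotype, genome-wide ancestry and the known-locus (SLC24A5) genotype;
#' \code{adjust = "ancestry"} adjusts for ancestry only and
#' \code{adjust = "none"} runs the crude regression.
#'
#' @param effect Candidate per-allele lightening effect (MM units, >= 0).
#' @param n Cohort size per replicate (default 685).
#' @param alpha Significance level(s); power is estimated for each.
#' @param reps Number of replicates (default 1000; at least 50).
#' @param fEur,fAfr Candidate derived-allele frequencies in the ancestral
#'   populations.
#' @param gammaAnc Coefficient on European ancestry.
#' @param betaKnown Per-allele effect of the known (SLC24A5-like) locus.
#' @param knownFreqs Length-2 c(fEur, fAfr) for the known locus.
#' @param varianceTarget Total phenotypic variance (default 0.85^2).
#' @param adjust Covariate set for the candidate test: "ancestry+known"
#'   (default), "ancestry", or "none".
#' @param seed Optional integer seed.
#' @return data.frame with one row per alpha: alpha, power, se, reps, n,
#'   effect.
#' @export
estimatePower <- function(effect, n = 685, alpha = 5e-8, reps = 1000,
                          fEur = 0.9, fAfr = 0.1, gammaAnc = -4.247,
                          betaKnown = -0.3459, knownFreqs = c(1.00, 0.01),
                          varianceTarget = 0.85^2,
                          adjust = c("ancestry+known", "ancestry", "none"),
                          seed = NULL) {
  adjust <- match.arg(adjust)
  if (reps < 50) stop("'reps' must be at least 50", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("'alpha' must lie in (0, 1)",
                                         call. = FALSE)
  pvals <- withSeed(seed, {
    vapply(seq_len(reps), function(i) {
      q <- drawAncestry(n)
      aK <- rbinom(n, 2L, 1 - q)
      gK <- rbinom(n, aK, knownFreqs[1]) + rbinom(n, 2L - aK, knownFreqs[2])
      aC <- rbinom(n, 2L, 1 - q)
      gC <- rbinom(n, aC, fEur) + rbinom(n, 2L - aC, fAfr)
      genetic <- gammaAnc * (1 - q) + betaKnown * gK - effect * gC
      s2 <- varianceTarget - var(genetic)
      if (s2 < 0)
        stop("calibration error: genetic variance exceeds the target",
             call. = FALSE)
      y <- genetic + rnorm(n, 0, sqrt(s2))
      X <- switch(adjust,
                  "ancestry+known" = cbind(1, gC, q, gK),
                  "ancestry" = cbind(1, gC, q),
                  "none" = cbind(1, gC))
      fit <- lm.fit(X, y)
      if (fit$rank < ncol(X)) return(NA_real_)
      rss <- sum(fit$residuals^2)
      dfr <- n - ncol(X)
      XtXinv <- chol2inv(qr.R(fit$qr))
      se <- sqrt(rss / dfr * XtXinv[2, 2])
      2 * pt(abs(fit$coefficients[2] / se), dfr, lower.tail = FALSE)
    }, numeric(1))
  })
  pvals <- pvals[!is.na(pvals)]
  pow <- vapply(alpha, function(a) mean(pvals < a), numeric(1))
  data.frame(alpha = alpha, power = pow,
             se = sqrt(pow * (1 - pow) / length(pvals)),
             reps = length(pvals), n = n, effect = effect)
}

#' Power grid over effect sizes and alpha levels
#'
#' Runs \code{\link{estimatePower}} for every effect size, evaluating all
#' alpha levels on the same replicates.
#'
#' @param effects Vector of candidate effect sizes (MM units per allele).
#' @param alphas Vector of significance levels (default the three working
#'   levels 5e-8, 1e-5, 1e-3).
#' @param ... Passed to \code{\link{estimatePower}}.
#' @param seed Optional integer root seed (one derived seed per effect).
#' @return data.frame stacking the per-effect results.
#' @export
powerGrid <- function(effects, alphas = c(5e-8, 1e-5, 1e-3), ...,
                      seed = NULL) {
  out <- lapply(seq_along(effects), function(i)
    estimatePower(effects[i], alpha = alphas, seed = deriveSeed(seed, i), ...))
  do.call(rbind, out)
}

#' Convert a per-allele effect from MM units to melanin units
#'
#' The melanin index M is the square of the MM index, so a shift of
#' \code{beta} MM at cohort mean \code{meanMM} corresponds to approximately
#' \code{copies * beta * 2 * meanMM} melanin units (local linearization of
#' M = MM^2). The \code{"exact"} mode reports the exact difference of
#' squares \code{meanMM^2 - (meanMM - copies * beta)^2}.
#'
#' @param betaMM Per-allele effect magnitude in MM units.
#' @param meanMM Cohort mean MM (must be > 0).
#' @param copies 1 (per-allele) or 2 (homozygous substitution).
#' @param mode "linear" (default) or "exact".
#' @return Effect size in melanin units.
#' @export
effectUnitConversion <- function(betaMM, meanMM, copies = 1,
                                 mode = c("linear", "exact")) {
  mode <- match.arg(mode)
  if (meanMM <= 0) stop("'meanMM' must be positive", call. = FALSE)
  switch(mode,
         linear = copies * betaMM * 2 * meanMM,
         exact = meanMM^2 - (meanMM - copies * betaMM)^2)
}
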