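## Synthetic admixed-cohort generators.
##
## Conventions used throughout the package:
##  * q is the genome-wide AFRICAN ancestry fraction of an individual;
##  * local ancestry `a` counts copies of EUROPEAN ancestry at a locus, so
##    a | q ~ Binomial(2, 1 - q) under independent assortment;
##  * genotypes G count copies of the DERIVED allele, whose frequencies in the
##    European/African ancestral populations are fEur/fAfr;
##  * lightening (derived) alleles carry negative effects on the MM phenotype.

#' Default generator calibration for the admixed cohort
#'
#' Genome-wide African ancestry is drawn from a Beta distribution with mean
#' 0.58 and SD 0.12, truncated to [0.235, 0.879]; these targets reproduce the
#' published summary of the reference admixed cohort (median 58%, range
#' 23.5%-87.9%). The phenotype model uses a coefficient of -4.247 on
#' genome-wide European ancestry, the per-allele effects of the four major
#' skin-color loci, and a residual calibrated so that the total phenotypic
#' SD is 0.85 MM.
#'
#' @return Named list of default parameters.
#' @export
cohortDefaults <- function() {
  list(
    ancestryMean = 0.58, ancestrySD = 0.12,
    ancestryLower = 0.235, ancestryUpper = 0.879,
    gammaAnc = -4.247,
    varianceTarget = 0.85^2,
    phenotypeMean = 7.39
  )
}

#' Reference table of the four major skin-color loci
#'
#' Derived-allele frequencies in the European (CEU-like) and African
#' (YRI-like) ancestral populations, and per-allele effects (MM units per
#' derived allele) as estimated by the full regression containing all four
#' loci plus genome-wide ancestry. Effects are negative: the derived allele
#' lightens skin.
#'
#' @param effects Either \code{"architecture"} (full-model estimates: SLC24A5
#'   0.334, GRM5-TYR 0.193, APBA2 0.155, SLC45A2 0.166) or \code{"power"}
#'   (the power-model SLC24A5 coefficient 0.3459 substituted for SLC24A5).
#' @return data.frame with columns id, chrom, pos, fEur, fAfr, beta.
#' @export
skinLociTable <- function(effects = c("architecture", "power")) {
  effects <- match.arg(effects)
  tab <- data.frame(
    id    = c("SLC24A5", "GRM5_TYR", "APBA2", "SLC45A2"),
    chrom = c("15", "11", "15", "5"),
    pos   = c(48426484L, 92748735L, 29228397L, 33951693L),
    fEur  = c(1.00, 0.66, 0.85, 0.99),
    fAfr  = c(0.01, 0.10, 0.05, 0.25),
    beta  = -c(0.334, 0.193, 0.155, 0.166),
    stringsAsFactors = FALSE
  )
  if (effects == "power") tab$beta[tab$id == "SLC24A5"] <- -0.3459
  tab
}

## Solve Beta shapes from mean and SD.
betaShapes <- function(mean, sd) {
  if (sd^2 >= mean * (1 - mean))
    stop("invalid Beta parameters: sd^2 must be < mean*(1-mean)", call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Draw genome-wide African ancestry fractions
#'
#' Default family is a Beta distribution calibrated to the cohort's published
#' summary (mean 0.58, SD 0.12) truncated by rejection to [0.235, 0.879].
#'
#' @param n Number of individuals.
#' @param family \code{"beta"} (optionally truncated) or \code{"point"}
#'   (degenerate point mass at \code{mean}).
#' @param mean,sd Beta mean and SD (used unless \code{shape1}/\code{shape2}
#'   are given).
#' @param shape1,shape2 Optional explicit Beta shapes.
#' @param lower,upper Truncation bounds; use 0 and 1 for no truncation.
#' @param seed Optional integer seed.
#' @return Numeric vector of African ancestry fractions in [0, 1].
#' @export
drawAncestry <- function(n, family = c("beta", "point"),
                         mean = 0.58, sd = 0.12,
                         shape1 = NULL, shape2 = NULL,
                         lower = 0.235, upper = 0.879, seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (family == "point") {
    assertScalarNumber(mean, "mean", 0, 1)
    return(rep(mean, n))
  }
  if (is.null(shape1) || is.null(shape2)) {
    assertScalarNumber(mean, "mean", 0, 1)
    assertScalarNumber(sd, "sd", 0, 0.5)
    sh <- betaShapes(mean, sd)
    shape1 <- sh[["shape1"]]; shape2 <- sh[["shape2"]]
  }
  if (shape1 <= 0 || shape2 <= 0)
    stop("Beta shapes must be positive", call. = FALSE)
  if (lower >= upper || lower < 0 || upper > 1)
    stop("truncation bounds must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  withSeed(seed, {
    q <- rbeta(n, shape1, shape2)
    repeat {
      bad <- q < lower | q > upper
      if (!any(bad)) break
      q[bad] <- rbeta(sum(bad), shape1, shape2)
    }
    q
  })
}

#' Draw local ancestry (copies of European ancestry per locus)
#'
#' In \code{"independent"} mode each locus is drawn
#' \code{Binomial(2, 1 - q)} independently. In \code{"markov"} mode each of
#' the two haplotypes follows a two-state Markov chain along the chromosome
#' with stationary European probability \code{1 - q} and switch intensity
#' \code{switchGenerations} per Morgan: over a genetic distance d the chain
#' retains its state with probability \code{exp(-sg * d)} and otherwise
#' redraws from the stationary distribution, so \code{switchGenerations = 0}
#' degenerates to chromosome-constant ancestry per haplotype.
#'
#' @param q African ancestry fractions (one per individual).
#' @param nLoci Number of loci (independent mode, or markov with equally
#'   spaced positions when \code{positions} is NULL).
#' @param positions Genetic positions in Morgans (required monotone increasing
#'   for markov mode).
#' @param mode "independent" or "markov".
#' @param switchGenerations Ancestry-switch intensity per Morgan (roughly the
#'   number of generations since admixture).
#' @param seed Optional integer seed.
#' @return Integer matrix, individuals x loci, values in \{0, 1, 2\} counting
#'   European copies, with \code{positions} attached as an attribute.
#' @export
drawLocalAncestry <- function(q, nLoci = NULL, positions = NULL,
                              mode = c("independent", "markov"),
                              switchGenerations = 20, seed = NULL) {
  mode <- match.arg(mode)
  if (any(q < 0 | q > 1)) stop("ancestry fractions must lie in [0, 1]", call. = FALSE)
  n <- length(q)
  if (is.null(positions)) {
    if (is.null(nLoci)) stop("give 'nLoci' or 'positions'", call. = FALSE)
    positions <- seq(0, by = 0.01, length.out = nLoci)
  }
  L <- length(positions)
  if (mode == "markov" && L > 1 && any(diff(positions) <= 0))
    stop("markov mode requires strictly increasing genetic positions", call. = FALSE)
  a <- withSeed(seed, {
    if (mode == "independent") {
      matrix(rbinom(n * L, 2L, rep(1 - q, L)), n, L)
    } else {
      pEur <- 1 - q
      hap <- function() {
        h <- matrix(0L, n, L)
        h[, 1] <- rbinom(n, 1L, pEur)
        if (L > 1) for (l in 2:L) {
          d <- positions[l] - positions[l - 1]
          pKeep <- exp(-switchGenerations * d)
          redraw <- runif(n) > pKeep
          h[, l] <- ifelse(redraw, rbinom(n, 1L, pEur), h[, l - 1])
        }
        h
      }
      hap() + hap()
    }
  })
  attr(a, "positions") <- positions
  a
}

#' Draw genotypes from local ancestry and ancestral allele frequencies
#'
#' Each allele copy on a European background carries the derived allele with
#' probability \code{fEur}, and \code{fAfr} on an African background. With
#' perfectly ancestry-informative frequencies (1, 0) the genotype equals the
#' European local-ancestry count exactly.
#'
#' @param la Local-ancestry matrix (European copies, individuals x loci).
#' @param fEur,fAfr Derived-allele frequencies per locus (scalar or one per
#'   locus), each in [0, 1].
#' @param missingRate Optional fraction of entries masked to NA.
#' @param seed Optional integer seed.
#' @return Numeric matrix of derived-allele counts in \{0, 1, 2\} (NA where
#'   masked).
#' @export
drawGenotypes <- function(la, fEur, fAfr, missingRate = 0, seed = NULL) {
  L <- ncol(la); n <- nrow(la)
  fEur <- rep(fEur, length.out = L); fAfr <- rep(fAfr, length.out = L)
  if (any(fEur < 0 | fEur > 1) || any(fAfr < 0 | fAfr > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  if (any(la < 0 | la > 2)) stop("local ancestry must lie in [0, 2]", call. = FALSE)
  withSeed(seed, {
    aInt <- round(la)
    pe <- matrix(rep(fEur, each = n), n, L)
    pa <- matrix(rep(fAfr, each = n), n, L)
    G <- matrix(rbinom(n * L, aInt, pe) + rbinom(n * L, 2L - aInt, pa), n, L)
    colnames(G) <- colnames(la)
    if (missingRate > 0)
      G[matrix(runif(n * L) < missingRate, n, L)] <- NA
    G
  })
}

#' Simulate an additive phenotype with optional dominance and epistasis
#'
#' \code{Y = sum_k beta_k G_k + gammaAnc * (1 - q) + dominance + epistasis +
#' e}, with \code{e ~ N(0, sigmaResid^2)}. When \code{varianceTarget} is
#' given, \code{sigmaResid} is solved from the empirical variance of the
#' realized genetic component so that \code{var(Y)} matches the target in
#' expectation; a target smaller than the realized genetic variance is a
#' calibration error.
#'
#' @param G Genotype matrix (derived-allele counts; individuals x loci).
#' @param q African ancestry fractions.
#' @param beta Per-locus additive effects (MM units per derived allele).
#' @param gammaAnc Coefficient on genome-wide European ancestry (1 - q).
#' @param dominance Optional per-locus dominance deviations applied to the
#'   heterozygote indicator.
#' @param epistasis Optional data.frame with columns i, j, coef giving
#'   pairwise G_i * G_j interaction effects.
#' @param sigmaResid Residual SD (ignored when \code{varianceTarget} given).
#' @param varianceTarget Optional total phenotypic variance (MM^2) to
#'   calibrate to.
#' @param intercept Constant added to the phenotype (default centers nothing).
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector with attribute \code{"sigmaResid"}.
#' @export
simulatePhenotype <- function(G, q, beta, gammaAnc = 0, dominance = NULL,
                              epistasis = NULL, sigmaResid = 0,
                              varianceTarget = NULL, intercept = 0,
                              seed = NULL) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (length(q) != n) stop("'q' must have one value per individual", call. = FALSE)
  if (length(beta) != ncol(G))
    stop("one effect per locus required", call. = FALSE)
  genetic <- drop(G %*% beta) + gammaAnc * (1 - q)
  if (!is.null(dominance)) {
    if (length(dominance) != ncol(G))
      stop("one dominance deviation per locus required", call. = FALSE)
    genetic <- genetic + drop((G == 1) %*% dominance)
  }
  if (!is.null(epistasis)) {
    for (r in seq_len(nrow(epistasis)))
      genetic <- genetic +
        epistasis$coef[r] * G[, epistasis$i[r]] * G[, epistasis$j[r]]
  }
  if (!is.null(varianceTarget)) {
    s2 <- varianceTarget - var(genetic)
    if (s2 < 0)
      stop(sprintf(paste0("calibration error: variance target %.4f is smaller ",
                          "than the realized genetic variance %.4f"),
                   varianceTarget, var(genetic)), call. = FALSE)
    sigmaResid <- sqrt(s2)
  }
  y <- withSeed(seed, genetic + intercept + rnorm(n, 0, sigmaResid))
  attr(y, "sigmaResid") <- sigmaResid
  y
}

#' Simulate a complete admixed cohort
#'
#' Convenience wrapper drawing ancestry, local ancestry, genotypes and
#' phenotype in one call, returning an \code{\link{AdmixedCohort}}.
#'
#' @param n Number of individuals.
#' @param loci data.frame with columns id, fEur, fAfr, beta (and optionally
#'   chrom, pos, posM); defaults to \code{\link{skinLociTable}()}.
#' @param gammaAnc Coefficient on European ancestry (default -4.247).
#' @param varianceTarget Total phenotypic variance target (default 0.85^2).
#' @param intercept Phenotype intercept; the default places the cohort mean
#'   near the published MM mean of 7.39.
#' @param laMode Local-ancestry mode ("independent" or "markov").
#' @param switchGenerations Markov switch intensity per Morgan.
#' @param dominance,epistasis Passed to \code{\link{simulatePhenotype}}.
#' @param missingRate Genotype missingness fraction.
#' @param ancestry Optional pre-drawn ancestry vector.
#' @param seed Optional integer root seed (stage seeds derived from it).
#' @return An \code{AdmixedCohort}.
#' @export
simulateCohort <- function(n, loci = skinLociTable(), gammaAnc = -4.247,
                           varianceTarget = 0.85^2, intercept = NULL,
                           laMode = "independent", switchGenerations = 20,
                           dominance = NULL, epistasis = NULL,
                           missingRate = 0, ancestry = NULL, seed = NULL) {
  defaults <- cohortDefaults()
  q <- ancestry %||% drawAncestry(n, seed = deriveSeed(seed, 1))
  positions <- if ("posM" %in% names(loci)) loci$posM else NULL
  la <- drawLocalAncestry(q, nLoci = nrow(loci), positions = positions,
                          mode = laMode, switchGenerations = switchGenerations,
                          seed = deriveSeed(seed, 2))
  colnames(la) <- loci$id
  G <- drawGenotypes(la, loci$fEur, loci$fAfr, missingRate = missingRate,
                     seed = deriveSeed(seed, 3))
  colnames(G) <- loci$id
  Gc <- G; Gc[is.na(Gc)] <- 0  # phenotype built on complete genotypes
  if (is.null(intercept))
    intercept <- defaults$phenotypeMean -
      mean(drop(Gc %*% loci$beta) + gammaAnc * (1 - q))
  y <- simulatePhenotype(Gc, q, loci$beta, gammaAnc = gammaAnc,
                         dominance = dominance, epistasis = epistasis,
                         varianceTarget = varianceTarget,
                         intercept = intercept, seed = deriveSeed(seed, 4))
  meta <- list(seed = seed, gammaAnc = gammaAnc,
               varianceTarget = varianceTarget, intercept = intercept,
               sigmaResid = attr(y, "sigmaResid"), laMode = laMode,
               switchGenerations = switchGenerations)
  new("AdmixedCohort", ancestry = q, localAncestry = la, genotypes = G,
      phenotype = as.numeric(y), loci = as.data.frame(loci), metadata = meta)
}

#' Three-locus ancestry-correlation simulation
#'
#' Simulates phenotypes under a genetic architecture with three unlinked,
#' perfectly ancestry-informative loci of equal per-allele effect, no direct
#' genome-wide ancestry effect, and residual noise independent of genotype
#' and ancestry calibrated so the total variance matches the cohort's
#' phenotypic variance. Returns the per-replicate Pearson correlation between
#' African ancestry and phenotype (and its square), quantifying how much
#' ancestry-phenotype correlation a few-gene architecture can induce through
#' admixture stratification alone.
#'
#' @param n Individuals per replicate (default 685).
#' @param reps Number of replicates (default 1000).
#' @param perAlleleEffect Per-allele lightening effect magnitude in MM units
#'   (default 0.334, the full-model SLC24A5 estimate; 0.3459 is the
#'   power-model alternative).
#' @param varianceTarget Total phenotypic variance (default 0.85^2).
#' @param seed Optional integer seed.
#' @return data.frame with columns replicate, r, rsq.
#' @export
threeLocusAncestrySim <- function(n = 685, reps = 1000,
                                  perAlleleEffect = 0.334,
                                  varianceTarget = 0.85^2, seed = NULL) {
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  withSeed(seed, {
    r <- vapply(seq_len(reps), function(i) {
      q <- drawAncestry(n)
      G <- matrix(rbinom(3L * n, 2L, 1 - q), n, 3)  # freqs (1, 0): G = a
      y <- simulatePhenotype(G, q, beta = rep(-perAlleleEffect, 3),
                             gammaAnc = 0, varianceTarget = varianceTarget)
      cor(q, y)
    }, numeric(1))
    data.frame(replicate = seq_len(reps), r = r, rsq = r^2)
  })
}

#' Synthetic reflectance panel
#'
#' Generates six 650 nm reflectance readings per individual (three per arm)
#' whose implied melanin-index values are \code{trueM} plus Gaussian noise,
#' with occasional gross outliers (large positive M offsets) at rate
#' \code{outlierProb}. Readings whose implied reflectance would leave (0, 1]
#' are resampled; the number of resamples is recorded in the
#' \code{"resampled"} attribute.
#'
#' @param trueM True melanin-index values (>= 0), one per individual.
#' @param noiseSD SD of the Gaussian measurement noise on the M scale.
#' @param outlierProb Per-reading probability of a gross outlier.
#' @param outlierShift Range (min, max) of the uniform positive M offset
#'   applied to outlier readings.
#' @param seed Optional integer seed.
#' @return Numeric matrix n x 6 of reflectance fractions in (0, 1], with
#'   attribute \code{"M"} holding the noisy M values.
#' @export
synthReflectance <- function(trueM, noiseSD = 0, outlierProb = 0,
                             outlierShift = c(150, 450), seed = NULL) {
  if (any(trueM < 0)) stop("'trueM' must be non-negative", call. = FALSE)
  n <- length(trueM)
  withSeed(seed, {
    M <- matrix(NA_real_, n, 6)
    resampled <- 0L
    for (j in 1:6) {
      m <- trueM + rnorm(n, 0, noiseSD)
      out <- runif(n) < outlierProb
      m[out] <- m[out] + runif(sum(out), outlierShift[1], outlierShift[2])
      bad <- m < 0  # implied reflectance > 1
      while (any(bad)) {
        resampled <- resampled + sum(bad)
        m[bad] <- trueM[bad] + rnorm(sum(bad), 0, noiseSD)
        bad <- m < 0
      }
      M[, j] <- m
    }
    refl <- 10^(-M / 100)
    if (resampled > 0)
      warning(sprintf("%d readings resampled to keep reflectance in (0, 1]",
                      resampled))
    attr(refl, "M") <- M
    attr(refl, "resampled") <- resampled
    refl
  })
}
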