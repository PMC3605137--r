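## Population-attributable variance (PAV) decomposition and non-additivity
## checks. All variances here are population (1/n) variances so small toy
## tables reproduce exactly.

#' Fit the full phenotype model (major loci + ancestry + covariates)
#'
#' Ordinary least squares of Y on the genotypes of the major loci, the
#' genome-wide ancestry fraction, and any extra covariates. Aliased
#' (collinear) columns are an error naming the offending terms, because PAV
#' requires every beta to be estimable.
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix of the major loci (columns named).
#' @param ancestry Optional genome-wide ancestry fractions (African q; the
#'   model uses q directly, sign conventions cancel in variance terms).
#' @param covariates Optional covariate matrix.
#' @return List with \code{betas} (named per-locus effects), \code{table}
#'   (coefficient summary), \code{r2}, and the \code{lm} \code{fit}.
#' @export
fitFullModel <- function(Y, G, ancestry = NULL, covariates = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("locus", seq_len(ncol(G)))
  df <- data.frame(Y = Y, G, check.names = FALSE)
  if (!is.null(ancestry)) df$.ancestry <- ancestry
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    df <- cbind(df, covariates)
  }
  fit <- lm(Y ~ ., data = df)
  co <- coef(fit)
  if (anyNA(co))
    stop("collinear model terms: ", paste(names(co)[is.na(co)], collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)
  list(betas = co[colnames(G)],
       ancestryCoef = if (is.null(ancestry)) NA_real_ else co[[".ancestry"]],
       table = as.data.frame(sm$coefficients),
       r2 = sm$r.squared,
       fit = fit)
}

#' Population-attributable variance of a locus set
#'
#' The fractional reduction in phenotypic variance that would occur if the
#' genotypes of the loci in \code{lociSet} were set to a common baseline in
#' every individual, holding the fitted effects fixed:
#' \code{PAV = [var(Y) - var(Y - sum_k beta_k G_k)] / var(Y)}. The choice of
#' baseline is irrelevant because only variances of the adjusted phenotype
#' enter.
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix (columns named).
#' @param betas Named per-locus effects, typically from
#'   \code{\link{fitFullModel}}.
#' @param lociSet Locus names (default: all columns of G with a beta).
#' @return Scalar PAV (fraction of var(Y)).
#' @export
pav <- function(Y, G, betas, lociSet = NULL) {
  G <- as.matrix(G)
  vy <- popVar(Y)
  if (vy == 0) stop("var(Y) is zero", call. = FALSE)
  lociSet <- lociSet %||% intersect(colnames(G), names(betas))
  if (!all(lociSet %in% colnames(G)) || !all(lociSet %in% names(betas)))
    stop("'lociSet' must name columns of G with matching betas", call. = FALSE)
  yAdj <- Y - drop(G[, lociSet, drop = FALSE] %*% betas[lociSet])
  (vy - popVar(yAdj)) / vy
}

#' Overlap decomposition of two variance components
#'
#' Inclusion-exclusion on population-attributable variances (or the ancestry
#' R-squared standing in for the ancestry component):
#' \code{overlap = pavA + pavB - pavCombined};
#' \code{uniqueA = pavCombined - pavB}; \code{uniqueB = pavCombined - pavA}.
#' A negative overlap beyond \code{tol} indicates inconsistent inputs and is
#' flagged.
#'
#' @param pavA,pavB Component variance fractions sharing the same Y.
#' @param pavCombined Variance fraction of both components jointly.
#' @param tol Consistency tolerance.
#' @return List with overlap, uniqueA, uniqueB, and \code{consistent}.
#' @export
pavOverlap <- function(pavA, pavB, pavCombined, tol = 1e-8) {
  overlap <- pavA + pavB - pavCombined
  list(overlap = overlap,
       uniqueA = pavCombined - pavB,
       uniqueB = pavCombined - pavA,
       consistent = overlap >= -tol)
}

#' Variance uniquely attributable to one locus
#'
#' Compares the residual sum of squares of the full regression (all loci,
#' ancestry, covariates) to the reduced model without the locus of
#' interest: \code{(RSS_reduced - RSS_full) / (n * var(Y))} with the
#' population variance of Y in the denominator.
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix of all major loci.
#' @param locus Name of the locus of interest.
#' @param ancestry,covariates As in \code{\link{fitFullModel}}.
#' @return Scalar unique variance fraction.
#' @export
uniqueContribution <- function(Y, G, locus, ancestry = NULL,
                               covariates = NULL) {
  G <- as.matrix(G)
  if (!locus %in% colnames(G)) stop("unknown locus: ", locus, call. = FALSE)
  full <- cbind(1, G, ancestry, covariates)
  red <- cbind(1, G[, setdiff(colnames(G), locus), drop = FALSE],
               ancestry, covariates)
  rssFull <- sum(qr.resid(qr(full), Y)^2)
  rssRed <- sum(qr.resid(qr(red), Y)^2)
  (rssRed - rssFull) / (length(Y) * popVar(Y))
}

#' Dominance and epistasis checks for the major loci
#'
#' Dominance: the additive model is augmented, one locus at a time, with the
#' heterozygote indicator; its coefficient and two-sided p-value quantify
#' the dominance deviation. Epistasis: for each pair of loci the additive
#' model gains a G_j * G_k product term. Loci without heterozygotes are
#' skipped with a status.
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix of the major loci (columns named).
#' @param ancestry,covariates Adjustment terms.
#' @return List with \code{dominance} and \code{epistasis} data.frames.
#' @export
dominanceEpistasisTests <- function(Y, G, ancestry = NULL, covariates = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("locus", seq_len(ncol(G)))
  base <- cbind(1, G, ancestry, covariates)
  testTerm <- function(extra) {
    X <- cbind(base, extra)
    fit <- lm.fit(X, Y)
    if (fit$rank < ncol(X)) return(c(NA_real_, NA_real_, NA_real_))
    rss <- sum(fit$residuals^2)
    dfr <- length(Y) - ncol(X)
    XtXinv <- chol2inv(qr.R(fit$qr))
    b <- fit$coefficients[ncol(X)]
    s <- sqrt(rss / dfr * XtXinv[ncol(X), ncol(X)])
    c(b, s, 2 * pt(abs(b / s), dfr, lower.tail = FALSE))
  }
  dom <- lapply(colnames(G), function(nm) {
    het <- as.numeric(G[, nm] == 1)
    if (sum(het, na.rm = TRUE) == 0)
      return(data.frame(id = nm, estimate = NA, se = NA, p = NA,
                        status = "no_heterozygotes"))
    r <- testTerm(het)
    data.frame(id = nm, estimate = r[1], se = r[2], p = r[3], status = "ok")
  })
  prs <- utils::combn(colnames(G), 2, simplify = FALSE)
  epi <- lapply(prs, function(pr) {
    r <- testTerm(G[, pr[1]] * G[, pr[2]])
    data.frame(i = pr[1], j = pr[2], estimate = r[1], se = r[2], p = r[3],
               status = if (anyNA(r)) "aliased" else "ok")
  })
  list(dominance = do.call(rbind, dom), epistasis = do.call(rbind, epi))
}

#' Full population-attributable variance report
#'
#' Fits the full model (major loci + ancestry + covariates), computes
#' per-locus and joint PAVs with the fitted effects, the ancestry R-squared
#' and combined-model R-squared, the loci/ancestry overlap decomposition,
#' per-locus unique contributions, and the missing-heritability panel at an
#' assumed narrow-sense heritability.
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix of the major loci.
#' @param ancestry Genome-wide African ancestry fractions.
#' @param covariates Optional covariates.
#' @param h2 Assumed heritability for the missing-heritability panel
#'   (default 0.8).
#' @param fixedBetas Optional named effects to use instead of the full-model
#'   estimates (sensitivity analysis).
#' @return A \code{\link{PAVReport}}.
#' @export
pavReport <- function(Y, G, ancestry, covariates = NULL, h2 = 0.8,
                      fixedBetas = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("locus", seq_len(ncol(G)))
  full <- fitFullModel(Y, G, ancestry = ancestry, covariates = covariates)
  betas <- fixedBetas %||% full$betas
  perLocus <- data.frame(
    id = colnames(G),
    beta = as.numeric(betas[colnames(G)]),
    pav = vapply(colnames(G), function(nm) pav(Y, G, betas, nm), numeric(1)),
    unique = vapply(colnames(G), function(nm)
      uniqueContribution(Y, G, nm, ancestry, covariates), numeric(1)),
    row.names = NULL
  )
  joint <- pav(Y, G, betas)
  ancR2 <- summary(lm(Y ~ ancestry))$r.squared
  combR2 <- full$r2
  ov <- pavOverlap(joint, ancR2, combR2)
  new("PAVReport",
      perLocus = perLocus, jointPAV = joint, ancestryR2 = ancR2,
      combinedR2 = combR2, overlap = ov, h2Assumed = h2,
      missingHeritability = max(0, h2 - combR2))
}
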