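## Genotype-, ancestry-based and conditional association scans.

#' Principal components of a genotype matrix
#'
#' EIGENSTRAT-style PCA: loci with minor allele frequency below
#' \code{mafMin} are dropped, missing genotypes are mean-imputed per locus,
#' each locus is centered and standardized by \code{sqrt(2 p (1 - p))} with p
#' the sample allele frequency, and the top K left singular vectors of the
#' standardized matrix are returned as individual scores.
#'
#' @param G Genotype matrix (individuals x loci, 0/1/2 with NA allowed).
#' @param K Number of components.
#' @param mafMin MAF filter applied before standardization.
#' @return Numeric matrix n x K of component scores (columns PC1..PCK).
#' @export
computePCs <- function(G, K = 3, mafMin = 0.01) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (K >= n) stop("'K' must be smaller than the sample size", call. = FALSE)
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= mafMin
  if (!any(keep)) stop("no loci pass the MAF filter", call. = FALSE)
  X <- G[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- 2 * p[j]
    X[, j] <- (x - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  if (all(apply(X, 2, function(col) all(col == col[1]))))
    stop("zero variance: all individuals identical after standardization",
         call. = FALSE)
  sv <- svd(X, nu = K, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(K)], K)
  colnames(scores) <- paste0("PC", seq_len(K))
  scores
}

#' Assemble a covariate design matrix
#'
#' Binds the supplied covariates (sex, principal components, conditioning
#' genotypes, genome-wide ancestry...) into a single matrix and checks for
#' rank deficiency.
#'
#' @param ... Vectors or matrices of covariates (NULL entries skipped).
#' @return Numeric covariate matrix (possibly with 0 columns).
#' @export
covariateSet <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  if (!length(parts)) return(matrix(numeric(0), 0, 0))
  C <- do.call(cbind, parts)
  C <- as.matrix(C)
  if (qr(cbind(1, C))$rank < ncol(C) + 1L)
    stop("covariate set is rank deficient", call. = FALSE)
  C
}

## Core per-locus OLS scan of Y on each column of X, adjusting for
## covariates C (with intercept). Uses Frisch-Waugh residualization for the
## complete-data fast path; loci with missing values fall back to a
## per-locus complete-case fit.
scanCore <- function(Y, X, C = NULL, mafIsGenotype = TRUE, mafMin = 0) {
  X <- as.matrix(X)
  n <- length(Y)
  L <- ncol(X)
  C1 <- if (is.null(C) || ncol(as.matrix(C)) == 0)
    matrix(1, n, 1) else cbind(1, as.matrix(C))
  p <- ncol(C1)
  beta <- se <- pval <- maf <- rep(NA_real_, L)
  status <- rep("ok", L)

  qrC <- qr(C1)
  Yr <- qr.resid(qrC, Y)
  df <- n - p - 1L

  freq <- colMeans(X, na.rm = TRUE) / 2
  maf <- if (mafIsGenotype) pmin(freq, 1 - freq) else NA_real_

  for (j in seq_len(L)) {
    x <- X[, j]
    if (mafIsGenotype && !is.na(maf[j]) && maf[j] < mafMin) {
      status[j] <- "low_maf"; next
    }
    if (anyNA(x)) {
      cc <- !is.na(x)
      if (sum(cc) <= p + 1L) { status[j] <- "zero_variance"; next }
      Xd <- cbind(C1[cc, , drop = FALSE], x[cc])
      fit <- lm.fit(Xd, Y[cc])
      if (fit$rank < ncol(Xd) || is.na(fit$coefficients[ncol(Xd)])) {
        status[j] <- if (var(x[cc]) == 0) "zero_variance" else "aliased"
        next
      }
      rss <- sum(fit$residuals^2)
      dfj <- sum(cc) - ncol(Xd)
      XtXinv <- chol2inv(qr.R(fit$qr))
      b <- fit$coefficients[ncol(Xd)]
      s <- sqrt(rss / dfj * XtXinv[ncol(Xd), ncol(Xd)])
      beta[j] <- b; se[j] <- s
      pval[j] <- 2 * pt(abs(b / s), dfj, lower.tail = FALSE)
      next
    }
    if (var(x) == 0) { status[j] <- "zero_variance"; next }
    xr <- qr.resid(qrC, x)
    sxx <- sum(xr^2)
    if (sxx < 1e-10 * sum((x - mean(x))^2)) { status[j] <- "aliased"; next }
    b <- sum(xr * Yr) / sxx
    rss <- sum(Yr^2) - b^2 * sxx
    s <- sqrt(rss / df / sxx)
    beta[j] <- b; se[j] <- s
    pval[j] <- 2 * pt(abs(b / s), df, lower.tail = FALSE)
  }
  data.frame(BETA = beta, SE = se, P = pval, MAF = maf, STATUS = status,
             stringsAsFactors = FALSE)
}

.lociMeta <- function(X, loci = NULL) {
  L <- ncol(X)
  ids <- colnames(X) %||% paste0("locus", seq_len(L))
  if (is.null(loci))
    return(data.frame(ID = ids, CHROM = NA_character_, POS = NA_integer_,
                      stringsAsFactors = FALSE))
  data.frame(ID = loci$id %||% ids,
             CHROM = as.character(loci$chrom %||% NA),
             POS = loci$pos %||% NA_integer_, stringsAsFactors = FALSE)
}

.makeScan <- function(Y, X, covariates, loci, mafIsGenotype, mafMin,
                      threshold, predictor) {
  res <- scanCore(Y, X, covariates, mafIsGenotype = mafIsGenotype,
                  mafMin = mafMin)
  tab <- cbind(.lociMeta(X, loci), res)
  ok <- !is.na(tab$P)
  lambda <- if (sum(ok) >= 1)
    median(qchisq(tab$P[ok], df = 1, lower.tail = FALSE)) /
      qchisq(0.5, df = 1) else NA_real_
  new("AssocScan", table = tab, lambda = as.numeric(lambda),
      threshold = threshold, predictor = predictor)
}

#' Genotype-based genome-wide association scan
#'
#' Per-locus ordinary least squares of the phenotype on the derived-allele
#' count (additive coding 0/1/2), adjusting for the supplied covariates;
#' two-sided t-test on the genotype coefficient with residual degrees of
#' freedom. Loci below the MAF filter, with zero variance, or collinear with
#' the covariates are flagged in STATUS and carry NA p-values.
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix (individuals x loci; NA = missing, handled by
#'   per-locus complete-case fits).
#' @param covariates Optional covariate matrix (see
#'   \code{\link{covariateSet}}).
#' @param mafMin Minor-allele-frequency filter (default 0.01).
#' @param threshold Genome-wide significance threshold (default 5.7e-8).
#' @param loci Optional per-locus annotation data.frame (id, chrom, pos).
#' @return An \code{\link{AssocScan}}.
#' @export
gwasScan <- function(Y, G, covariates = NULL, mafMin = 0.01,
                     threshold = 5.7e-8, loci = NULL) {
  .makeScan(Y, as.matrix(G), covariates, loci, mafIsGenotype = TRUE,
            mafMin = mafMin, threshold = threshold, predictor = "genotype")
}

#' Local-ancestry (admixture-mapping) association scan
#'
#' As \code{\link{gwasScan}} but with the European local-ancestry dosage as
#' the per-locus predictor and the admixture-mapping genome-wide threshold
#' (default 7e-6). No MAF filter applies; constant-dosage loci are skipped.
#'
#' @param Y Phenotype vector.
#' @param la Local-ancestry dosage matrix (individuals x loci, values in
#'   [0, 2]).
#' @param covariates Optional covariate matrix.
#' @param threshold Genome-wide significance threshold.
#' @param loci Optional per-locus annotation.
#' @return An \code{\link{AssocScan}}.
#' @export
ancestryScan <- function(Y, la, covariates = NULL, threshold = 7e-6,
                         loci = NULL) {
  .makeScan(Y, as.matrix(la), covariates, loci, mafIsGenotype = FALSE,
            mafMin = 0, threshold = threshold, predictor = "ancestry")
}

#' Conditional association scan
#'
#' Re-runs the genotype scan with the genotypes of the index loci appended
#' to the covariates. An index locus tested against itself is aliased and
#' reported with STATUS "aliased" (p = NA).
#'
#' @param Y Phenotype vector.
#' @param G Genotype matrix.
#' @param indexLoci Column names or indices of the conditioning loci.
#' @param covariates Optional covariate matrix.
#' @param ... Passed to \code{\link{gwasScan}}.
#' @return An \code{\link{AssocScan}}.
#' @export
conditionalScan <- function(Y, G, indexLoci, covariates = NULL, ...) {
  G <- as.matrix(G)
  idx <- if (is.character(indexLoci)) match(indexLoci, colnames(G)) else indexLoci
  if (anyNA(idx)) stop("index loci not found in the genotype matrix",
                       call. = FALSE)
  cond <- G[, idx, drop = FALSE]
  if (anyNA(cond)) {
    # mean-impute conditioning genotypes so the covariate set stays complete
    for (j in seq_len(ncol(cond)))
      cond[is.na(cond[, j]), j] <- mean(cond[, j], na.rm = TRUE)
  }
  covariates <- if (is.null(covariates)) cond else cbind(covariates, cond)
  gwasScan(Y, G, covariates = covariates, ...)
}

#' Genomic-control inflation factor
#'
#' Converts two-sided p-values to 1-df chi-square quantiles and reports the
#' median divided by its null expectation (0.4549...). Loci inside the
#' supplied exclusion windows (e.g. around detected peaks) are removed
#' first.
#'
#' @param p Vector of p-values (at least 100 after exclusion).
#' @param exclude Optional logical or integer index of p-values to exclude.
#' @return Scalar lambda.
#' @export
genomicControl <- function(p, exclude = NULL) {
  if (!is.null(exclude)) p <- if (is.logical(exclude)) p[!exclude] else p[-exclude]
  p <- p[!is.na(p)]
  if (length(p) < 100)
    stop("need at least 100 p-values after exclusions", call. = FALSE)
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Candidate-SNP-set q-q comparison
#'
#' For each named candidate set, returns the sorted -log10 p-values and
#' two-sample Kolmogorov-Smirnov p-values comparing the candidate set with a
#' random background of loci spaced at least \code{spacing} apart, both for
#' the association p-values and for the minor allele frequencies.
#'
#' @param scan An \code{\link{AssocScan}} whose table carries POS (used for
#'   spacing the background) and MAF.
#' @param sets Named list of character vectors of locus IDs.
#' @param spacing Minimum distance between background loci (same units as
#'   POS; default 1e6).
#' @param seed Optional integer seed for the random background start.
#' @return List with \code{background} (IDs) and per-set entries
#'   (\code{logp} sorted decreasing, \code{ksP}, \code{ksMAF}, \code{status}).
#' @export
candidateSetQQ <- function(scan, sets, spacing = 1e6, seed = NULL) {
  tab <- scanTable(scan)
  tab <- tab[!is.na(tab$P), , drop = FALSE]
  candidateIDs <- unique(unlist(sets))
  pool <- tab[!(tab$ID %in% candidateIDs), , drop = FALSE]
  bg <- withSeed(seed, {
    if (all(is.na(pool$POS))) {
      pool[sample(nrow(pool), min(nrow(pool), 500)), , drop = FALSE]
    } else {
      ord <- pool[order(pool$CHROM, pool$POS), , drop = FALSE]
      keep <- logical(nrow(ord))
      lastPos <- -Inf; lastChrom <- ""
      start <- sample(seq_len(max(1, min(10, nrow(ord)))), 1)
      for (i in start:nrow(ord)) {
        if (!identical(ord$CHROM[i], lastChrom) ||
            ord$POS[i] - lastPos >= spacing) {
          keep[i] <- TRUE
          lastPos <- ord$POS[i]; lastChrom <- ord$CHROM[i]
        }
      }
      ord[keep, , drop = FALSE]
    }
  })
  out <- list(background = list(ids = bg$ID,
                                logp = sort(-log10(bg$P), decreasing = TRUE)))
  for (nm in names(sets)) {
    sub <- tab[tab$ID %in% sets[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[nm]] <- list(status = "empty")
      next
    }
    ksP <- suppressWarnings(ks.test(sub$P, bg$P)$p.value)
    ksMAF <- if (all(is.na(sub$MAF)) || all(is.na(bg$MAF))) NA_real_ else
      suppressWarnings(ks.test(sub$MAF, bg$MAF)$p.value)
    out[[nm]] <- list(status = "ok",
                      logp = sort(-log10(sub$P), decreasing = TRUE),
                      ksP = ksP, ksMAF = ksMAF)
  }
  out
}
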