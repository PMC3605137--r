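makeStratifiedCohort <- function(n = 400, L = 60, seed = 1,
                                 eurRange = c(0.5, 1), afrRange = c(0, 0.5)) {
  q <- drawAncestry(n, seed = seed)
  la <- drawLocalAncestry(q, nLoci = L, seed = seed + 1)
  fEur <- withr::with_seed(seed + 2, runif(L, eurRange[1], eurRange[2]))
  fAfr <- withr::with_seed(seed + 3, runif(L, afrRange[1], afrRange[2]))
  G <- drawGenotypes(la, fEur, fAfr, seed = seed + 4)
  colnames(G) <- sprintf("snp%03d", seq_len(L))
  list(q = q, la = la, G = G)
}

test_that("PCA scores match a dense eigendecomposition and track ancestry", {
  # a dense panel of strong ancestry-informative markers, so PC1 should be
  # nearly identical to genome-wide ancestry
  cc <- makeStratifiedCohort(n = 250, L = 400, seed = 11,
                             eurRange = c(0.85, 1), afrRange = c(0, 0.15))
  pcs <- computePCs(cc$G, K = 3)
  expect_gt(abs(cor(pcs[, 1], cc$q)), 0.95)
  # oracle: eigenvectors of the standardized covariance, small matrix
  p <- colMeans(cc$G) / 2
  X <- scale(cc$G, center = 2 * p, scale = sqrt(2 * p * (1 - p)))
  ev <- eigen(tcrossprod(X))
  for (k in 1:3) {
    sc <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_lt(min(sum((pcs[, k] - sc)^2), sum((pcs[, k] + sc)^2)) /
                sum(sc^2), 1e-8)
  }
  expect_error(computePCs(cc$G, K = nrow(cc$G)), "sample size")
  expect_error(computePCs(matrix(1, 10, 5), K = 2), "MAF|variance")
})

test_that("per-locus OLS equals the normal-equation oracle", {
  cc <- makeStratifiedCohort(n = 120, L = 10, seed = 21)
  y <- withr::with_seed(22, 7 - 0.3 * cc$G[, 4] - 2 * (1 - cc$q) +
                          rnorm(120, 0, 0.5))
  scan <- gwasScan(y, cc$G, covariates = cbind(q = cc$q), mafMin = 0)
  tab <- scanTable(scan)
  for (j in seq_len(10)) {
    o <- oracleOLS(cbind(cc$q, cc$G[, j]), y)
    expect_equal(tab$BETA[j], unname(o$beta[3]), tolerance = 1e-10)
    expect_equal(tab$SE[j], unname(o$se[3]), tolerance = 1e-10)
    expect_equal(tab$P[j], unname(o$p[3]), tolerance = 1e-10)
  }
  # missing-genotype path: per-locus complete-case equals the oracle on the
  # complete cases
  Gm <- cc$G
  Gm[c(3, 50, 77), 4] <- NA
  scanM <- gwasScan(y, Gm, covariates = cbind(q = cc$q), mafMin = 0)
  ccases <- !is.na(Gm[, 4])
  o <- oracleOLS(cbind(cc$q[ccases], Gm[ccases, 4]), y[ccases])
  expect_equal(scanTable(scanM)$BETA[4], unname(o$beta[3]), tolerance = 1e-10)
  expect_equal(scanTable(scanM)$P[4], unname(o$p[3]), tolerance = 1e-10)
})

test_that("scan statuses flag filtered, constant and aliased loci", {
  n <- 100
  G <- cbind(rare = c(1, rep(0, n - 1)),
             mono = rep(1, n),
             dup = rep(c(0, 1, 2), length.out = n),
             ok = rep(c(0, 1, 2, 1), length.out = n))
  y <- rnorm(n)
  scan <- gwasScan(y, G, covariates = cbind(G[, "dup"]), mafMin = 0.01)
  st <- scanTable(scan)$STATUS
  names(st) <- scanTable(scan)$ID
  expect_equal(unname(st["rare"]), "low_maf")
  expect_equal(unname(st["mono"]), "zero_variance")
  expect_equal(unname(st["dup"]), "aliased")
  expect_equal(unname(st["ok"]), "ok")
})

test_that("null scans are calibrated at nominal type-I levels", {
  # pool several independent null phenotypes so the shared-phenotype
  # correlation between per-locus tests does not distort the binomial error
  n <- 300; L <- 500; B <- 5
  p <- unlist(lapply(seq_len(B), function(b) {
    withr::with_seed(30 + b, {
      G <- matrix(rbinom(n * L, 2, 0.3), n, L)
      y <- rnorm(n)
    })
    scanTable(gwasScan(y, G, mafMin = 0))$P
  }))
  for (alpha in c(0.05, 0.01, 5e-4)) {
    se <- sqrt(alpha * (1 - alpha) / length(p))
    expect_lt(abs(mean(p < alpha) - alpha), 3.5 * se + 1e-12)
  }
  lambda <- genomicControl(p)
  expect_gt(lambda, 0.9)
  expect_lt(lambda, 1.1)
})

test_that("a simulated causal locus is the top hit with the right sign", {
  cc <- makeStratifiedCohort(n = 500, L = 40, seed = 41)
  y <- withr::with_seed(42, 7 - 0.6 * cc$G[, 17] + rnorm(500, 0, 0.6))
  scan <- gwasScan(y, cc$G, covariates = cbind(cc$q), mafMin = 0)
  tab <- scanTable(scan)
  expect_equal(which.min(tab$P), 17L)
  expect_lt(tab$BETA[17], 0)   # lightening allele keeps its negative sign
  # adding pure-noise covariates barely moves the signal
  noise <- withr::with_seed(43, matrix(rnorm(500 * 3), 500, 3))
  scan2 <- gwasScan(y, cc$G, covariates = cbind(cc$q, noise), mafMin = 0)
  lp1 <- -log10(scanTable(scan)$P[17])
  lp2 <- -log10(scanTable(scan2)$P[17])
  expect_lt(abs(lp2 - lp1) / lp1, 0.10)
})

test_that("ancestry scan equals the genotype scan at perfectly informative loci", {
  q <- drawAncestry(300, seed = 51)
  la <- drawLocalAncestry(q, nLoci = 5, seed = 52)
  G <- drawGenotypes(la, 1, 0, seed = 53)
  y <- withr::with_seed(54, 7 - 0.4 * la[, 2] + rnorm(300, 0, 0.7))
  sG <- gwasScan(y, G, covariates = cbind(q), mafMin = 0)
  sA <- ancestryScan(y, la, covariates = cbind(q))
  expect_equal(scanTable(sA)$BETA, scanTable(sG)$BETA, tolerance = 1e-12)
  expect_equal(scanTable(sA)$P, scanTable(sG)$P, tolerance = 1e-12)
  # constant dosage is skipped
  la2 <- cbind(la, const = 2)
  sA2 <- ancestryScan(y, la2, covariates = cbind(q))
  expect_equal(tail(scanTable(sA2)$STATUS, 1), "zero_variance")
})

test_that("ancestry-scan p-values are uniform under the null", {
  q <- drawAncestry(400, seed = 55)
  la <- drawLocalAncestry(q, nLoci = 300, seed = 56)
  y <- withr::with_seed(57, rnorm(400))
  sA <- ancestryScan(y, la, covariates = cbind(q))
  ks <- suppressWarnings(ks.test(scanTable(sA)$P, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ancestry peaks are broader than genotype peaks under linked ancestry", {
  n <- 600; L <- 81
  positions <- seq(0, 0.8, length.out = L)
  q <- drawAncestry(n, seed = 61)
  la <- drawLocalAncestry(q, positions = positions, mode = "markov",
                          switchGenerations = 20, seed = 62)
  # causal locus in the middle, perfectly ancestry informative
  G <- drawGenotypes(la, fEur = 1, fAfr = 0, seed = 63)
  causal <- 41L
  y <- withr::with_seed(64, 7 - 0.5 * G[, causal] + rnorm(n, 0.7))
  sG <- gwasScan(y, G, covariates = cbind(q), mafMin = 0)
  sA <- ancestryScan(y, la, covariates = cbind(q))
  width <- function(scan) {
    lp <- -log10(scanTable(scan)$P)
    sum(lp >= max(lp, na.rm = TRUE) / 2, na.rm = TRUE)
  }
  # half-maximum width: ancestry dosage is locally smooth, genotype adds
  # allele-frequency noise, so the ancestry peak spans at least as many loci
  expect_gte(width(sA), width(sG))
  peakA <- which.min(scanTable(sA)$P)
  expect_lt(abs(peakA - causal), 15)
})

test_that("conditional scans remove and reveal signals as constructed", {
  cc <- makeStratifiedCohort(n = 500, L = 30, seed = 71)
  y <- withr::with_seed(72, 7 - 0.5 * cc$G[, 5] - 0.45 * cc$G[, 20] +
                          rnorm(500, 0, 0.6))
  thr <- 1e-6
  base <- gwasScan(y, cc$G, covariates = cbind(cc$q), mafMin = 0,
                   threshold = thr)
  # conditioning on one causal locus leaves the other significant
  c1 <- conditionalScan(y, cc$G, indexLoci = "snp005",
                        covariates = cbind(cc$q), mafMin = 0, threshold = thr)
  t1 <- scanTable(c1)
  expect_equal(t1$STATUS[5], "aliased")
  expect_lt(t1$P[20], thr)
  # conditioning on both: nothing else passes
  c2 <- conditionalScan(y, cc$G, indexLoci = c("snp005", "snp020"),
                        covariates = cbind(cc$q), mafMin = 0, threshold = thr)
  expect_equal(nrow(significantLoci(c2)), 0L)
  # conditioning on a null locus leaves the causal -log10 p within noise
  c3 <- conditionalScan(y, cc$G, indexLoci = "snp012",
                        covariates = cbind(cc$q), mafMin = 0, threshold = thr)
  lp0 <- -log10(scanTable(base)$P[5])
  lp3 <- -log10(scanTable(c3)$P[5])
  expect_lt(abs(lp3 - lp0) / lp0, 0.15)
})

test_that("genomic control is calibrated and detects stratification", {
  withr::with_seed(81, {
    p <- pchisq(rchisq(1e5, 1), 1, lower.tail = FALSE)
    expect_gt(genomicControl(p), 0.95)
    expect_lt(genomicControl(p), 1.05)
  })
  expect_equal(genomicControl(rep(0.5, 200)), 1)
  expect_error(genomicControl(runif(50)), "100")
  # stratified phenotype: unadjusted scan inflates, PC adjustment restores
  cc <- makeStratifiedCohort(n = 400, L = 400, seed = 82)
  y <- withr::with_seed(83, 7 - 3 * (1 - cc$q) + rnorm(400, 0, 0.8))
  lambdaRaw <- gcLambda(gwasScan(y, cc$G, mafMin = 0))
  pcs <- computePCs(cc$G, K = 3)
  lambdaAdj <- gcLambda(gwasScan(y, cc$G, covariates = pcs, mafMin = 0))
  expect_gt(lambdaRaw, 1.1)
  expect_gt(lambdaAdj, 0.9)
  expect_lt(lambdaAdj, 1.1)
})

test_that("candidate-set q-q comparison is exchangeable under the null", {
  n <- 250; L <- 600
  withr::with_seed(91, {
    G <- matrix(rbinom(n * L, 2, 0.3), n, L)
    colnames(G) <- sprintf("s%04d", seq_len(L))
    y <- rnorm(n)
  })
  loci <- data.frame(id = colnames(G), chrom = "1",
                     pos = seq(1, by = 5e5, length.out = L))
  scan <- gwasScan(y, G, mafMin = 0, loci = loci)
  # many random candidate subsets of null loci: KS rarely rejects
  rej <- withr::with_seed(92, vapply(1:60, function(i) {
    sets <- list(cand = sample(colnames(G), 40))
    qq <- candidateSetQQ(scan, sets, spacing = 1e6)
    qq$cand$ksP < 0.01
  }, logical(1)))
  expect_gte(mean(!rej), 0.95)
  # enrichment: candidate set seeded with moderate-effect loci
  causal <- sprintf("s%04d", 1:15)
  y2 <- withr::with_seed(93, y - 0.25 * rowSums(G[, causal]))
  scan2 <- gwasScan(y2, G, mafMin = 0, loci = loci)
  qq2 <- candidateSetQQ(scan2, list(cand = causal), spacing = 1e6, seed = 94)
  expect_gt(median(qq2$cand$logp), median(qq2$background$logp))
  # KS statistic equals the brute-force empirical-CDF supremum
  a <- c(0.1, 0.3, 0.35, 0.8); b <- c(0.05, 0.2, 0.5, 0.7, 0.9)
  D <- suppressWarnings(ks.test(a, b)$statistic)
  grid <- sort(unique(c(a, b)))
  Dbrute <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                           numeric(1))))
  expect_equal(unname(D), Dbrute)
})
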