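test_that("PAV reproduces a hand-computed toy table exactly", {
  toy <- toyPavTable()
  betas <- c(L1 = -0.4, L2 = -0.5)
  yAdj <- toy$Y - (-0.4) * toy$G[, "L1"] - (-0.5) * toy$G[, "L2"]
  expected <- (popVar(toy$Y) - popVar(yAdj)) / popVar(toy$Y)
  expect_equal(pav(toy$Y, toy$G, betas), expected, tolerance = 1e-12)
  # single-locus PAV, fully by hand
  y1 <- toy$Y + 0.4 * toy$G[, "L1"]
  expect_equal(pav(toy$Y, toy$G, betas, "L1"),
               (popVar(toy$Y) - popVar(y1)) / popVar(toy$Y),
               tolerance = 1e-12)
})

test_that("PAV is invariant to genotype baseline and phenotype shift", {
  toy <- toyPavTable()
  betas <- c(L1 = -0.4, L2 = -0.5)
  p0 <- pav(toy$Y, toy$G, betas)
  expect_equal(pav(toy$Y, toy$G - 1, betas), p0, tolerance = 1e-12)
  expect_equal(pav(toy$Y + 100, toy$G, betas), p0, tolerance = 1e-9)
  expect_equal(pav(toy$Y, toy$G, c(L1 = 0, L2 = 0)), 0)
  expect_error(pav(rep(1, 6), toy$G, betas), "zero")
})

test_that("printed variance components give the published overlap", {
  ov <- pavOverlap(0.35, 0.44, 0.57)
  expect_equal(ov$overlap, 0.22)
  expect_equal(ov$uniqueA, 0.13)   # loci beyond ancestry
  expect_equal(ov$uniqueB, 0.22)   # ancestry beyond loci
  expect_true(ov$consistent)
  expect_false(pavOverlap(0.1, 0.1, 0.5)$consistent)
})

test_that("independent loci add exactly; admixture-correlated loci overlap", {
  # orthogonal design: equal-frequency balanced genotypes, cov = 0
  G <- cbind(A = rep(c(0, 1, 2), each = 3), B = rep(c(0, 1, 2), times = 3))
  expect_equal(popVar(G[, 1]), popVar(G[, 2]))
  expect_equal(mean((G[, 1] - mean(G[, 1])) * (G[, 2] - mean(G[, 2]))), 0)
  y <- 7 - 0.4 * G[, "A"] - 0.3 * G[, "B"]
  betas <- c(A = -0.4, B = -0.3)
  v1 <- pav(y, G, betas, "A"); v2 <- pav(y, G, betas, "B")
  v12 <- pav(y, G, betas)
  expect_equal(v12, v1 + v2, tolerance = 1e-12)
  # admixed cohort: unlinked loci correlate through ancestry, same-sign
  # effects, so the joint PAV is subadditive
  q <- drawAncestry(2000, seed = 5)
  la <- drawLocalAncestry(q, nLoci = 2, seed = 6)
  Ga <- drawGenotypes(la, c(1, 0.99), c(0.01, 0.25), seed = 7)
  colnames(Ga) <- c("A", "B")
  expect_gt(cov(Ga[, 1], Ga[, 2]), 0)
  ya <- withr::with_seed(8, 7 - 0.334 * Ga[, 1] - 0.166 * Ga[, 2] +
                           rnorm(2000, 0, 0.5))
  betasA <- c(A = -0.334, B = -0.166)
  expect_lt(pav(ya, Ga, betasA),
            pav(ya, Ga, betasA, "A") + pav(ya, Ga, betasA, "B"))
})

test_that("two-locus non-additivity identity holds numerically", {
  # V1 + V2 - V12 = 2 b1 b2 cov(G1, G2) / var(Y), an exact identity for any
  # data; checked on an admixed draw against the symbolic expansion
  q <- drawAncestry(800, seed = 15)
  la <- drawLocalAncestry(q, nLoci = 2, seed = 16)
  G <- drawGenotypes(la, c(1, 0.9), c(0, 0.1), seed = 17)
  colnames(G) <- c("G1", "G2")
  y <- withr::with_seed(18, 7 - 0.3 * G[, 1] - 0.2 * G[, 2] + rnorm(800, 0, 0.6))
  b <- c(G1 = -0.3, G2 = -0.2)
  v1 <- pav(y, G, b, "G1"); v2 <- pav(y, G, b, "G2"); v12 <- pav(y, G, b)
  covG <- mean((G[, 1] - mean(G[, 1])) * (G[, 2] - mean(G[, 2])))
  expect_equal(v1 + v2 - v12, 2 * b[["G1"]] * b[["G2"]] * covG / popVar(y),
               tolerance = 1e-12)
})

test_that("PAV of a superset dominates under shared-sign positive correlation", {
  co <- simulateCohort(800, seed = 25)
  full <- fitFullModel(phenotypes(co), genotypes(co), ancestry(co))
  b <- full$betas
  G <- genotypes(co); Y <- phenotypes(co)
  subsets <- list("SLC24A5", c("SLC24A5", "GRM5_TYR"),
                  c("SLC24A5", "GRM5_TYR", "APBA2"),
                  c("SLC24A5", "GRM5_TYR", "APBA2", "SLC45A2"))
  pavs <- vapply(subsets, function(s) pav(Y, G, b, s), numeric(1))
  expect_true(all(diff(pavs) > -1e-9))
})

test_that("unique contribution matches RSS arithmetic and orthogonal limits", {
  cc <- toyPavTable()
  q <- c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7)
  # oracle by explicit RSS computations
  full <- oracleOLS(cbind(cc$G, q), cc$Y)
  red <- oracleOLS(cbind(cc$G[, -1], q), cc$Y)
  expected <- (red$rss - full$rss) / (6 * popVar(cc$Y))
  expect_equal(uniqueContribution(cc$Y, cc$G, "L1", ancestry = q), expected,
               tolerance = 1e-10)
  # a locus duplicated as a covariate contributes nothing uniquely
  expect_equal(uniqueContribution(cc$Y, cc$G, "L1", covariates = cc$G[, 1]),
               0, tolerance = 1e-10)
  # orthogonal design: unique contribution ~ marginal PAV
  G <- cbind(A = rep(c(0, 1, 2), each = 3), B = rep(c(0, 1, 2), times = 3))
  y <- 7 - 0.4 * G[, "A"] - 0.3 * G[, "B"]
  expect_equal(uniqueContribution(y, G, "A"),
               pav(y, G, c(A = -0.4, B = -0.3), "A"), tolerance = 1e-10)
})

test_that("full-model fit recovers generated effects and flags collinearity", {
  withr::with_seed(35, {
    hits <- replicate(30, {
      co <- simulateCohort(685)
      f <- fitFullModel(phenotypes(co), genotypes(co), ancestry(co))
      ci <- confint(f$fit)["SLC24A5", ]
      ci[1] <= -0.334 && -0.334 <= ci[2]
    })
  })
  expect_gte(mean(hits), 0.90 - 3 * sqrt(0.95 * 0.05 / 30))
  # zero-effect cohort: estimates within noise of zero
  loci0 <- skinLociTable(); loci0$beta <- 0
  co0 <- simulateCohort(685, loci = loci0, gammaAnc = 0,
                        varianceTarget = 0.25, seed = 36)
  f0 <- fitFullModel(phenotypes(co0), genotypes(co0), ancestry(co0))
  se0 <- f0$table[names(f0$betas), "Std. Error"]
  expect_true(all(abs(f0$betas) < 4 * se0))
  # collinear columns are named in the error
  G <- genotypes(co0)
  expect_error(fitFullModel(phenotypes(co0), cbind(G, dup = G[, 1]),
                            ancestry(co0)),
               "collinear.*dup")
})

test_that("dominance and epistasis checks are calibrated and sensitive", {
  # additive null: dominance p-values roughly uniform
  withr::with_seed(45, {
    pvals <- replicate(60, {
      co <- simulateCohort(300)
      d <- dominanceEpistasisTests(phenotypes(co), genotypes(co),
                                   ancestry(co))
      d$dominance$p[1]
    })
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 60))
  # ancestral-dominant locus (heterozygote pulled toward the ancestral
  # homozygote, i.e. positive deviation against a negative additive effect)
  loci <- skinLociTable()
  q <- drawAncestry(800, seed = 46)
  la <- drawLocalAncestry(q, nLoci = 4, seed = 47)
  G <- drawGenotypes(la, loci$fEur, loci$fAfr, seed = 48)
  colnames(G) <- loci$id
  y <- simulatePhenotype(G, q, loci$beta, gammaAnc = -4.247,
                         dominance = c(0.25, 0, 0, 0), sigmaResid = 0.4,
                         seed = 49)
  d <- dominanceEpistasisTests(y, G, q)
  expect_lt(d$dominance$p[1], 0.01)
  expect_gt(d$dominance$estimate[1], 0)
  # injected pairwise interaction recovered within its CI
  epi <- data.frame(i = 1, j = 2, coef = 0.15)
  co2 <- simulateCohort(1000, epistasis = epi, seed = 48)
  d2 <- dominanceEpistasisTests(phenotypes(co2), genotypes(co2),
                                ancestry(co2))
  row <- d2$epistasis[d2$epistasis$i == "SLC24A5" &
                        d2$epistasis$j == "GRM5_TYR", ]
  expect_lt(abs(row$estimate - 0.15), 2.5 * row$se)
  expect_lt(row$p, 0.05)
})

test_that("pavReport assembles a consistent decomposition", {
  co <- simulateCohort(685, seed = 55)
  rep <- pavReport(phenotypes(co), genotypes(co), ancestry(co))
  expect_s4_class(rep, "PAVReport")
  expect_true(all(rep@perLocus$pav >= 0 & rep@perLocus$pav <= 1))
  expect_true(rep@overlap$consistent)
  expect_gte(rep@missingHeritability, 0)
  # fixed-beta sensitivity mode
  repF <- pavReport(phenotypes(co), genotypes(co), ancestry(co),
                    fixedBetas = c(SLC24A5 = -0.334, GRM5_TYR = -0.193,
                                   APBA2 = -0.155, SLC45A2 = -0.166))
  expect_equal(repF@perLocus$beta,
               c(-0.334, -0.193, -0.155, -0.166))
})
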