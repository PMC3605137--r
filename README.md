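# admixcolor

Quantitative pigmentation genetics in two-way admixed cohorts.

In a recently admixed African–European population, skin and eye color vary
over almost the full human range, and genome-wide ancestry proportions vary
widely between individuals. That makes such cohorts ideal for mapping
pigmentation loci — and statistically treacherous, because *admixture
stratification* correlates genotypes at unlinked loci with each other and
with genome-wide ancestry. `admixcolor` implements the complete analysis
chain for this setting, aimed at statistical geneticists who want a tested,
seed-reproducible reference implementation:

- **Synthetic cohorts** — genome-wide African ancestry `q` from a Beta
  distribution calibrated to median 0.58 and range 0.235–0.879; local
  ancestry `a ~ Binomial(2, 1−q)` (or a per-haplotype Markov chain along the
  genetic map); genotypes from ancestral derived-allele frequencies
  (f_EUR, f_AFR); phenotypes `Y = Σ β_k G_k + γ(1−q) + ε` with the residual
  calibrated to a total-variance target (default 0.85² MM²).
- **Phenotypes** — the **MM index**: square root of the Huber-robust mean of
  six melanin-index readings, `M = 100·log10(1/reflectance)`; and the
  **T index**: arc-length position of an iris's normalized (green, blue)
  color along a Hastie–Stuetzle principal curve, 0 at the lightest blue.
  Includes iris-image rendering and circular-edge segmentation.
- **Association** — per-locus OLS genotype scans, local-ancestry
  (admixture-mapping) scans, conditional scans, EIGENSTRAT-style PCA,
  genomic control, candidate-set q–q/KS comparisons.
- **Variance architecture** — population-attributable variance
  `PAV_S = [var(Y) − var(Y − Σ_{k∈S} β_k G_k)]/var(Y)`, ancestry R²,
  unique contributions, inclusion–exclusion overlap, dominance and
  epistasis checks.
- **Power** — simulation-based detection power for candidate loci under
  admixture stratification, and MM↔melanin effect-size unit conversions.

## Worked example

```r
library(admixcolor)

co <- simulateCohort(685, seed = 7)   # four major skin loci + ancestry
co
#> AdmixedCohort: 685 individuals, 4 loci
#>   African ancestry q: median 0.586, range [0.236, 0.862]
#>   phenotype (MM units): mean 7.403, sd 0.838
#>   loci: SLC24A5, GRM5_TYR, APBA2, SLC45A2

scan <- gwasScan(phenotypes(co), genotypes(co),
                 covariates = ancestry(co), loci = lociInfo(co))
scanTable(scan)[, c("ID", "BETA", "SE", "P")]
#>                ID       BETA         SE            P
#> SLC24A5   SLC24A5 -0.2759557 0.02573167 6.645674e-25
#> GRM5_TYR GRM5_TYR -0.2140946 0.02802609 7.423963e-14
#> APBA2       APBA2 -0.1275410 0.02852271 9.093756e-06
#> SLC45A2   SLC45A2 -0.2016807 0.02670314 1.373696e-13

pavReport(phenotypes(co), genotypes(co), ancestry(co))
#> PAVReport
#>   SLC24A5      beta -0.2750  PAV  15.2%  unique   5.2%
#>   GRM5_TYR     beta -0.2146  PAV   8.3%  unique   2.9%
#>   APBA2        beta -0.1213  PAV   6.9%  unique   0.9%
#>   SLC45A2      beta -0.1731  PAV   8.0%  unique   2.0%
#>   joint locus PAV: 35.9%
#>   ancestry R2:     63.9%
#>   combined R2:     75.3%
#>   loci/ancestry overlap: 24.5% (unique loci 11.4%, unique ancestry 39.4%)
#>   missing heritability at h2 = 0.80: 4.7%
```

Each marginal scan coefficient is attenuated relative to the generating
effect because the correlated loci and ancestry share signal; the full
model (`fitFullModel`) recovers the generating per-allele effects
unbiasedly. The joint PAV of the four loci (~36%) exceeds the sum of what
each adds uniquely — that gap *is* admixture stratification.

Eye color, end to end:

```r
pc <- fitPrincipalCurve(rbind(ladder <- {
  s <- rep(seq(0, 1, length.out = 30), each = 12)
  gb <- t(apply(irisColorLadder(s), 1, function(x) (x / sum(x))[2:3]))
  gb + matrix(rnorm(length(gb), 0, 0.004), ncol = 2)
}), span = 0.25)
im  <- synthIrisImage(irisRGB = irisColorLadder(0.05)[1, ], noiseSD = 0.02)
seg <- extractIris(im$image, im$pupilCenter)
tIndex(medianRGB(seg$pixels)[2:3], pc)   # ~0.03: a blue eye (T < 0.15)
```

A YAML-configured end-to-end run (`simulate → phenotype → scans → PAV →
power`, with provenance and MD5 manifest) is available as
`runPipeline("config.yaml", "outdir")` or via
`Rscript inst/scripts/admixcolor.R run --config config.yaml --out outdir`.

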