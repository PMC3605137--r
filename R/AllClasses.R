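#' AdmixedCohort: container for a simulated two-way admixed cohort
#'
#' Holds, for n individuals, the genome-wide African ancestry fraction q, a
#' local-ancestry matrix (copies of European ancestry per locus, 0-2), a
#' genotype matrix (copies of the derived allele per locus, 0-2, NA where
#' missing), an optional quantitative phenotype (MM units), and a per-locus
#' annotation table.
#'
#' @slot ancestry Numeric vector of African ancestry fractions in [0, 1].
#' @slot localAncestry Numeric matrix, individuals x loci, values in [0, 2]
#'   counting European-ancestry copies (integer for simulated truth, fractional
#'   for posterior dosages).
#' @slot genotypes Numeric matrix, individuals x loci, derived-allele counts in
#'   \{0, 1, 2\} or NA.
#' @slot phenotype Numeric vector (length n or 0 before simulation).
#' @slot loci data.frame with one row per locus (columns such as id, chrom,
#'   pos, posM, fEur, fAfr, beta).
#' @slot metadata List of generator parameters and seeds.
#' @export
setClass("AdmixedCohort",
  representation(
    ancestry = "numeric",
    localAncestry = "matrix",
    genotypes = "matrix",
    phenotype = "numeric",
    loci = "data.frame",
    metadata = "list"
  ),
  prototype(
    ancestry = numeric(0),
    localAncestry = matrix(numeric(0), 0, 0),
    genotypes = matrix(numeric(0), 0, 0),
    phenotype = numeric(0),
    loci = data.frame(),
    metadata = list()
  )
)

setValidity("AdmixedCohort", function(object) {
  msgs <- character(0)
  n <- length(object@ancestry)
  if (any(!is.finite(object@ancestry)) ||
      any(object@ancestry < 0 | object@ancestry > 1))
    msgs <- c(msgs, "ancestry fractions must lie in [0, 1]")
  for (nm in c("localAncestry", "genotypes")) {
    m <- slot(object, nm)
    if (length(m) && nrow(m) != n)
      msgs <- c(msgs, sprintf("%s must have one row per individual", nm))
  }
  la <- object@localAncestry
  if (length(la) && any(la < 0 | la > 2, na.rm = TRUE))
    msgs <- c(msgs, "localAncestry values must lie in [0, 2]")
  g <- object@genotypes
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msgs <- c(msgs, "genotypes must be 0, 1, 2 or NA")
  if (length(object@phenotype) && length(object@phenotype) != n)
    msgs <- c(msgs, "phenotype must have one value per individual")
  if (length(g) && nrow(object@loci) && ncol(g) != nrow(object@loci))
    msgs <- c(msgs, "loci table must have one row per genotype column")
  if (length(msgs)) msgs else TRUE
})

#' PrincipalCurve: fitted one-dimensional curve in the (green, blue) plane
#'
#' An ordered polyline with cumulative arc-length at each vertex, oriented so
#' that vertex 1 (arc-length 0) is the lightest-color end (highest blue
#' fraction).
#'
#' @slot vertices Numeric matrix (m x 2) of curve vertices.
#' @slot arcLength Numeric vector of cumulative arc-length, strictly
#'   increasing from 0.
#' @slot converged Logical: did the projection distance stabilize within
#'   \code{maxIter} iterations?
#' @slot iterations Integer iteration count.
#' @slot meanSqDist Mean squared projection distance at the final iterate.
#' @export
setClass("PrincipalCurve",
  representation(
    vertices = "matrix",
    arcLength = "numeric",
    converged = "logical",
    iterations = "integer",
    meanSqDist = "numeric"
  )
)

setValidity("PrincipalCurve", function(object) {
  msgs <- character(0)
  if (nrow(object@vertices) < 2L)
    msgs <- c(msgs, "curve needs at least two vertices")
  if (ncol(object@vertices) != 2L)
    msgs <- c(msgs, "vertices must be two-dimensional")
  al <- object@arcLength
  if (length(al) != nrow(object@vertices))
    msgs <- c(msgs, "one arc-length per vertex required")
  if (length(al) && (abs(al[1]) > 1e-12 || any(diff(al) <= 0)))
    msgs <- c(msgs, "arc-length must increase strictly from 0")
  if (length(msgs)) msgs else TRUE
})

#' AssocScan: per-locus association scan result
#'
#' @slot table data.frame with one row per tested locus: ID, CHROM, POS, BETA,
#'   SE, P, MAF, STATUS ("ok", "low_maf", "zero_variance", "aliased").
#' @slot lambda Genomic-control inflation factor computed from the "ok" loci.
#' @slot threshold Genome-wide significance threshold applied.
#' @slot predictor "genotype" or "ancestry".
#' @export
setClass("AssocScan",
  representation(
    table = "data.frame",
    lambda = "numeric",
    threshold = "numeric",
    predictor = "character"
  )
)

#' PAVReport: population-attributable variance decomposition
#'
#' @slot perLocus data.frame: per-locus fitted effect, marginal PAV, unique
#'   contribution.
#' @slot jointPAV PAV of all major loci set jointly to a common baseline.
#' @slot ancestryR2 R-squared of phenotype on genome-wide ancestry (the
#'   ancestry analogue of PAV).
#' @slot combinedR2 R-squared of the model with all major loci plus ancestry.
#' @slot overlap List with shared and unique fractions (loci vs ancestry).
#' @slot h2Assumed Assumed narrow-sense heritability for the
#'   missing-heritability panel.
#' @slot missingHeritability h2Assumed minus the combined explained fraction
#'   (floored at 0).
#' @export
setClass("PAVReport",
  representation(
    perLocus = "data.frame",
    jointPAV = "numeric",
    ancestryR2 = "numeric",
    combinedR2 = "numeric",
    overlap = "list",
    h2Assumed = "numeric",
    missingHeritability = "numeric"
  )
)
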