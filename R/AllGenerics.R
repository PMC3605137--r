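#' @rdname AdmixedCohort-class
#' @param object,x An \code{AdmixedCohort}.
#' @export
setGeneric("ancestry", function(x) standardGeneric("ancestry"))

#' @rdname AdmixedCohort-class
#' @export
setGeneric("localAncestry", function(x) standardGeneric("localAncestry"))

#' @rdname AdmixedCohort-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname AdmixedCohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname AdmixedCohort-class
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))

#' @rdname AdmixedCohort-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname AdmixedCohort-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname AssocScan-class
#' @param x An \code{AssocScan}.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname AssocScan-class
#' @export
setGeneric("gcLambda", function(x) standardGeneric("gcLambda"))

#' @rdname AssocScan-class
#' @export
setGeneric("significantLoci", function(x) standardGeneric("significantLoci"))

#' @rdname PrincipalCurve-class
#' @param x A \code{PrincipalCurve}.
#' @export
setGeneric("curveVertices", function(x) standardGeneric("curveVertices"))

#' @rdname PrincipalCurve-class
#' @export
setGeneric("curveLength", function(x) standardGeneric("curveLength"))

## ---- methods -------------------------------------------------------------

#' @rdname AdmixedCohort-class
#' @export
setMethod("ancestry", "AdmixedCohort", function(x) x@ancestry)

#' @rdname AdmixedCohort-class
#' @export
setMethod("localAncestry", "AdmixedCohort", function(x) x@localAncestry)

#' @rdname AdmixedCohort-class
#' @export
setMethod("genotypes", "AdmixedCohort", function(x) x@genotypes)

#' @rdname AdmixedCohort-class
#' @export
setMethod("phenotypes", "AdmixedCohort", function(x) x@phenotype)

#' @rdname AdmixedCohort-class
#' @export
setMethod("lociInfo", "AdmixedCohort", function(x) x@loci)

#' @rdname AdmixedCohort-class
#' @export
setMethod("nIndividuals", "AdmixedCohort", function(x) length(x@ancestry))

#' @rdname AdmixedCohort-class
#' @export
setMethod("nLoci", "AdmixedCohort", function(x) ncol(x@genotypes))

setMethod("show", "AdmixedCohort", function(object) {
  cat("AdmixedCohort:", length(object@ancestry), "individuals,",
      ncol(object@genotypes), "loci\n")
  if (length(object@ancestry)) {
    q <- object@ancestry
    cat(sprintf("  African ancestry q: median %.3f, range [%.3f, %.3f]\n",
                median(q), min(q), max(q)))
  }
  if (length(object@phenotype))
    cat(sprintf("  phenotype (MM units): mean %.3f, sd %.3f\n",
                mean(object@phenotype), sd(object@phenotype)))
  if (nrow(object@loci))
    cat("  loci:", paste(head(object@loci$id, 6), collapse = ", "),
        if (nrow(object@loci) > 6) "..." else "", "\n")
})

#' @rdname AssocScan-class
#' @export
setMethod("scanTable", "AssocScan", function(x) x@table)

#' @rdname AssocScan-class
#' @export
setMethod("gcLambda", "AssocScan", function(x) x@lambda)

#' @rdname AssocScan-class
#' @export
setMethod("significantLoci", "AssocScan", function(x) {
  tab <- x@table
  tab[!is.na(tab$P) & tab$P < x@threshold, , drop = FALSE]
})

setMethod("show", "AssocScan", function(object) {
  ok <- sum(object@table$STATUS == "ok")
  cat(sprintf("AssocScan (%s predictor): %d loci tested (%d in table)\n",
              object@predictor, ok, nrow(object@table)))
  cat(sprintf("  genomic-control lambda: %.3f; threshold: %g\n",
              object@lambda, object@threshold))
  hits <- significantLoci(object)
  cat("  genome-wide significant loci:", nrow(hits), "\n")
})

#' @rdname PrincipalCurve-class
#' @export
setMethod("curveVertices", "PrincipalCurve", function(x) x@vertices)

#' @rdname PrincipalCurve-class
#' @export
setMethod("curveLength", "PrincipalCurve",
          function(x) x@arcLength[length(x@arcLength)])

setMethod("show", "PrincipalCurve", function(object) {
  cat(sprintf("PrincipalCurve: %d vertices, total arc-length %.4f\n",
              nrow(object@vertices), curveLength(object)))
  cat(sprintf("  converged: %s after %d iterations (mean sq dist %.3g)\n",
              object@converged, object@iterations, object@meanSqDist))
})

setMethod("show", "PAVReport", function(object) {
  cat("PAVReport\n")
  pl <- object@perLocus
  for (i in seq_len(nrow(pl)))
    cat(sprintf("  %-12s beta %+.4f  PAV %5.1f%%  unique %5.1f%%\n",
                pl$id[i], pl$beta[i], 100 * pl$pav[i], 100 * pl$unique[i]))
  cat(sprintf("  joint locus PAV: %.1f%%\n", 100 * object@jointPAV))
  cat(sprintf("  ancestry R2:     %.1f%%\n", 100 * object@ancestryR2))
  cat(sprintf("  combined R2:     %.1f%%\n", 100 * object@combinedR2))
  cat(sprintf("  loci/ancestry overlap: %.1f%% (unique loci %.1f%%, unique ancestry %.1f%%)\n",
              100 * object@overlap$overlap, 100 * object@overlap$uniqueA,
              100 * object@overlap$uniqueB))
  cat(sprintf("  missing heritability at h2 = %.2f: %.1f%%\n",
              object@h2Assumed, 100 * object@missingHeritability))
})
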