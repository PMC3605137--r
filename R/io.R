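## Readers/writers: VCF genotype interchange and keyed TSV tables.
## Convention: the derived allele is the ALT allele; coordinates are
## 1-based.

#' Write cohort genotypes to a VCF file
#'
#' One record per locus, ALT = derived allele, unphased GT fields; missing
#' genotypes become "./.". The root seed and generator convention are
#' recorded in header lines.
#'
#' @param cohort An \code{\link{AdmixedCohort}}.
#' @param path Output path (plain-text .vcf).
#' @param ids Optional individual IDs (default IND0001...).
#' @return The path, invisibly.
#' @export
writeCohortVCF <- function(cohort, path, ids = NULL) {
  G <- genotypes(cohort)
  n <- nrow(G)
  ids <- ids %||% sprintf("IND%04d", seq_len(n))
  loci <- lociInfo(cohort)
  gtStrings <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gtStrings[g + 1L])
    paste(c(loci$chrom[j] %||% "1", loci$pos[j] %||% j, loci$id[j],
            "A", "G", ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=admixcolor",
    sprintf("##admixcolor_seed=%s",
            cohort@metadata$seed %||% "NA"),
    "##admixcolor_convention=ALT_is_derived_allele",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype matrix from a VCF file
#'
#' Counts ALT (derived) alleles per individual; missing GT fields become NA.
#' Multiallelic records are rejected with a message naming the locus.
#'
#' @param path Path to a VCF (.vcf or .vcf.gz).
#' @return Numeric matrix individuals x loci (dimnames = IDs), with a
#'   \code{"loci"} attribute (CHROM/POS/ID data.frame).
#' @export
readGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multiallelic records not supported: ",
         paste(fix$ID[multi], collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  countAlt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
    out
  }
  G <- t(apply(gt, 1, countAlt))
  G <- t(G)  # individuals x loci
  dimnames(G) <- list(colnames(gt), rownames(gt))
  attr(G, "loci") <- data.frame(chrom = fix$CHROM,
                                pos = as.integer(fix$POS),
                                id = fix$ID, stringsAsFactors = FALSE)
  G
}

#' Write cohort tables (ancestry, phenotype, local ancestry) as TSV
#'
#' @param cohort An \code{\link{AdmixedCohort}}.
#' @param dir Output directory (created if needed).
#' @param ids Optional individual IDs.
#' @return Named vector of file paths, invisibly.
#' @export
writeCohortTables <- function(cohort, dir, ids = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nIndividuals(cohort)
  ids <- ids %||% sprintf("IND%04d", seq_len(n))
  paths <- c(ancestry = file.path(dir, "ancestry.tsv"),
             phenotype = file.path(dir, "phenotypes.tsv"),
             localAncestry = file.path(dir, "local_ancestry.tsv"))
  write.table(data.frame(id = ids, q_afr = ancestry(cohort)),
              paths["ancestry"], sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(id = ids)
  if (length(phenotypes(cohort))) ph$MM <- phenotypes(cohort)
  write.table(ph, paths["phenotype"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  la <- as.data.frame(localAncestry(cohort))
  names(la) <- lociInfo(cohort)$id %||% names(la)
  write.table(cbind(id = ids, la), paths["localAncestry"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.readKeyedTSV <- function(path, key = "id") {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!key %in% names(raw))
    stop("missing key column '", key, "' in ", path, call. = FALSE)
  if (anyDuplicated(raw[[key]]))
    stop("duplicate IDs in ", path, call. = FALSE)
  for (nm in setdiff(names(raw), key)) {
    col <- raw[[nm]]
    if (any(grepl("^-?[0-9]+,[0-9]+$", col)))
      stop("locale decimal commas in column '", nm, "' of ", path,
           "; use '.' as the decimal separator", call. = FALSE)
    num <- suppressWarnings(as.numeric(col))
    if (!all(is.na(num) & nzchar(col))) raw[[nm]] <- num
  }
  raw
}

#' Read and join phenotype / ancestry / covariate tables
#'
#' Each TSV must have a header and an individual-ID key column; tables are
#' inner-joined on the key and the number of individuals dropped from each
#' input is reported in the \code{"dropped"} attribute. Duplicate IDs and
#' locale decimal commas are errors.
#'
#' @param ... Named TSV paths (e.g. phenotypes = "pheno.tsv",
#'   ancestry = "anc.tsv").
#' @param key Key column name (default "id").
#' @return Joined data.frame (one row per individual present in every
#'   table).
#' @export
readTables <- function(..., key = "id") {
  paths <- list(...)
  if (!length(paths)) stop("no tables given", call. = FALSE)
  tabs <- lapply(paths, .readKeyedTSV, key = key)
  joined <- Reduce(function(a, b) merge(a, b, by = key, sort = TRUE), tabs)
  if (nrow(joined) == 0)
    stop("empty join: no individual IDs shared across tables", call. = FALSE)
  dropped <- vapply(tabs, function(t) nrow(t) - nrow(joined), numeric(1))
  attr(joined, "dropped") <- dropped
  joined
}
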