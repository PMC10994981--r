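#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges IntegerList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

MISSING_ALLELE <- NA_integer_

#' GenotypeExperiment: georeferenced multiallelic diploid genotypes
#'
#' Container for diploid genotype calls at multiallelic loci
#' (microsatellite-like integer allele codes) together with per-sample
#' geography and cohort membership. Extends
#' [SummarizedExperiment::SummarizedExperiment] with rows = loci and
#' columns = samples. Two integer assays, `allele1` and `allele2`, hold the
#' unordered allele pair of each call; a missing genotype has `NA` in both.
#' `colData` carries `longitude`, `latitude` (decimal degrees WGS84, `NA`
#' when unlocated) and `cohort` (`"focal"` or `"reference"`); `rowData`
#' carries the per-locus set of observed allele codes as an
#' [IRanges::IntegerList] column `alleleLabels`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("allele1", "allele2") %in% an))
    return("assays must include 'allele1' and 'allele2'")
  a1 <- assay(object, "allele1")
  a2 <- assay(object, "allele2")
  if (!is.integer(a1) || !is.integer(a2))
    msg <- c(msg, "allele matrices must be integer")
  if (any(is.na(a1) != is.na(a2)))
    msg <- c(msg, "half-called genotypes present: allele1/allele2 NA patterns differ")
  cd <- colData(object)
  need <- c("longitude", "latitude", "cohort")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must have longitude, latitude, cohort")
  else {
    lat <- cd$latitude; lon <- cd$longitude
    if (any(!is.na(lat) & (lat < -90 | lat > 90)))
      msg <- c(msg, "latitude outside [-90, 90]")
    if (any(!is.na(lon) & (lon < -180 | lon > 180)))
      msg <- c(msg, "longitude outside [-180, 180]")
    if (!all(cd$cohort %in% c("focal", "reference")))
      msg <- c(msg, "cohort must be 'focal' or 'reference'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus names (rownames) must be unique")
  rd <- rowData(object)
  if (!"alleleLabels" %in% colnames(rd))
    msg <- c(msg, "rowData must carry an 'alleleLabels' IntegerList")
  else {
    labs <- rd$alleleLabels
    for (i in seq_len(nrow(object))) {
      li <- labs[[i]]
      if (length(li) < 1) { msg <- c(msg, sprintf("locus %d has no alleles", i)); break }
      if (anyDuplicated(li)) { msg <- c(msg, sprintf("duplicate allele labels at locus %d", i)); break }
      obs <- c(a1[i, ], a2[i, ])
      obs <- obs[!is.na(obs)]
      if (length(obs) && !all(obs %in% li)) {
        msg <- c(msg, sprintf("allele code outside alleleLabels at locus '%s'",
                              rownames(object)[i]))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param allele1,allele2 integer matrices (loci in rows, samples in
#'   columns) of allele codes; `NA` in both marks a missing genotype. The
#'   pair is unordered: callers may supply alleles in any order.
#' @param sampleInfo data.frame with one row per sample: columns
#'   `sample_id`, `longitude`, `latitude`, `cohort`. Coordinates may be
#'   `NA`; `cohort` defaults to `"focal"` when absent.
#' @param locusNames character vector of locus names; defaults to
#'   `rownames(allele1)`.
#' @return a [GenotypeExperiment-class] object.
#' @examples
#' a1 <- matrix(c(98L, 100L, 98L, 102L), nrow = 2,
#'              dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' a2 <- matrix(c(100L, 100L, 98L, 104L), nrow = 2,
#'              dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' si <- data.frame(sample_id = c("s1", "s2"), longitude = c(144.3, 145.0),
#'                  latitude = c(-38.1, -37.8), cohort = "focal")
#' ge <- GenotypeExperiment(a1, a2, si)
#' ge
#' @export
GenotypeExperiment <- function(allele1, allele2, sampleInfo, locusNames = rownames(allele1)) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  stopifnot(identical(dim(allele1), dim(allele2)))
  if (is.null(locusNames)) locusNames <- paste0("locus", seq_len(nrow(allele1)))
  sampleInfo <- as.data.frame(sampleInfo)
  stopifnot("sample_id" %in% colnames(sampleInfo),
            nrow(sampleInfo) == ncol(allele1))
  if (is.null(sampleInfo$longitude)) sampleInfo$longitude <- NA_real_
  if (is.null(sampleInfo$latitude)) sampleInfo$latitude <- NA_real_
  if (is.null(sampleInfo$cohort)) sampleInfo$cohort <- "focal"
  # demote half-called genotypes to missing (whole-genotype missingness)
  half <- is.na(allele1) != is.na(allele2)
  if (any(half)) {
    warning(sum(half), " half-called genotype(s) demoted to missing")
    allele1[half] <- NA_integer_
    allele2[half] <- NA_integer_
  }
  # canonical order within the pair so equality is order-free
  swap <- !is.na(allele1) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]; allele1[swap] <- allele2[swap]; allele2[swap] <- tmp
  }
  dimnames(allele1) <- dimnames(allele2) <-
    list(locusNames, as.character(sampleInfo$sample_id))
  labs <- lapply(seq_len(nrow(allele1)), function(i) {
    obs <- sort(unique(c(allele1[i, ], allele2[i, ])))
    obs <- obs[!is.na(obs)]
    if (!length(obs)) obs <- 0L   # placeholder label for an all-missing locus
    obs
  })
  rd <- DataFrame(row.names = locusNames)
  rd$alleleLabels <- IntegerList(labs)
  cd <- DataFrame(longitude = as.numeric(sampleInfo$longitude),
                  latitude = as.numeric(sampleInfo$latitude),
                  cohort = as.character(sampleInfo$cohort),
                  row.names = as.character(sampleInfo$sample_id))
  se <- SummarizedExperiment(
    assays = SimpleList(allele1 = allele1, allele2 = allele2),
    rowData = rd, colData = cd)
  new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment number of loci
#' @param x,object a `GenotypeExperiment`
#' @export
nLoci <- function(x) nrow(x)

#' @describeIn GenotypeExperiment number of samples
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeExperiment locus names
#' @export
lociNames <- function(x) rownames(x)

#' @describeIn GenotypeExperiment sample identifiers
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn GenotypeExperiment list with the two allele-call matrices
#' @export
alleleCalls <- function(x) list(allele1 = assay(x, "allele1"),
                                allele2 = assay(x, "allele2"))

#' @describeIn GenotypeExperiment per-locus allele label sets (IntegerList)
#' @export
alleleLabels <- function(x) rowData(x)$alleleLabels

#' @describeIn GenotypeExperiment data.frame of sample_id, longitude, latitude, cohort
#' @export
sampleInfo <- function(x) {
  cd <- colData(x)
  data.frame(sample_id = colnames(x), longitude = cd$longitude,
             latitude = cd$latitude, cohort = cd$cohort,
             stringsAsFactors = FALSE)
}

#' @describeIn GenotypeExperiment per-sample fraction of loci with a call
#' @export
callRate <- function(x) colMeans(!is.na(assay(x, "allele1")))

setMethod("show", "GenotypeExperiment", function(object) {
  cat("GenotypeExperiment:", nrow(object), "loci x", ncol(object), "samples\n")
  co <- table(colData(object)$cohort)
  cat("  cohorts:", paste(names(co), co, sep = "=", collapse = ", "), "\n")
  located <- sum(!is.na(colData(object)$latitude))
  cat("  located samples:", located, "\n")
  cr <- callRate(object)
  cat(sprintf("  call rate: mean %.3f, min %.3f\n",
              mean(cr), if (length(cr)) min(cr) else NA_real_))
  na <- lengths(alleleLabels(object))
  cat(sprintf("  alleles per locus: median %s, range %s-%s\n",
              stats::median(na), min(na), max(na)))
})

#' GroupPartition: ordered spatial groups along a linearized path
#'
#' Assignment of linearized samples to ordered groups along the invasion
#' path, with per-group size, median signed path distance and segment
#' bounds (km).
#'
#' @slot samples data.frame: `sample_id`, `s_km`, `group_id`
#' @slot groups data.frame: `group_id`, `n`, `median_s_km`, `lo_km`, `hi_km`
#' @export
setClass("GroupPartition",
         representation(samples = "data.frame", groups = "data.frame"))

setValidity("GroupPartition", function(object) {
  g <- object@groups; s <- object@samples
  msg <- character()
  if (!all(c("sample_id", "s_km", "group_id") %in% colnames(s)))
    msg <- c(msg, "samples needs sample_id, s_km, group_id")
  if (!all(c("group_id", "n", "median_s_km", "lo_km", "hi_km") %in% colnames(g)))
    msg <- c(msg, "groups needs group_id, n, median_s_km, lo_km, hi_km")
  else {
    if (is.unsorted(g$lo_km)) msg <- c(msg, "groups must be ordered along the path")
    tab <- table(factor(s$group_id, levels = g$group_id))
    if (!all(as.integer(tab) == g$n)) msg <- c(msg, "group sizes inconsistent with membership")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroupPartition", function(object) {
  g <- object@groups
  cat("GroupPartition:", nrow(g), "groups,", nrow(object@samples), "samples\n")
  cat(sprintf("  group sizes: %s\n", paste(g$n, collapse = ", ")))
  cat(sprintf("  median s (km): %s\n",
              paste(sprintf("%.0f", g$median_s_km), collapse = ", ")))
})

#' @describeIn GroupPartition per-sample group assignment table
#' @param x a `GroupPartition`
#' @export
groupAssignments <- function(x) x@samples

#' @describeIn GroupPartition per-group summary table
#' @export
groupTable <- function(x) x@groups

#' AlleleFreqTable: group x locus x allele frequencies
#'
#' Per-(group, locus) allele frequencies computed from non-missing gene
#' copies, with the gene-copy counts they are based on. Cells with zero
#' called copies are masked (`NA` frequencies, `nCopies = 0`).
#'
#' @slot freqs named list, one matrix per locus (groups x alleles),
#'   columns named by allele code
#' @slot nCopies integer matrix groups x loci of gene-copy counts
#' @slot groupIds character vector of group identifiers
#' @export
setClass("AlleleFreqTable",
         representation(freqs = "list", nCopies = "matrix", groupIds = "character"))

setValidity("AlleleFreqTable", function(object) {
  for (loc in names(object@freqs)) {
    f <- object@freqs[[loc]]
    ok <- !is.na(f[, 1])
    if (any(ok)) {
      rs <- rowSums(f[ok, , drop = FALSE])
      if (any(abs(rs - 1) > 1e-9))
        return(sprintf("frequencies at locus '%s' do not sum to 1", loc))
      if (any(f[ok, ] < 0)) return("negative frequency")
    }
  }
  TRUE
})

setMethod("show", "AlleleFreqTable", function(object) {
  cat("AlleleFreqTable:", length(object@groupIds), "groups x",
      length(object@freqs), "loci\n")
  cat("  gene copies per (group, locus): median",
      stats::median(object@nCopies), "\n")
})

#' @describeIn AlleleFreqTable frequency matrix (groups x alleles) for one locus
#' @param x an `AlleleFreqTable`
#' @param locus locus name
#' @export
locusFrequencies <- function(x, locus) x@freqs[[locus]]

#' @describeIn AlleleFreqTable gene-copy count matrix (groups x loci)
#' @export
geneCopies <- function(x) x@nCopies
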