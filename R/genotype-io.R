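#' Read multiallelic diploid genotypes
#'
#' Reads a genotype file in either GENEPOP or the flat table dialect into a
#' [GenotypeExperiment-class].
#'
#' **GENEPOP**: title line, one locus name per line (or comma-separated),
#' `Pop` separators, then one line per sample `id , tok tok ...` with 4- or
#' 6-character genotype tokens (2- or 3-digit allele codes); `0000` /
#' `000000` is a missing genotype. Coordinates and cohort are carried in a
#' sidecar table `<path>.meta.tsv` (columns `sample_id`, `longitude`,
#' `latitude`, `cohort`) written by [writeGenotypes()]; without a sidecar
#' all samples are unlocated and `focal`.
#'
#' **table**: tab-delimited, one row per sample with columns `sample_id`,
#' `longitude`, `latitude`, `cohort`, then two columns `<locus>_1`,
#' `<locus>_2` per locus; missing alleles are empty cells or 0.
#'
#' Half-called genotypes (one allele present) are demoted to missing with a
#' warning: missingness is a whole-genotype state, matching the per-locus
#' call-rate rule applied downstream.
#'
#' @param path file to read
#' @param format `"genepop"` or `"table"`
#' @return a [GenotypeExperiment-class]
#' @seealso [writeGenotypes()], [filterByCallRate()]
#' @export
readGenotypes <- function(path, format = c("genepop", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genepop") readGenepop(path) else readGenotypeTable(path)
}

readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) < 2) stop("parse error at line 1: empty or truncated GENEPOP file")
  isPop <- toupper(trimws(lines)) == "POP"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop) || firstPop < 3)
    stop("parse error: malformed header, no 'Pop' line after locus list")
  locusLines <- trimws(lines[2:(firstPop - 1)])
  locusLines <- locusLines[locusLines != ""]
  loci <- trimws(unlist(strsplit(locusLines, ",")))
  loci <- loci[loci != ""]
  if (!length(loci)) stop("parse error: no locus names in header")
  if (anyDuplicated(loci)) stop("parse error: duplicate locus names in header")

  ids <- character(); rows1 <- list(); rows2 <- list()
  width <- NA_integer_
  for (ln in seq(firstPop, length(lines))) {
    raw <- trimws(lines[ln])
    if (raw == "" || toupper(raw) == "POP") next
    commaAt <- regexpr(",", raw, fixed = TRUE)
    if (commaAt < 0)
      stop("parse error at line ", ln, ": sample line lacks ',' separator")
    id <- trimws(substr(raw, 1, commaAt - 1))
    toks <- strsplit(trimws(substr(raw, commaAt + 1, nchar(raw))), "[ \t]+")[[1]]
    toks <- toks[toks != ""]
    if (length(toks) != length(loci))
      stop("parse error at line ", ln, ": ragged row, ", length(toks),
           " genotypes for ", length(loci), " loci")
    w <- unique(nchar(toks))
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop("parse error at line ", ln,
           ": genotype token width must be 4 or 6 characters")
    if (is.na(width)) width <- w
    if (w != width)
      stop("parse error at line ", ln, ": allele-code width mismatch (",
           w, " vs ", width, ")")
    if (any(grepl("[^0-9]", toks)))
      stop("parse error at line ", ln, ": non-numeric genotype token")
    half <- width / 2
    a1 <- as.integer(substr(toks, 1, half))
    a2 <- as.integer(substr(toks, half + 1, width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    ids <- c(ids, id); rows1[[length(rows1) + 1L]] <- a1; rows2[[length(rows2) + 1L]] <- a2
  }
  if (!length(ids)) stop("parse error: no sample lines after 'Pop'")
  if (anyDuplicated(ids)) stop("parse error: duplicate sample ids")
  allele1 <- do.call(cbind, rows1); allele2 <- do.call(cbind, rows2)
  si <- data.frame(sample_id = ids, longitude = NA_real_, latitude = NA_real_,
                   cohort = "focal", stringsAsFactors = FALSE)
  metaPath <- paste0(path, ".meta.tsv")
  if (file.exists(metaPath)) {
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
    m <- match(si$sample_id, meta$sample_id)
    hit <- !is.na(m)
    if ("longitude" %in% colnames(meta)) si$longitude[hit] <- meta$longitude[m[hit]]
    if ("latitude" %in% colnames(meta)) si$latitude[hit] <- meta$latitude[m[hit]]
    if ("cohort" %in% colnames(meta)) si$cohort[hit] <- meta$cohort[m[hit]]
  }
  GenotypeExperiment(allele1, allele2, si, locusNames = loci)
}

readGenotypeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df) || !"sample_id" %in% colnames(df))
    stop("parse error: table needs a sample_id column and at least one row")
  cn <- colnames(df)
  a1cols <- grep("_1$", cn, value = TRUE)
  loci <- sub("_1$", "", a1cols)
  loci <- loci[paste0(loci, "_2") %in% cn]
  if (!length(loci)) stop("parse error: no <locus>_1/<locus>_2 column pairs")
  toAllele <- function(v) {
    v <- suppressWarnings(as.integer(v))
    v[!is.na(v) & v == 0L] <- NA_integer_
    v
  }
  allele1 <- t(vapply(df[paste0(loci, "_1")], toAllele, integer(nrow(df))))
  allele2 <- t(vapply(df[paste0(loci, "_2")], toAllele, integer(nrow(df))))
  if (nrow(df) == 1L) { allele1 <- matrix(allele1, ncol = 1); allele2 <- matrix(allele2, ncol = 1) }
  si <- data.frame(sample_id = as.character(df$sample_id),
                   longitude = if ("longitude" %in% cn) as.numeric(df$longitude) else NA_real_,
                   latitude = if ("latitude" %in% cn) as.numeric(df$latitude) else NA_real_,
                   cohort = if ("cohort" %in% cn) as.character(df$cohort) else "focal",
                   stringsAsFactors = FALSE)
  GenotypeExperiment(allele1, allele2, si, locusNames = loci)
}

#' Write genotypes to GENEPOP or the table dialect
#'
#' The output is re-readable by [readGenotypes()] with a lossless
#' round-trip of calls, locus names and sample ids. For GENEPOP, sample
#' geography and cohort are written to a sidecar `<path>.meta.tsv`, and the
#' digit width (2 or 3) is chosen from the largest allele code; codes above
#' 999 cannot be encoded and raise an error. Samples are grouped into one
#' `Pop` section per cohort.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param path output file
#' @param format `"genepop"` or `"table"`
#' @param title GENEPOP title line
#' @return `path`, invisibly
#' @export
writeGenotypes <- function(ge, path, format = c("genepop", "table"),
                           title = "surfline genotype export") {
  format <- match.arg(format)
  ac <- alleleCalls(ge)
  if (format == "table") {
    df <- sampleInfo(ge)
    for (i in seq_len(nLoci(ge))) {
      df[[paste0(lociNames(ge)[i], "_1")]] <- ac$allele1[i, ]
      df[[paste0(lociNames(ge)[i], "_2")]] <- ac$allele2[i, ]
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  mx <- suppressWarnings(max(c(ac$allele1, ac$allele2), na.rm = TRUE))
  if (!is.finite(mx)) mx <- 1L
  if (mx > 999L) stop("allele code ", mx, " exceeds 3-digit GENEPOP encoding")
  digits <- if (mx > 99L) 3L else 2L
  enc <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(lociNames(ge), con)
  si <- sampleInfo(ge)
  # one Pop section per contiguous cohort run, preserving sample order
  prevCohort <- NULL
  for (j in seq_len(nrow(si))) {
    if (!identical(prevCohort, si$cohort[j])) {
      writeLines("Pop", con)
      prevCohort <- si$cohort[j]
    }
    toks <- paste0(enc(ac$allele1[, j]), enc(ac$allele2[, j]))
    writeLines(paste0(si$sample_id[j], " , ", paste(toks, collapse = " ")), con)
  }
  utils::write.table(si, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop samples genotyped at too few loci
#'
#' Retains exactly those samples whose fraction of non-missing loci is at
#' least `minFraction` (the study protocol drops individuals genotyped at
#' fewer than 60% of loci). Loci are unchanged; the result may be empty.
#' The operation is idempotent and monotone in `minFraction`.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param minFraction minimum call-rate fraction in (0, 1]
#' @return the filtered [GenotypeExperiment-class]
#' @export
filterByCallRate <- function(ge, minFraction = 0.6) {
  stopifnot(minFraction > 0, minFraction <= 1)
  keep <- callRate(ge) >= minFraction
  ge[, keep]
}
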