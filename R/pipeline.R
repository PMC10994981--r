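#' Build a pipeline configuration
#'
#' Defaults follow the documented analysis protocol: individuals dropped
#' below a 60% call rate, 1-degree QC grid cells, a 150 km maximum offset
#' from the invasion path, 18 equidistant segments merged to a minimum
#' group size of 10, minimum-sample rarefaction, and per-locus Bonferroni
#' correction of the allele-cline scan at family-wide alpha .05.
#'
#' @param genotypes path to the genotype file
#' @param format `"table"` or `"genepop"`
#' @param path,origin GeoJSON files for the invasion path and origin point
#'   (origin may be `NULL` when embedded in `path`)
#' @param outputDir directory for result tables
#' @param minCallRate per-individual call-rate floor
#' @param qc list: `enabled`, `cellSizeDeg`, `nReps`, `minCellN`, `ld`
#' @param maxOffsetKm,nSegments,minGroupSize spatial grouping parameters
#' @param rarefy `"min"` or an integer rarefaction size (gene copies)
#' @param directions which directional subsets to scan
#' @param alpha family-wide significance level
#' @param bonferroniFamily `"locus"` or `"global"`
#' @param minInformativeGroups cline-scan informativeness floor
#' @param nPerm Mantel permutations
#' @param fstMethod `"wc_theta"` or `"nei_gst"`
#' @param seed master seed; every stage derives its own stream from it
#' @return config list (class `PipelineConfig`)
#' @export
pipelineConfig <- function(genotypes, format = "table", path, origin = NULL,
                           outputDir = "surfline_out", minCallRate = 0.6,
                           qc = list(enabled = TRUE, cellSizeDeg = 1,
                                     nReps = 999, minCellN = 10, ld = FALSE),
                           maxOffsetKm = 150, nSegments = 18,
                           minGroupSize = 10, rarefy = "min",
                           directions = c("west", "east"), alpha = 0.05,
                           bonferroniFamily = "locus",
                           minInformativeGroups = 3, nPerm = 999,
                           fstMethod = "wc_theta", seed = 1) {
  qcDefaults <- list(enabled = TRUE, cellSizeDeg = 1, nReps = 999,
                     minCellN = 10, ld = FALSE)
  qcDefaults[names(qc)] <- qc
  structure(list(genotypes = genotypes, format = format, path = path,
                 origin = origin, outputDir = outputDir,
                 minCallRate = minCallRate, qc = qcDefaults,
                 maxOffsetKm = maxOffsetKm, nSegments = nSegments,
                 minGroupSize = minGroupSize, rarefy = rarefy,
                 directions = directions, alpha = alpha,
                 bonferroniFamily = bonferroniFamily,
                 minInformativeGroups = minInformativeGroups, nPerm = nPerm,
                 fstMethod = fstMethod, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param file YAML file whose keys mirror the arguments of
#'   [pipelineConfig()]
#' @return a `PipelineConfig`
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, y)
}

writeTsv <- function(df, dir, name) {
  p <- file.path(dir, name)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

stageSeed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Run the full expansion-signature pipeline
#'
#' Orchestrates: call-rate filtering, grid-cell QC with locus exclusion,
#' linearization onto the invasion path, equidistant grouping with
#' small-group merging, per-group diversity, directional gradient Mantel
#' tests, the per-allele cline scan with surfing summary, and
#' differentiation-versus-distance tables. All tables are written as TSV
#' under `cfg$outputDir` together with a JSON run manifest (config, seed,
#' package version); identical config and seed give identical outputs. Any
#' stage failure aborts with the stage name.
#'
#' @param cfg a `PipelineConfig`, or the path of a YAML file for
#'   [readPipelineConfig()]
#' @return invisibly, a list with every result table plus `outputDir`
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  stopifnot(inherits(cfg, "PipelineConfig"))
  for (f in c(cfg$genotypes, cfg$path, cfg$origin))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  message("[surfline] reading genotypes: ", cfg$genotypes)
  ge <- stage("read", readGenotypes(cfg$genotypes, cfg$format))
  ge <- stage("callrate_filter", filterByCallRate(ge, cfg$minCallRate))

  qcTab <- NULL
  if (isTRUE(cfg$qc$enabled)) {
    message("[surfline] QC: grid-cell HWE/LD screening")
    qcTab <- stage("qc", qcReport(
      ge, cellSizeDeg = cfg$qc$cellSizeDeg, nReps = cfg$qc$nReps,
      seed = stageSeed(cfg, 101), alpha = cfg$alpha,
      minCellN = cfg$qc$minCellN, ld = isTRUE(cfg$qc$ld)))
    writeTsv(qcTab, cfg$outputDir, "qc_report.tsv")
    keep <- qcTab$locus[qcTab$verdict == "keep"]
    if (length(keep) < nLoci(ge))
      message("[surfline] QC dropped ", nLoci(ge) - length(keep), " locus/loci")
    ge <- ge[match(keep, lociNames(ge)), ]
  }

  message("[surfline] linearizing onto the invasion path")
  path <- stage("path", readPathGeoJSON(cfg$path, cfg$origin))
  geF <- ge[, sampleInfo(ge)$cohort == "focal"]
  lin <- stage("linearize", linearizeSamples(geF, path, cfg$maxOffsetKm))
  writeTsv(lin, cfg$outputDir, "linearized_samples.tsv")

  part <- stage("partition", mergeSmallGroups(
    partitionEquidistant(lin, cfg$nSegments), cfg$minGroupSize))
  gtab <- groupTable(part)
  writeTsv(gtab, cfg$outputDir, "groups.tsv")
  writeTsv(groupAssignments(part), cfg$outputDir, "group_assignments.tsv")

  message("[surfline] diversity statistics for ", nrow(gtab), " groups")
  ft <- stage("frequencies", alleleFrequencies(geF, part))
  div <- stage("diversity", diversitySummary(geF, part, rarefy = cfg$rarefy))
  writeTsv(div, cfg$outputDir, "diversity_summary.tsv")
  cohorts <- unique(sampleInfo(ge)$cohort)
  cohortTab <- if (length(cohorts) > 1)
    stage("cohorts", cohortDiversity(ge)) else NULL
  if (!is.null(cohortTab)) writeTsv(cohortTab, cfg$outputDir, "cohort_diversity.tsv")

  med <- groupMedianDistance(part)
  grad <- list(); scans <- list(); summaries <- list()
  for (d in cfg$directions) {
    gset <- directionGroups(part, d)
    message("[surfline] direction '", d, "': ", length(gset), " groups")
    if (length(gset) < 3) {
      warning("direction '", d, "' has fewer than 3 groups; skipped")
      next
    }
    grad[[d]] <- stage(paste0("gradients_", d), gradientTests(
      div, med, gset, direction = d, alpha = cfg$alpha, nPerm = cfg$nPerm,
      seed = stageSeed(cfg, 211)))
    sc <- stage(paste0("cline_scan_", d), alleleClineScan(
      ft, med, gset, direction = d, alpha = cfg$alpha,
      family = cfg$bonferroniFamily,
      minInformativeGroups = cfg$minInformativeGroups,
      nPerm = cfg$nPerm, seed = stageSeed(cfg, 307)))
    scans[[d]] <- sc$perAllele
    summaries[[d]] <- sc$summary
  }
  emptyDf <- data.frame(direction = character())
  gradTab <- if (length(grad)) do.call(rbind, grad) else emptyDf
  scanTab <- if (length(scans)) do.call(rbind, scans) else emptyDf
  surfTab <- if (length(summaries)) do.call(rbind, summaries) else emptyDf
  rownames(gradTab) <- rownames(scanTab) <- rownames(surfTab) <- NULL
  writeTsv(gradTab, cfg$outputDir, "gradient_tests.tsv")
  writeTsv(scanTab, cfg$outputDir, "allele_scan.tsv")
  writeTsv(surfTab, cfg$outputDir, "surfing_summary.tsv")

  message("[surfline] differentiation (", cfg$fstMethod, ")")
  fst <- stage("fst", pairwiseFst(geF, part, method = cfg$fstMethod))
  gstAll <- stage("gst", neiGst(ft))
  dvd <- stage("differentiation", differentiationVsDistance(
    fst, med, nPerm = cfg$nPerm, seed = stageSeed(cfg, 401)))
  fstDf <- data.frame(group_id = rownames(fst), fst, check.names = FALSE)
  writeTsv(fstDf, cfg$outputDir, "pairwise_fst.tsv")
  writeTsv(dvd$perGroup, cfg$outputDir, "differentiation_by_group.tsv")
  writeTsv(dvd$adjacent, cfg$outputDir, "differentiation_adjacent.tsv")

  manifest <- list(
    package = "surfline",
    version = as.character(utils::packageVersion("surfline")),
    config = unclass(cfg),
    config_hash = configHash(cfg),
    seed = cfg$seed,
    n_samples = nSamples(ge), n_loci = nLoci(ge),
    n_groups = nrow(gtab), gst_overall = gstAll)
  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results <- list(config = cfg, qc = qcTab, linearized = lin,
                  partition = part, diversity = div, cohorts = cohortTab,
                  gradients = gradTab, alleleScan = scanTab,
                  surfing = surfTab, fst = fst, gstOverall = gstAll,
                  differentiation = dvd, outputDir = cfg$outputDir)
  writeLines(makeReport(results), file.path(cfg$outputDir, "report.md"))
  invisible(results)
}

configHash <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                           null = "null")
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Human-readable pipeline report
#'
#' Renders the pipeline's result bundle as markdown: the cohort diversity
#' contrast, per-group diversity, gradient Mantel tests per direction, and
#' the allele-surfing tally with proportions on both the all-examined and
#' the examined-minus-insufficient denominators.
#'
#' @param results list returned by [runPipeline()]
#' @return character vector of markdown lines
#' @export
makeReport <- function(results) {
  out <- c("# Range-expansion signature report", "")
  fmtTable <- function(df) {
    if (is.null(df) || !nrow(df)) return("(no rows)")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste(colnames(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  if (!is.null(results$cohorts)) {
    out <- c(out, "## Cohort diversity contrast", "",
             fmtTable(results$cohorts), "")
  }
  out <- c(out, "## Spatial groups and diversity", "",
           fmtTable(results$diversity), "")
  out <- c(out, "## Diversity gradients (Mantel tests)", "",
           fmtTable(results$gradients), "")
  out <- c(out, "## Allele surfing summary", "", fmtTable(results$surfing), "")
  if (!is.null(results$surfing) && nrow(results$surfing)) {
    for (k in seq_len(nrow(results$surfing))) {
      s <- results$surfing[k, ]
      out <- c(out, sprintf(
        paste0("- %s: %d alleles examined, %d insufficient; %d significant",
               " (raw), %d after Bonferroni; proportions %.4f / %.4f of",
               " examined, %.4f / %.4f of tested"),
        s$direction, s$n_alleles_examined, s$n_insufficient,
        s$n_significant_raw, s$n_significant_bonferroni,
        s$prop_raw_of_examined, s$prop_bonf_of_examined,
        s$prop_raw_of_tested, s$prop_bonf_of_tested))
    }
    out <- c(out, "")
  }
  if (!is.null(results$gstOverall))
    out <- c(out, sprintf("Overall Nei GST across groups: %.4f",
                          results$gstOverall), "")
  out
}
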