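#' Assign located samples to latitude/longitude grid cells
#'
#' Bins samples into `cellSizeDeg` x `cellSizeDeg` cells by floor division
#' of latitude and longitude; the cell id names its south-west corner
#' (half-open convention: a sample exactly on a boundary belongs to the
#' cell it names). Spatial binning before Hardy-Weinberg and linkage tests
#' limits the violation of random-mating assumptions over a continental
#' sampling extent. Unlocated samples are left unassigned (`NA`).
#'
#' @param ge a [GenotypeExperiment-class]
#' @param cellSizeDeg cell edge in degrees (default 1)
#' @return data.frame `sample_id`, `cell_id`
#' @export
assignGridCells <- function(ge, cellSizeDeg = 1) {
  si <- sampleInfo(ge)
  located <- !is.na(si$latitude) & !is.na(si$longitude)
  if (!any(located)) warning("no located samples; empty grid partition")
  latF <- floor(si$latitude / cellSizeDeg) * cellSizeDeg
  lonF <- floor(si$longitude / cellSizeDeg) * cellSizeDeg
  cell <- ifelse(located, paste0(latF, "_", lonF), NA_character_)
  data.frame(sample_id = si$sample_id, cell_id = cell,
             stringsAsFactors = FALSE)
}

hweLogScore <- function(a1, a2) {
  # conditional-probability score: terms depending only on allele totals
  # are constant under permutation of gene copies
  het <- sum(a1 != a2)
  code <- pmin(a1, a2) * 1e6 + pmax(a1, a2)
  cnt <- rle(sort.int(code))$lengths
  het * log(2) - sum(lfactorial(cnt))
}

#' Monte-Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Tests the observed diploid genotype table at one (multiallelic) locus
#' against the conditional distribution of genotype tables given the
#' observed gene copies (random pairing of copies). Each replicate shuffles
#' the pooled copies, pairs them, and scores the resulting table by its
#' conditional probability; the p-value is the plus-one-corrected fraction
#' of tables at most as probable as the observed one:
#' `p = (1 + n_extreme) / (1 + nReps)`, so p is never exactly 0.
#'
#' @param a1,a2 integer allele vectors for called individuals (same length)
#' @param nReps Monte-Carlo replicates (default 9999)
#' @param seed RNG seed
#' @return list: `p`, `nReps`, `flag` (`"ok"` or `"monomorphic"`)
#' @export
hweExactTest <- function(a1, a2, nReps = 9999, seed = 1) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  stopifnot(n >= 2, nReps >= 1)
  pool <- c(a1, a2)
  if (length(unique(pool)) < 2)
    return(list(p = 1, nReps = nReps, flag = "monomorphic"))
  obs <- hweLogScore(a1, a2)
  extreme <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(nReps)) {
      perm <- sample(pool)
      b1 <- perm[seq_len(n)]; b2 <- perm[n + seq_len(n)]
      if (hweLogScore(b1, b2) <= obs + 1e-9) extreme <- extreme + 1L
    }
  })
  list(p = (1 + extreme) / (1 + nReps), nReps = nReps, flag = "ok")
}

genotypeCode <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))

gStatistic <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  i <- tab > 0
  2 * sum(tab[i] * log(tab[i] / E[i]))
}

#' Permutation G-test of genotypic linkage disequilibrium
#'
#' Tests association between the genotype categories of two loci over the
#' individuals called at both, using the log-likelihood-ratio (G) statistic
#' of the joint genotype contingency table; the null distribution comes
#' from permuting one locus's genotypes across individuals.
#' `p = (1 + #(G_perm >= G_obs)) / (1 + nReps)`.
#'
#' @param a1,a2 allele vectors of locus 1 (per individual)
#' @param b1,b2 allele vectors of locus 2
#' @param nReps permutation replicates (default 9999)
#' @param seed RNG seed
#' @return list: `p`, `G`, `nReps`, `flag` (`"ok"`, `"skipped"` when fewer
#'   than 5 doubly-called individuals, `"monomorphic"`)
#' @export
ldGenotypicTest <- function(a1, a2, b1, b2, nReps = 9999, seed = 1) {
  keep <- !is.na(a1) & !is.na(b1)
  if (sum(keep) < 5)
    return(list(p = NA_real_, G = NA_real_, nReps = nReps, flag = "skipped"))
  gA <- factor(genotypeCode(a1[keep], a2[keep]))
  gB <- factor(genotypeCode(b1[keep], b2[keep]))
  if (nlevels(gA) < 2 || nlevels(gB) < 2)
    return(list(p = 1, G = 0, nReps = nReps, flag = "monomorphic"))
  Gobs <- gStatistic(table(gA, gB))
  extreme <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(nReps))
      if (gStatistic(table(gA, sample(gB))) >= Gobs - 1e-9)
        extreme <- extreme + 1L
  })
  list(p = (1 + extreme) / (1 + nReps), G = Gobs, nReps = nReps, flag = "ok")
}

#' Brookfield null-allele frequency estimate
#'
#' Estimates the frequency of a non-amplifying (null) allele from the
#' heterozygote deficit: `r = (He - Ho) / (1 + He)`. A negative estimate
#' (observed heterozygosity above expected) is returned as-is with a
#' `"no-deficit"` flag.
#'
#' @param obsHet,expHet observed and expected heterozygosity in `[0, 1]`
#' @return list: `estimate`, `flag`
#' @export
nullAlleleEstimate <- function(obsHet, expHet) {
  stopifnot(obsHet >= 0, obsHet <= 1, expHet >= 0, expHet <= 1)
  r <- (expHet - obsHet) / (1 + expHet)
  list(estimate = r, flag = if (r < 0) "no-deficit" else "ok")
}

#' Grid-cell quality-control report for all loci
#'
#' Runs, within each grid cell holding at least `minCellN` located and
#' genotyped individuals: the Hardy-Weinberg Monte-Carlo exact test per
#' locus, the genotypic linkage-disequilibrium permutation test per locus
#' pair, and the Brookfield null-allele estimate per locus. P-values are
#' Bonferroni-corrected within each family (all HWE tests together; all LD
#' tests together) at family-wide level `alpha`. A locus is dropped when it
#' rejects HWE (after correction) in more than `hweRejectFraction` of its
#' testable cells, or is in corrected-significant LD in more than
#' `ldRejectFraction` of its testable pairs.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param cellSizeDeg grid cell size in degrees (default 1)
#' @param nReps Monte-Carlo/permutation replicates per test (default 9999)
#' @param seed master seed; each test gets a derived seed
#' @param alpha family-wide significance level (default .05)
#' @param hweRejectFraction fraction of testable cells rejecting HWE above
#'   which a locus is dropped (default 0.5)
#' @param ldRejectFraction as above for LD pairs (default 0.5)
#' @param minCellN minimum located genotyped individuals for a cell to be
#'   tested (default 10)
#' @param ld run the (quadratic in loci) LD scan (default TRUE)
#' @return data.frame, one row per locus: `locus`, `cells_tested`,
#'   `n_hwe_reject`, `n_ld_tests`, `n_ld_flag`, `null_est_median`,
#'   `verdict`, `reasons`
#' @export
qcReport <- function(ge, cellSizeDeg = 1, nReps = 9999, seed = 1,
                     alpha = 0.05, hweRejectFraction = 0.5,
                     ldRejectFraction = 0.5, minCellN = 10, ld = TRUE) {
  cells <- assignGridCells(ge, cellSizeDeg)
  ac <- alleleCalls(ge)
  loci <- lociNames(ge)
  L <- length(loci)
  cellIds <- stats::na.omit(unique(cells$cell_id))
  hweP <- list(); ldP <- list(); nullEst <- vector("list", L)
  testSeed <- 0L
  for (cell in cellIds) {
    cols <- which(cells$cell_id == cell & !is.na(cells$cell_id))
    for (i in seq_len(L)) {
      a1 <- ac$allele1[i, cols]; a2 <- ac$allele2[i, cols]
      called <- !is.na(a1)
      if (sum(called) < minCellN) next
      testSeed <- testSeed + 1L
      res <- hweExactTest(a1[called], a2[called], nReps = nReps,
                          seed = (seed + testSeed) %% .Machine$integer.max)
      hweP[[length(hweP) + 1L]] <- data.frame(
        locus = loci[i], cell = cell, p = res$p, flag = res$flag,
        stringsAsFactors = FALSE)
      n <- sum(called)
      f <- table(c(a1[called], a2[called])) / (2 * n)
      he <- heFromFreq(as.numeric(f), 2 * n, unbiased = FALSE)
      ho <- mean(a1[called] != a2[called])
      nullEst[[i]] <- c(nullEst[[i]], nullAlleleEstimate(ho, he)$estimate)
    }
    if (ld && L >= 2) {
      for (i in seq_len(L - 1)) for (j in (i + 1):L) {
        both <- !is.na(ac$allele1[i, cols]) & !is.na(ac$allele1[j, cols])
        if (sum(both) < max(5, minCellN)) next
        testSeed <- testSeed + 1L
        res <- ldGenotypicTest(ac$allele1[i, cols], ac$allele2[i, cols],
                               ac$allele1[j, cols], ac$allele2[j, cols],
                               nReps = nReps,
                               seed = (seed + testSeed) %% .Machine$integer.max)
        if (res$flag != "ok") next
        ldP[[length(ldP) + 1L]] <- data.frame(
          locus1 = loci[i], locus2 = loci[j], cell = cell, p = res$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  hwe <- if (length(hweP)) do.call(rbind, hweP) else
    data.frame(locus = character(), cell = character(), p = numeric(),
               flag = character())
  ldt <- if (length(ldP)) do.call(rbind, ldP) else
    data.frame(locus1 = character(), locus2 = character(), cell = character(),
               p = numeric())
  hweThr <- if (nrow(hwe)) alpha / nrow(hwe) else alpha   # Bonferroni family: all HWE tests
  ldThr <- if (nrow(ldt)) alpha / nrow(ldt) else alpha    # family: all LD tests
  out <- do.call(rbind, lapply(seq_len(L), function(i) {
    h <- hwe[hwe$locus == loci[i], , drop = FALSE]
    nRej <- sum(h$p < hweThr)
    lsub <- ldt[ldt$locus1 == loci[i] | ldt$locus2 == loci[i], , drop = FALSE]
    nLd <- sum(lsub$p < ldThr)
    reasons <- character()
    if (nrow(h) && nRej / nrow(h) > hweRejectFraction)
      reasons <- c(reasons, "hwe_departure")
    if (nrow(lsub) && nLd / nrow(lsub) > ldRejectFraction)
      reasons <- c(reasons, "linkage_disequilibrium")
    data.frame(locus = loci[i], cells_tested = nrow(h), n_hwe_reject = nRej,
               n_ld_tests = nrow(lsub), n_ld_flag = nLd,
               null_est_median = if (length(nullEst[[i]]))
                 stats::median(nullEst[[i]]) else NA_real_,
               verdict = if (length(reasons)) "drop" else "keep",
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  attr(out, "hwe_threshold") <- hweThr
  attr(out, "ld_threshold") <- ldThr
  attr(out, "hwe_tests") <- hwe
  attr(out, "ld_tests") <- ldt
  out
}
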