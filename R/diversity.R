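#' Per-group allele frequencies
#'
#' Tabulates allele frequencies for every (group, locus) cell from
#' non-missing gene copies only; the gene-copy count is twice the number of
#' called individuals. Cells with no calls are masked.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param partition a [GroupPartition-class] over (a subset of) the samples
#' @return an [AlleleFreqTable-class]
#' @export
alleleFrequencies <- function(ge, partition) {
  s <- partition@samples
  gids <- partition@groups$group_id
  ac <- alleleCalls(ge)
  idx <- match(s$sample_id, sampleIds(ge))
  if (anyNA(idx)) stop("partition contains samples absent from the dataset")
  loci <- lociNames(ge)
  labs <- alleleLabels(ge)
  freqs <- vector("list", length(loci)); names(freqs) <- loci
  nCop <- matrix(0L, length(gids), length(loci),
                 dimnames = list(gids, loci))
  for (i in seq_along(loci)) {
    al <- as.character(labs[[i]])
    f <- matrix(NA_real_, length(gids), length(al),
                dimnames = list(gids, al))
    for (gi in seq_along(gids)) {
      cols <- idx[s$group_id == gids[gi]]
      a <- c(ac$allele1[i, cols], ac$allele2[i, cols])
      a <- a[!is.na(a)]
      nCop[gi, i] <- length(a)
      if (length(a)) {
        cnt <- table(factor(as.character(a), levels = al))
        f[gi, ] <- as.numeric(cnt) / length(a)
      }
    }
    freqs[[i]] <- f
  }
  new("AlleleFreqTable", freqs = freqs, nCopies = nCop, groupIds = gids)
}

heFromFreq <- function(p, nCopies, unbiased = TRUE) {
  he <- 1 - sum(p^2)
  if (unbiased) {
    if (nCopies < 2) return(NA_real_)
    he <- he * nCopies / (nCopies - 1)
  }
  he
}

#' Expected heterozygosity per group and locus
#'
#' Gene diversity `1 - sum(p_a^2)`; the unbiased (Nei) form multiplies by
#' `n/(n-1)` gene copies and is undefined (masked) below 2 copies.
#'
#' @param ft an [AlleleFreqTable-class]
#' @param unbiased use the small-sample correction (default TRUE)
#' @return matrix groups x loci of He, masked where undefined
#' @export
expectedHeterozygosity <- function(ft, unbiased = TRUE) {
  loci <- names(ft@freqs)
  he <- matrix(NA_real_, length(ft@groupIds), length(loci),
               dimnames = list(ft@groupIds, loci))
  for (i in seq_along(loci)) {
    f <- ft@freqs[[i]]
    for (gi in seq_along(ft@groupIds)) {
      n <- ft@nCopies[gi, i]
      if (n > 0 && !is.na(f[gi, 1]))
        he[gi, i] <- heFromFreq(f[gi, ], n, unbiased)
    }
  }
  he
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement from the observed copies:
#' `A_g = sum_a (1 - choose(N - N_a, g) / choose(N, g))`, computed with
#' log-binomials. `A_g` is 1 for a monomorphic locus, equals the observed
#' allele count at `g = N`, and is non-decreasing in `g`.
#'
#' @param counts integer vector of allele copy counts (`N_a`); zeros allowed
#' @param g rarefaction size in gene copies, `2 <= g <= sum(counts)`
#' @return expected distinct alleles, or `NA` if `g > N`
#' @export
rarefiedRichness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) return(NA_real_)
  stopifnot(g >= 2)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Private allele counts between two cohorts
#'
#' An allele is private to a cohort if it is observed there and absent from
#' the other cohort at the same locus; counts are summed over the shared
#' locus set. Loci missing from either dataset are excluded with a warning.
#'
#' @param geA,geB [GenotypeExperiment-class] objects (e.g. the focal and
#'   reference cohorts)
#' @return list with `privateA`, `privateB` (integer totals) and
#'   `perLocus` data.frame
#' @export
privateAlleles <- function(geA, geB) {
  shared <- intersect(lociNames(geA), lociNames(geB))
  dropped <- setdiff(union(lociNames(geA), lociNames(geB)), shared)
  if (length(dropped))
    warning("loci absent from one cohort excluded: ",
            paste(dropped, collapse = ", "))
  obsAlleles <- function(ge, locus) {
    ac <- alleleCalls(ge)
    i <- match(locus, lociNames(ge))
    a <- c(ac$allele1[i, ], ac$allele2[i, ])
    unique(a[!is.na(a)])
  }
  per <- do.call(rbind, lapply(shared, function(loc) {
    aA <- obsAlleles(geA, loc); aB <- obsAlleles(geB, loc)
    data.frame(locus = loc,
               privateA = length(setdiff(aA, aB)),
               privateB = length(setdiff(aB, aA)),
               stringsAsFactors = FALSE)
  }))
  list(privateA = sum(per$privateA), privateB = sum(per$privateB),
       perLocus = per)
}

#' Nei's GST over a set of groups
#'
#' Per locus, `HS` is the unweighted mean of within-group gene diversity
#' `1 - sum(p^2)` and `HT` the gene diversity of the unweighted mean allele
#' frequencies; the multi-locus statistic is
#' `(mean(HT) - mean(HS)) / mean(HT)` averaging over loci with data.
#' Returns `NA` (masked) when `mean(HT)` is 0 (all groups monomorphic for
#' one allele).
#'
#' @param ft an [AlleleFreqTable-class]
#' @param groups group ids to include (default all)
#' @return GST in `[0, 1]`, or `NA`
#' @export
neiGst <- function(ft, groups = NULL) {
  if (is.null(groups)) groups <- ft@groupIds
  gi <- match(groups, ft@groupIds)
  stopifnot(!anyNA(gi), length(gi) >= 2)
  hs <- ht <- rep(NA_real_, length(ft@freqs))
  for (i in seq_along(ft@freqs)) {
    f <- ft@freqs[[i]][gi, , drop = FALSE]
    ok <- !is.na(f[, 1])
    if (sum(ok) < 2) next
    f <- f[ok, , drop = FALSE]
    hs[i] <- mean(1 - rowSums(f^2))
    pbar <- colMeans(f)
    ht[i] <- 1 - sum(pbar^2)
  }
  use <- !is.na(hs)
  if (!any(use) || mean(ht[use]) == 0) return(NA_real_)
  (mean(ht[use]) - mean(hs[use])) / mean(ht[use])
}

# Per-(group, locus, allele) statistics needed by the Weir-Cockerham
# variance components: sample size n_i (called individuals), allele
# frequency p_i and observed heterozygote frequency h_i.
wcComponents <- function(ge, partition, groupPair) {
  s <- partition@samples
  ac <- alleleCalls(ge)
  idx <- match(s$sample_id, sampleIds(ge))
  A <- 0; ABC <- 0
  for (i in seq_len(nLoci(ge))) {
    dat <- lapply(groupPair, function(gid) {
      cols <- idx[s$group_id == gid]
      a1 <- ac$allele1[i, cols]; a2 <- ac$allele2[i, cols]
      called <- !is.na(a1)
      list(a1 = a1[called], a2 = a2[called])
    })
    n <- vapply(dat, function(d) length(d$a1), numeric(1))
    if (any(n < 1)) next
    alleles <- unique(c(unlist(lapply(dat, `[[`, "a1")),
                        unlist(lapply(dat, `[[`, "a2"))))
    if (length(alleles) < 2) next
    r <- length(n)
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    if (nbar <= 1 || nc <= 0) next
    for (al in alleles) {
      p <- vapply(dat, function(d) (sum(d$a1 == al) + sum(d$a2 == al)) / (2 * length(d$a1)), numeric(1))
      h <- vapply(dat, function(d) mean((d$a1 == al) != (d$a2 == al)), numeric(1))
      pbar <- sum(n * p) / (r * nbar)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; ABC <- ABC + a + b + cc
    }
  }
  c(a = A, abc = ABC)
}

#' Pairwise differentiation matrix between groups
#'
#' Computes pairwise Weir-Cockerham theta (multi-locus ratio of summed
#' variance components over loci and alleles) or pairwise Nei GST between
#' every pair of groups. Pairs with no co-typed polymorphic locus are
#' masked.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param partition a [GroupPartition-class]
#' @param method `"wc_theta"` (default) or `"nei_gst"`
#' @return symmetric numeric matrix with zero diagonal, group ids as
#'   dimnames
#' @export
pairwiseFst <- function(ge, partition, method = c("wc_theta", "nei_gst")) {
  method <- match.arg(method)
  gids <- partition@groups$group_id
  stopifnot(length(gids) >= 2)
  ft <- if (method == "nei_gst") alleleFrequencies(ge, partition) else NULL
  M <- matrix(0, length(gids), length(gids), dimnames = list(gids, gids))
  for (i in seq_len(length(gids) - 1)) for (j in (i + 1):length(gids)) {
    v <- if (method == "wc_theta") {
      comp <- wcComponents(ge, partition, c(gids[i], gids[j]))
      if (comp["abc"] == 0) NA_real_ else unname(comp["a"] / comp["abc"])
    } else neiGst(ft, c(gids[i], gids[j]))
    M[i, j] <- M[j, i] <- v
  }
  M
}

#' Per-group and per-cohort diversity summary
#'
#' Computes, for each group of a partition: sample size, mean gene-copy
#' count, the sum and median over loci of rarefied allelic richness (at a
#' common rarefaction size per locus), the raw allele count and median
#' alleles per locus, and mean (unbiased) expected heterozygosity. Both the
#' rarefied and raw richness variants are reported because either may be
#' plotted against distance.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param partition a [GroupPartition-class]
#' @param rarefy `"min"` (default): per locus, `g` is the smallest
#'   gene-copy count over groups with data, floored at 2; or an integer `g`
#' @param unbiased unbiased He (default TRUE)
#' @return data.frame, one row per group
#' @export
diversitySummary <- function(ge, partition, rarefy = "min", unbiased = TRUE) {
  ft <- alleleFrequencies(ge, partition)
  he <- expectedHeterozygosity(ft, unbiased = unbiased)
  gids <- ft@groupIds
  loci <- names(ft@freqs)
  rich <- rawCount <- matrix(NA_real_, length(gids), length(loci),
                             dimnames = list(gids, loci))
  for (i in seq_along(loci)) {
    f <- ft@freqs[[i]]
    nc <- ft@nCopies[, i]
    g <- if (identical(rarefy, "min")) {
      withData <- nc[nc > 0]
      if (!length(withData)) next
      max(2L, min(withData))
    } else as.integer(rarefy)
    for (gi in seq_along(gids)) {
      if (nc[gi] == 0) next
      cnt <- round(f[gi, ] * nc[gi])
      rawCount[gi, i] <- sum(cnt > 0)
      if (nc[gi] >= g) rich[gi, i] <- rarefiedRichness(cnt, g)
    }
  }
  data.frame(
    group_id = gids,
    n = partition@groups$n[match(gids, partition@groups$group_id)],
    median_s_km = partition@groups$median_s_km[match(gids, partition@groups$group_id)],
    sum_rarefied_richness = rowSums(rich, na.rm = TRUE),
    median_rarefied_richness = apply(rich, 1, stats::median, na.rm = TRUE),
    sum_alleles = rowSums(rawCount, na.rm = TRUE),
    median_alleles = apply(rawCount, 1, stats::median, na.rm = TRUE),
    mean_he = rowMeans(he, na.rm = TRUE),
    stringsAsFactors = FALSE)
}

#' Cohort-level diversity contrast
#'
#' Summarises each cohort (e.g. the invading population versus its source)
#' as a single group: number of individuals, total alleles, private
#' alleles, mean alleles per locus and mean expected heterozygosity --
#' the classic founder-effect contrast table.
#'
#' @param ge a [GenotypeExperiment-class] containing both cohorts
#' @param unbiased unbiased He (default TRUE)
#' @return data.frame, one row per cohort
#' @export
cohortDiversity <- function(ge, unbiased = TRUE) {
  si <- sampleInfo(ge)
  cohorts <- unique(si$cohort)
  part <- new("GroupPartition",
              samples = data.frame(sample_id = si$sample_id, s_km = 0,
                                   group_id = si$cohort, stringsAsFactors = FALSE),
              groups = data.frame(group_id = cohorts,
                                  n = as.integer(table(si$cohort)[cohorts]),
                                  median_s_km = 0, lo_km = 0, hi_km = 0,
                                  stringsAsFactors = FALSE))
  ft <- alleleFrequencies(ge, part)
  he <- expectedHeterozygosity(ft, unbiased = unbiased)
  nAll <- vapply(cohorts, function(co) {
    sum(vapply(ft@freqs, function(f) sum(f[co, ] > 0, na.rm = TRUE), numeric(1)))
  }, numeric(1))
  priv <- if (length(cohorts) == 2) {
    pa <- privateAlleles(ge[, si$cohort == cohorts[1]],
                         ge[, si$cohort == cohorts[2]])
    c(pa$privateA, pa$privateB)
  } else rep(NA_integer_, length(cohorts))
  data.frame(cohort = cohorts,
             n_individuals = as.integer(table(si$cohort)[cohorts]),
             total_alleles = as.integer(nAll),
             private_alleles = priv,
             mean_alleles_per_locus = nAll / nLoci(ge),
             mean_he = rowMeans(he, na.rm = TRUE)[cohorts],
             stringsAsFactors = FALSE, row.names = NULL)
}
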