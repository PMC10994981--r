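# independent straight-line Weir-Cockerham theta for two groups, written
# directly from the 1984 variance-component formulas over raw genotypes
wcThetaOracle <- function(geno) {
  # geno: list of 2 groups; each a list per locus of 2-row allele matrices
  num <- den <- 0
  nloc <- length(geno[[1]])
  for (l in seq_len(nloc)) {
    gl <- lapply(geno, `[[`, l)
    gl <- lapply(gl, function(m) m[, !is.na(m[1, ]), drop = FALSE])
    n <- vapply(gl, ncol, numeric(1))
    if (any(n < 1)) next
    alleles <- unique(c(gl[[1]], gl[[2]]))
    if (length(alleles) < 2) next
    r <- 2; nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    if (nbar <= 1 || nc <= 0) next
    for (al in alleles) {
      p <- vapply(gl, function(m) mean(m == al), numeric(1))
      h <- vapply(gl, function(m) mean(xor(m[1, ] == al, m[2, ] == al)),
                  numeric(1))
      pbar <- sum(n * p) / sum(n)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / sum(n)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a; den <- den + a + b + cc
    }
  }
  num / den
}

twoGroupPartition <- function(ids, grp) {
  directPartition(s_km = ifelse(grp == "A", -100, 100), group_id = grp,
                  ids = ids)
}

test_that("allele frequencies count gene copies and mask empty cells", {
  ge <- makeGE(list(L1 = list(c(1L, 1L), c(1L, 2L), NA),
                    L2 = list(NA, NA, NA)))
  part <- directPartition(c(0, 0, 0), c("G1", "G1", "G1"),
                          ids = sampleIds(ge))
  ft <- alleleFrequencies(ge, part)
  f <- locusFrequencies(ft, "L1")
  expect_equal(unname(f["G1", "1"]), 0.75)   # AA + AB -> p_A = 3/4
  expect_equal(unname(f["G1", "2"]), 0.25)
  expect_equal(unname(geneCopies(ft)["G1", "L1"]), 4)
  expect_true(all(is.na(locusFrequencies(ft, "L2"))))
  expect_equal(unname(geneCopies(ft)["G1", "L2"]), 0)
})

test_that("frequencies sum to one on arbitrary fixtures", {
  sim <- simulateExpansion(expansionPreset("two_cluster_barrier", seed = 2,
                                           nSample = 6, nLoci = 5))
  lin <- linearizeSamples(sim$ge, sim$path, 150)
  part <- partitionEquidistant(lin, 4)
  ft <- alleleFrequencies(sim$ge, part)
  for (loc in lociNames(sim$ge)) {
    f <- locusFrequencies(ft, loc)
    ok <- !is.na(f[, 1])
    expect_equal(unname(rowSums(f[ok, , drop = FALSE])),
                 rep(1, sum(ok)), tolerance = 1e-12)
  }
})

test_that("expected heterozygosity follows the biased and unbiased forms", {
  ge <- makeGE(list(L1 = list(c(1L, 1L), c(2L, 2L)),      # p = {0.5, 0.5}, n = 4
                    L2 = list(c(3L, 3L), c(3L, 3L))))     # monomorphic
  part <- directPartition(c(0, 0), c("G1", "G1"), ids = sampleIds(ge))
  ft <- alleleFrequencies(ge, part)
  expect_equal(unname(expectedHeterozygosity(ft, unbiased = FALSE)["G1", "L1"]), 0.5)
  expect_equal(unname(expectedHeterozygosity(ft, unbiased = TRUE)["G1", "L1"]),
               4 / 3 * 0.5)
  expect_equal(unname(expectedHeterozygosity(ft, unbiased = FALSE)["G1", "L2"]), 0)
  expect_equal(unname(expectedHeterozygosity(ft, unbiased = TRUE)["G1", "L2"]), 0)
})

test_that("rarefied richness matches enumeration and boundary cases", {
  # {a:3, b:1}, g = 2: enumerate all C(4,2) = 6 copy pairs; mean distinct
  # alleles = (3*1 + 3*2)/6 = 1.5
  expect_equal(rarefiedRichness(c(3, 1), 2), 1.5)
  expect_equal(rarefiedRichness(c(7, 0), 4), 1)        # monomorphic
  expect_equal(rarefiedRichness(c(3, 2, 1), 6), 3)     # g = N: observed count
  expect_true(is.na(rarefiedRichness(c(2, 1), 4)))     # g > N masked
})

test_that("rarefied richness is monotone in g and matches subsampling", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      counts <- rmultinom(1, 30, rgamma(5, 1))[, 1]
      counts <- counts[counts > 0]
      N <- sum(counts)
      ag <- vapply(2:N, function(g) rarefiedRichness(counts, g), numeric(1))
      expect_true(all(diff(ag) >= -1e-12))
      # Monte-Carlo subsampling oracle at one g
      g <- max(2, N %/% 3)
      pool <- rep(seq_along(counts), counts)
      mc <- mean(vapply(1:4000, function(i)
        length(unique(sample(pool, g))), numeric(1)))
      expect_equal(rarefiedRichness(counts, g), mc, tolerance = 0.05)
    }
  })
})

test_that("private alleles are set differences summed over shared loci", {
  geA <- makeGE(list(L1 = list(c(1L, 2L), c(2L, 3L))))
  geB <- makeGE(list(L1 = list(c(2L, 3L), c(3L, 4L))))
  pa <- privateAlleles(geA, geB)
  expect_equal(pa$privateA, 1)   # allele 1
  expect_equal(pa$privateB, 1)   # allele 4
  same <- privateAlleles(geA, geA)
  expect_equal(same$privateA, 0)
  expect_equal(same$privateB, 0)
  geC <- makeGE(list(L1 = list(c(9L, 9L)), L2 = list(c(5L, 6L))))
  expect_warning(privateAlleles(geA, geC), "excluded")
})

test_that("Nei GST matches the arithmetic oracle and its bounds", {
  mkft <- function(pA) {
    f <- rbind(c(pA[1], 1 - pA[1]), c(pA[2], 1 - pA[2]))
    dimnames(f) <- list(c("A", "B"), c("1", "2"))
    new("AlleleFreqTable", freqs = list(L1 = f),
        nCopies = matrix(100L, 2, 1, dimnames = list(c("A", "B"), "L1")),
        groupIds = c("A", "B"))
  }
  # fixed differences: HS = 0, HT = 0.5, GST = 1
  expect_equal(neiGst(mkft(c(1, 0))), 1)
  # identical groups: GST = 0
  expect_equal(neiGst(mkft(c(0.3, 0.3))), 0)
  # p = 0.9 vs 0.5: HS = (0.18 + 0.5)/2 = 0.34, HT with pbar = 0.7 is 0.42,
  # GST = 0.08/0.42 (independent spreadsheet-style arithmetic)
  expect_equal(neiGst(mkft(c(0.9, 0.5))), (0.42 - 0.34) / 0.42,
               tolerance = 1e-12)
  # both groups monomorphic for the same allele: masked
  expect_true(is.na(neiGst(mkft(c(1, 1)))))
})

test_that("pairwise theta agrees with an independent WC implementation", {
  for (seed in 1:8) {
    sim <- withr::with_seed(seed, {
      n1 <- 25; n2 <- 30
      geno <- list(list(), list())
      calls <- list()
      for (l in 1:4) {
        f1 <- rgamma(4, 1); f1 <- f1 / sum(f1)
        f2 <- rgamma(4, 1); f2 <- f2 / sum(f2)
        m1 <- matrix(sample(1:4, 2 * n1, TRUE, prob = f1), 2)
        m2 <- matrix(sample(1:4, 2 * n2, TRUE, prob = f2), 2)
        geno[[1]][[l]] <- m1; geno[[2]][[l]] <- m2
        calls[[sprintf("L%d", l)]] <- c(
          lapply(seq_len(n1), function(j) m1[, j]),
          lapply(seq_len(n2), function(j) m2[, j]))
      }
      list(geno = geno, calls = calls, grp = rep(c("A", "B"), c(n1, n2)))
    })
    ge <- makeGE(sim$calls)
    part <- twoGroupPartition(sampleIds(ge), sim$grp)
    M <- pairwiseFst(ge, part, "wc_theta")
    expect_equal(M["A", "B"], wcThetaOracle(sim$geno), tolerance = 1e-12)
    expect_equal(M["A", "B"], M["B", "A"])
    expect_equal(unname(diag(M)), c(0, 0))
  }
})

test_that("differentiation is invariant to allele relabeling and group order", {
  sim <- withr::with_seed(4, {
    calls <- list()
    for (l in 1:3) {
      calls[[sprintf("L%d", l)]] <- lapply(1:40, function(j)
        sample(1:5, 2, TRUE, prob = if (j <= 20) c(5, 1, 1, 1, 1) else c(1, 1, 1, 1, 5)))
    }
    calls
  })
  ge <- makeGE(sim)
  grp <- rep(c("A", "B"), each = 20)
  part <- twoGroupPartition(sampleIds(ge), grp)
  theta <- pairwiseFst(ge, part, "wc_theta")["A", "B"]
  gst <- neiGst(alleleFrequencies(ge, part))
  # relabel alleles with an arbitrary injection
  relab <- c(11L, 7L, 23L, 2L, 31L)
  calls2 <- lapply(sim, function(loc) lapply(loc, function(g) relab[g]))
  ge2 <- makeGE(calls2)
  part2 <- twoGroupPartition(sampleIds(ge2), grp)
  expect_equal(pairwiseFst(ge2, part2, "wc_theta")["A", "B"], theta,
               tolerance = 1e-12)
  expect_equal(neiGst(alleleFrequencies(ge2, part2)), gst, tolerance = 1e-12)
  # reversed group order
  partR <- directPartition(ifelse(grp == "A", 100, -100), grp,
                           ids = sampleIds(ge))
  expect_equal(pairwiseFst(ge, partR, "wc_theta")["A", "B"], theta,
               tolerance = 1e-12)
})

test_that("merging identical groups keeps GST against either half at zero", {
  withr::with_seed(8, {
    calls <- list(L1 = lapply(1:30, function(j) sample(1:3, 2, TRUE)))
  })
  ge <- makeGE(calls)
  # groups A and B are literally the same frequency vector (same samples
  # counted under two labels is not possible; use identical genotype sets)
  callsAB <- list(L1 = c(calls$L1, calls$L1))
  geAB <- makeGE(callsAB)
  grp <- rep(c("A", "B"), each = 30)
  ft <- alleleFrequencies(geAB, twoGroupPartition(sampleIds(geAB), grp))
  expect_equal(neiGst(ft), 0, tolerance = 1e-12)
})

test_that("diversity summary reports rarefied and raw richness plus He", {
  sim <- simulateExpansion(expansionPreset("strong_founder_west", seed = 11,
                                           nDemes = 8, nSample = 8, nLoci = 6,
                                           stabilityGenerations = 5))
  lin <- linearizeSamples(sim$ge, sim$path, 150)
  part <- partitionEquidistant(lin, 4)
  div <- diversitySummary(sim$ge, part)
  expect_equal(nrow(div), 4)
  expect_true(all(div$mean_he >= 0 & div$mean_he <= 1))
  expect_true(all(div$median_rarefied_richness >= 1))
  expect_true(all(div$sum_rarefied_richness <= div$sum_alleles + 1e-9))
})

test_that("cohort contrast shows the founder-effect deficit", {
  # reference cohort drawn from the rich source; focal cohort from a
  # bottlenecked subset of it
  withr::with_seed(31, {
    nRef <- 40; nFoc <- 60
    calls <- list()
    for (l in 1:6) {
      src <- rgamma(10, 0.8); src <- src / sum(src)
      keep <- sample(1:10, 3, prob = src)      # founders carry few alleles
      bott <- rep(0, 10); bott[keep] <- src[keep] / sum(src[keep])
      calls[[sprintf("L%d", l)]] <- c(
        lapply(seq_len(nFoc), function(j) sample(1:10, 2, TRUE, prob = bott)),
        lapply(seq_len(nRef), function(j) sample(1:10, 2, TRUE, prob = src)))
    }
    calls
  }) -> calls
  ge <- makeGE(calls, cohort = rep(c("focal", "reference"), c(60, 40)))
  tab <- cohortDiversity(ge)
  foc <- tab[tab$cohort == "focal", ]; ref <- tab[tab$cohort == "reference", ]
  expect_lt(foc$total_alleles, ref$total_alleles)
  expect_lt(foc$mean_he, ref$mean_he)
  expect_lt(foc$private_alleles, ref$private_alleles)
  expect_equal(foc$mean_alleles_per_locus, foc$total_alleles / 6)
})
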