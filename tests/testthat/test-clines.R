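test_that("value distance matrices are |differences| with exclusions flagged", {
  D <- valueDistanceMatrix(c(a = 0, b = 1, c = 3))
  expect_equal(sort(D[upper.tri(D)]), c(1, 2, 3))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_identical(D, t(D))
  Dz <- valueDistanceMatrix(c(a = 2, b = 2, c = 2))
  expect_true(attr(Dz, "zero_variance"))
  Dx <- valueDistanceMatrix(c(a = 1, b = NA, c = 2))
  expect_identical(attr(Dx, "excluded"), "b")
  expect_error(valueDistanceMatrix(c(a = 1, b = NA)), "insufficient")
})

test_that("Mantel r is exact for identity, scaling and affine transforms", {
  A <- randomDist(5, 1)
  expect_equal(mantelTest(A, A)$r, 1)
  expect_equal(mantelTest(A, 2 * A)$r, 1)
  # affine transform of the underlying values leaves r and p unchanged
  v <- stats::setNames(c(0.1, 0.5, 0.2, 0.9, 0.4), sprintf("G%02d", 1:5))
  B <- randomDist(5, 2)
  r1 <- mantelTest(valueDistanceMatrix(v), B, seed = 3)
  r2 <- mantelTest(valueDistanceMatrix(3 * v + 7), B, seed = 3)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)
})

test_that("four-group enumeration equals the brute-force oracle exactly", {
  for (seed in 1:10) {
    A <- randomDist(4, seed)
    B <- randomDist(4, seed + 100)
    res <- mantelTest(A, B)
    expect_true(res$exhaustive)
    expect_identical(res$nPerm, 24L)
    expect_equal(res$p, bruteMantelP(A, B), tolerance = 1e-12)
    res2 <- mantelTest(A, B, tail = "two_sided")
    expect_equal(res2$p, bruteMantelP(A, B, "two_sided"), tolerance = 1e-12)
  }
})

test_that("sampled permutation p converges to the enumerated p", {
  A <- randomDist(6, 5)
  B <- randomDist(6, 55)
  exact <- mantelTest(A, B)   # 720 enumerated permutations
  nPerm <- 4999
  sampled <- mantelTest(A, B, nPerm = nPerm, seed = 9, enumLimit = 3)
  expect_false(sampled$exhaustive)
  expect_lt(abs(sampled$p - exact$p), 2 / sqrt(nPerm))
})

test_that("Mantel r is symmetric in its matrix arguments", {
  A <- randomDist(5, 7); B <- randomDist(5, 77)
  expect_equal(mantelTest(A, B)$r, mantelTest(B, A)$r, tolerance = 1e-12)
})

test_that("Mantel p is uniform under independent random matrices", {
  pvals <- vapply(1:500, function(s)
    mantelTest(randomDist(5, s), randomDist(5, s + 5000))$p, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_true(rej > 0.011 && rej < 0.105)
})

test_that("Mantel agrees with vegan on the correlation statistic", {
  skip_if_not_installed("vegan")
  A <- randomDist(8, 3); B <- randomDist(8, 33)
  ours <- mantelTest(A, B, nPerm = 999, seed = 4)
  veg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - veg$signif), 0.05)
})

test_that("zero-variance matrices are flagged, not tested", {
  A <- valueDistanceMatrix(c(a = 1, b = 1, c = 1))
  B <- valueDistanceMatrix(c(a = 0.3, b = 0.9, c = 0.1))
  res <- mantelTest(A, B)
  expect_identical(res$flag, "zero_variance")
  expect_true(is.na(res$r))
})

test_that("a monotone allele cline is detected with a negative trend", {
  freqs <- c(G01 = 0.8, G02 = 0.65, G03 = 0.5, G04 = 0.35, G05 = 0.2, G06 = 0.1)
  other <- 1 - freqs
  f <- cbind(`1` = freqs, `2` = other)
  ft <- new("AlleleFreqTable", freqs = list(L1 = f),
            nCopies = matrix(40L, 6, 1, dimnames = list(names(freqs), "L1")),
            groupIds = names(freqs))
  med <- stats::setNames(seq(0, -2500, length.out = 6), names(freqs))  # westward
  scan <- alleleClineScan(ft, med, names(freqs), direction = "west",
                          nPerm = 999, seed = 1)
  a1 <- scan$perAllele[scan$perAllele$allele == "1", ]
  expect_true(a1$significant_raw)
  expect_identical(a1$trend_sign, "-")     # declines away from the origin
  expect_equal(a1$p_threshold, 0.05 / 2)   # two alleles at the locus
  expect_equal(scan$summary$n_alleles_examined, 2)
})

test_that("constant or sparse alleles count as insufficient", {
  p2 <- c(0.2, 0.3, 0.25, 0.15, 0.35)
  f <- cbind(`1` = rep(0.5, 5), `2` = p2, `3` = 0.5 - p2)
  gid <- sprintf("G%02d", 1:5)
  dimnames(f) <- list(gid, c("1", "2", "3"))
  ft <- new("AlleleFreqTable", freqs = list(L1 = f),
            nCopies = matrix(40L, 5, 1, dimnames = list(gid, "L1")),
            groupIds = gid)
  med <- stats::setNames(seq(-100, -900, length.out = 5), gid)
  # allele 1 constant -> insufficient; an allele present in < 3 groups ->
  # insufficient
  f2 <- cbind(`1` = c(0.9, 0.8, 0.85, 0.9, 0.8),
              `2` = c(0.1, 0.2, 0.15, 0, 0.1),
              `3` = c(0, 0, 0, 0.1, 0.1))
  dimnames(f2) <- list(gid, c("1", "2", "3"))
  ft2 <- new("AlleleFreqTable", freqs = list(L1 = f2 / rowSums(f2)),
             nCopies = matrix(40L, 5, 1, dimnames = list(gid, "L1")),
             groupIds = gid)
  scanC <- alleleClineScan(ft, med, gid, nPerm = 99, seed = 1)
  expect_identical(
    scanC$perAllele$status[scanC$perAllele$allele == "1"], "insufficient")
  scan2 <- alleleClineScan(ft2, med, gid, nPerm = 99, seed = 1,
                           minInformativeGroups = 3)
  expect_identical(
    scan2$perAllele$status[scan2$perAllele$allele == "3"], "insufficient")
})

test_that("Bonferroni threshold and count ordering hold in every scan", {
  # a 10-allele locus at alpha .05 has per-test threshold .005
  withr::with_seed(14, {
    gid <- sprintf("G%02d", 1:8)
    f <- matrix(rgamma(80, 1), 8, 10)
    f <- f / rowSums(f)
    dimnames(f) <- list(gid, as.character(101:110))
    ft <- new("AlleleFreqTable", freqs = list(L1 = f),
              nCopies = matrix(30L, 8, 1, dimnames = list(gid, "L1")),
              groupIds = gid)
    med <- stats::setNames(sort(runif(8, -3000, 0)), gid)
  })
  scan <- alleleClineScan(ft, med, gid, nPerm = 199, seed = 2)
  expect_true(all(scan$perAllele$p_threshold == 0.005))
  expect_lte(scan$summary$n_significant_bonferroni,
             scan$summary$n_significant_raw)
  expect_lte(scan$summary$n_significant_raw,
             scan$summary$n_alleles_examined - scan$summary$n_insufficient)
  # global family divides by the total examined instead
  scanG <- alleleClineScan(ft, med, gid, nPerm = 199, seed = 2,
                           family = "global")
  expect_true(all(scanG$perAllele$p_threshold ==
                    0.05 / scanG$summary$n_alleles_examined))
})

test_that("scans abort on directional subsets smaller than three groups", {
  ft <- new("AlleleFreqTable",
            freqs = list(L1 = matrix(c(0.5, 0.4, 0.5, 0.6), 2, 2,
                                     dimnames = list(c("G01", "G02"),
                                                     c("1", "2")))),
            nCopies = matrix(10L, 2, 1,
                             dimnames = list(c("G01", "G02"), "L1")),
            groupIds = c("G01", "G02"))
  med <- c(G01 = -10, G02 = -500)
  expect_error(alleleClineScan(ft, med, c("G01", "G02")), "fewer than 3")
  expect_error(gradientTests(data.frame(), med, c("G01", "G02")),
               "insufficient groups")
})

test_that("differentiation-vs-distance summarises structure along the path", {
  gid <- sprintf("G%02d", 1:5)
  med <- stats::setNames(c(-2000, -1500, -1000, -500, 0), gid)
  flat <- matrix(0, 5, 5, dimnames = list(gid, gid))
  resFlat <- differentiationVsDistance(flat, med)
  expect_true(all(resFlat$perGroup$mean_pairwise == 0))
  expect_equal(nrow(resFlat$adjacent), 4)     # n_groups - 1 adjacent pairs
  expect_identical(resFlat$mantel$flag, "zero_variance")
  # a barrier between G02 and G03 dominates the adjacent-pair series
  block <- flat
  block[1:2, 3:5] <- 0.3; block[3:5, 1:2] <- 0.3
  block[1, 2] <- block[2, 1] <- 0.02
  block[3, 4] <- block[4, 3] <- 0.02; block[3, 5] <- block[5, 3] <- 0.03
  block[4, 5] <- block[5, 4] <- 0.02
  resB <- differentiationVsDistance(block, med)
  peak <- resB$adjacent$pair[which.max(resB$adjacent$statistic)]
  expect_identical(peak, "G02-G03")
})

test_that("label permutation restores the null for the allele scan", {
  # break the spatial signal of a structured simulation by shuffling group
  # labels; the raw-alpha significant fraction then matches alpha
  sim <- simulateExpansion(expansionPreset("strong_founder_west", seed = 99,
                                           nDemes = 12, nSample = 8,
                                           nLoci = 10,
                                           stabilityGenerations = 10))
  lin <- linearizeSamples(sim$ge, sim$path, 150)
  part <- partitionEquidistant(lin, 8)
  ft <- alleleFrequencies(sim$ge, part)
  med <- groupMedianDistance(part)
  fracs <- vapply(1:30, function(s) {
    shuffled <- withr::with_seed(s, stats::setNames(sample(med), names(med)))
    sc <- alleleClineScan(ft, shuffled, names(med), nPerm = 199, seed = s)
    sc$summary$n_significant_raw /
      (sc$summary$n_alleles_examined - sc$summary$n_insufficient)
  }, numeric(1))
  expect_true(mean(fracs) > 0.005 && mean(fracs) < 0.12)
})
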