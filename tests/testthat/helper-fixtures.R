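# fixture builders shared across test files

suppressPackageStartupMessages(library(SummarizedExperiment))

# small GenotypeExperiment from a compact description: calls[[locus]] is a list of
# length-2 integer vectors (or NA for missing), one per sample
makeGE <- function(calls, lon = NULL, lat = NULL, cohort = NULL,
                   ids = NULL) {
  nloc <- length(calls)
  nsam <- length(calls[[1]])
  a1 <- matrix(NA_integer_, nloc, nsam)
  a2 <- matrix(NA_integer_, nloc, nsam)
  for (i in seq_len(nloc)) for (j in seq_len(nsam)) {
    g <- calls[[i]][[j]]
    if (!anyNA(g)) { a1[i, j] <- g[1]; a2[i, j] <- g[2] }
  }
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nsam))
  si <- data.frame(sample_id = ids,
                   longitude = if (is.null(lon)) NA_real_ else lon,
                   latitude = if (is.null(lat)) NA_real_ else lat,
                   cohort = if (is.null(cohort)) "focal" else cohort)
  GenotypeExperiment(a1, a2, si,
                     locusNames = names(calls) %||% sprintf("L%d", seq_len(nloc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random dataset generator for round-trip property tests
randomGE <- function(nloc = 4, nsam = 8, maxAllele = 120, missingRate = 0.1,
                     seed = 1) {
  withr::with_seed(seed, {
    a1 <- matrix(sample(90:maxAllele, nloc * nsam, TRUE), nloc, nsam)
    a2 <- matrix(sample(90:maxAllele, nloc * nsam, TRUE), nloc, nsam)
    miss <- matrix(runif(nloc * nsam) < missingRate, nloc, nsam)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    si <- data.frame(sample_id = sprintf("ind%03d", seq_len(nsam)),
                     longitude = runif(nsam, 115, 150),
                     latitude = runif(nsam, -38, -20),
                     cohort = sample(c("focal", "reference"), nsam, TRUE))
    GenotypeExperiment(a1, a2, si, locusNames = sprintf("loc%02d", seq_len(nloc)))
  })
}

# straight east-west path at the equator: trivial geometry for hand checks
equatorPath <- function(lengthKm = 1000, originFrac = 0.5) {
  kmPerDeg <- pi / 180 * 6371.0088
  pathPolyline(rbind(c(0, 0), c(lengthKm / kmPerDeg, 0)),
               origin = c(lengthKm * originFrac / kmPerDeg, 0))
}

# brute-force Mantel oracle: explicit recursion over label permutations,
# recomputing the correlation from the permuted full matrix each time
bruteMantelP <- function(A, B, tail = "greater") {
  n <- nrow(A)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  rObs <- cor(A[upper.tri(A)], B[upper.tri(B)])
  rs <- vapply(perms(seq_len(n)), function(p) {
    Bp <- B[p, p]
    cor(A[upper.tri(A)], Bp[upper.tri(Bp)])
  }, numeric(1))
  if (tail == "greater") mean(rs >= rObs - 1e-12)
  else mean(abs(rs) >= abs(rObs) - 1e-12)
}

randomDist <- function(n, seed) {
  withr::with_seed(seed, valueDistanceMatrix(
    stats::setNames(runif(n), sprintf("G%02d", 1:n))))
}

# run one simulated dataset through grouping, gradient tests and the
# allele-cline scan for one direction
analyseSim <- function(sim, direction = "west", nSegments = 18,
                       minGroup = 10, nPerm = 199, seed = 1) {
  lin <- linearizeSamples(sim$ge, sim$path, 150)
  part <- mergeSmallGroups(partitionEquidistant(lin, nSegments), minGroup)
  med <- groupMedianDistance(part)
  gset <- directionGroups(part, direction)
  div <- diversitySummary(sim$ge, part)
  ft <- alleleFrequencies(sim$ge, part)
  gt <- gradientTests(div, med, gset, direction, nPerm = nPerm, seed = seed)
  sc <- alleleClineScan(ft, med, gset, direction, nPerm = nPerm, seed = seed)
  list(part = part, med = med, groups = gset, div = div,
       gradients = gt, scan = sc)
}

# partition built directly from known group memberships (bypasses geometry)
directPartition <- function(s_km, group_id, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(s_km))
  gids <- unique(group_id[order(s_km)])
  groups <- do.call(rbind, lapply(gids, function(g) {
    mem <- s_km[group_id == g]
    data.frame(group_id = g, n = length(mem),
               median_s_km = stats::median(mem),
               lo_km = min(mem), hi_km = max(mem) + 1e-9)
  }))
  groups <- groups[order(groups$lo_km), ]
  rownames(groups) <- NULL
  new("GroupPartition",
      samples = data.frame(sample_id = ids, s_km = s_km, group_id = group_id),
      groups = groups)
}
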