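#' Pairwise absolute-difference distance matrix from group values
#'
#' Builds the square symmetric matrix `D_ij = |v_i - v_j|` over groups
#' with a defined value; groups with `NA` are excluded (recorded in the
#' `"excluded"` attribute). A constant input yields an all-zero matrix,
#' flagged via the `"zero_variance"` attribute.
#'
#' @param values named numeric vector (names = group ids)
#' @return labelled symmetric matrix with zero diagonal
#' @export
valueDistanceMatrix <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("insufficient groups: fewer than 2 defined values")
  v <- values[ok]
  D <- abs(outer(v, v, "-"))
  dimnames(D) <- list(names(v), names(v))
  attr(D, "excluded") <- names(values)[!ok]
  attr(D, "zero_variance") <- isTRUE(all(D == 0))
  D
}

upperVec <- function(M) M[upper.tri(M)]

allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# permutation index matrix: exhaustive for small n, sampled otherwise
mantelPermutations <- function(n, nPerm, seed, enumLimit = 7) {
  if (n <= enumLimit) {
    P <- allPermutations(n)
    attr(P, "exhaustive") <- TRUE
  } else {
    P <- withr::with_seed(seed,
      t(vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))))
    attr(P, "exhaustive") <- FALSE
  }
  P
}

#' Mantel permutation test of two distance matrices
#'
#' Correlates the upper triangles of two labelled distance matrices and
#' assesses significance by jointly permuting the rows and columns of `B`.
#' With 7 or fewer groups, all `n!` permutations are enumerated and the
#' p-value is the exact fraction of permutations (identity included) at
#' least as extreme as observed; otherwise `nPerm` sampled permutations
#' give `p = (1 + n_extreme) / (1 + nPerm)`. The default tail `"greater"`
#' suits cline detection, where a gradient makes both matrices co-increase.
#'
#' @param A,B square symmetric matrices with matching labels, >= 3 groups
#' @param nPerm sampled permutations when not enumerating (default 999)
#' @param seed RNG seed
#' @param tail `"greater"` (one-tailed, r > 0) or `"two_sided"`
#' @param enumLimit largest group count for which permutations are
#'   enumerated rather than sampled (default 7)
#' @return list: `r`, `p`, `nPerm` (permutations actually used),
#'   `exhaustive`, `tail`, `flag` (`"ok"` or `"zero_variance"`)
#' @export
mantelTest <- function(A, B, nPerm = 999, seed = 1,
                       tail = c("greater", "two_sided"), enumLimit = 7) {
  tail <- match.arg(tail)
  stopifnot(nrow(A) == ncol(A), nrow(B) == ncol(B), nrow(A) >= 3)
  if (!is.null(dimnames(A)) && !is.null(dimnames(B))) {
    stopifnot(identical(rownames(A), rownames(B)))
  }
  va <- upperVec(A)
  n <- nrow(A)
  if (stats::sd(va) == 0 || stats::sd(upperVec(B)) == 0)
    return(list(r = NA_real_, p = NA_real_, nPerm = 0L, exhaustive = FALSE,
                tail = tail, flag = "zero_variance"))
  P <- mantelPermutations(n, nPerm, seed, enumLimit = enumLimit)
  exhaustive <- attr(P, "exhaustive")
  rPerm <- mantelPermCor(va, B, P)
  rObs <- stats::cor(va, upperVec(B))
  stat <- if (tail == "greater") rPerm else abs(rPerm)
  obs <- if (tail == "greater") rObs else abs(rObs)
  if (exhaustive) {
    p <- mean(stat >= obs - 1e-12)
    used <- nrow(P)
  } else {
    p <- (1 + sum(stat >= obs - 1e-12)) / (1 + nrow(P))
    used <- nrow(P)
  }
  list(r = rObs, p = p, nPerm = used, exhaustive = exhaustive, tail = tail,
       flag = "ok")
}

# Precomputed permutation machinery shared by all alleles tested over the
# same group subset: the upper triangles of B under every permutation,
# row-standardised so a batch Mantel r is one matrix product.
permutedTriangles <- function(B, nPerm, seed) {
  n <- nrow(B)
  P <- mantelPermutations(n, nPerm, seed)
  ut <- which(upper.tri(B), arr.ind = TRUE)
  V <- matrix(0, nrow(P), nrow(ut))
  for (k in seq_len(nrow(P)))
    V[k, ] <- B[cbind(P[k, ut[, 1]], P[k, ut[, 2]])]
  mu <- rowMeans(V)
  sy <- apply(V, 1, stats::sd)
  Vs <- (V - mu) / ifelse(sy == 0, Inf, sy)
  list(Vs = Vs, vb = upperVec(B), exhaustive = attr(P, "exhaustive"),
       nPerm = nrow(P))
}

mantelAgainstCache <- function(va, cache, tail) {
  sx <- stats::sd(va)
  if (sx == 0)
    return(list(r = NA_real_, p = NA_real_, flag = "zero_variance"))
  m <- length(va)
  xc <- va - mean(va)
  rPerm <- as.numeric(cache$Vs %*% xc) / ((m - 1) * sx)
  rObs <- stats::cor(va, cache$vb)
  stat <- if (tail == "greater") rPerm else abs(rPerm)
  obs <- if (tail == "greater") rObs else abs(rObs)
  p <- if (cache$exhaustive) mean(stat >= obs - 1e-12)
       else (1 + sum(stat >= obs - 1e-12)) / (1 + cache$nPerm)
  list(r = rObs, p = p, flag = "ok")
}

# correlation of va with the upper triangle of B under each row-permutation
mantelPermCor <- function(va, B, P) {
  ut <- which(upper.tri(B), arr.ind = TRUE)
  xc <- va - mean(va)
  sx <- stats::sd(va)
  m <- length(va)
  vapply(seq_len(nrow(P)), function(k) {
    vb <- B[cbind(P[k, ut[, 1]], P[k, ut[, 2]])]
    sy <- stats::sd(vb)
    if (sy == 0) return(0)
    sum(xc * (vb - mean(vb))) / ((m - 1) * sx * sy)
  }, numeric(1))
}

#' Scan every allele for a frequency cline along the expansion path
#'
#' For each (locus, allele) observed in the chosen groups, runs a Mantel
#' test of the matrix of absolute allele-frequency differences against the
#' matrix of absolute differences in group median path distance. Alleles
#' observed in fewer than `minInformativeGroups` groups, or with zero
#' frequency variance, are counted as having insufficient data. Raw
#' significance is assessed at `alpha`; Bonferroni significance at
#' `alpha / (number of alleles at the locus)` (family `"locus"`, the
#' default) or `alpha / total alleles examined` (family `"global"`). A
#' consistent excess of significant clines in the expansion direction is
#' the allele-surfing signature.
#'
#' @param ft an [AlleleFreqTable-class]
#' @param medians named numeric vector of group median path distances (km)
#' @param groups group ids forming the directional subset (>= 3)
#' @param direction label recorded in the output (e.g. `"west"`)
#' @param alpha family-wide level (default .05)
#' @param family `"locus"` or `"global"` Bonferroni family
#' @param minInformativeGroups minimum groups where the allele is present
#'   (default 3)
#' @param nPerm,seed,tail passed to [mantelTest()]
#' @return list: `perAllele` data.frame (locus, allele, n_groups, freq
#'   range, r, p, p_threshold, significant_raw, significant_bonf,
#'   trend_sign, status) and `summary` one-row data.frame tallying the
#'   scan with proportions on both the examined and the
#'   examined-minus-insufficient denominators
#' @export
alleleClineScan <- function(ft, medians, groups, direction = "unspecified",
                            alpha = 0.05, family = c("locus", "global"),
                            minInformativeGroups = 3, nPerm = 999, seed = 1,
                            tail = c("greater", "two_sided")) {
  family <- match.arg(family)
  tail <- match.arg(tail)
  gi <- match(groups, ft@groupIds)
  stopifnot(!anyNA(gi))
  if (length(groups) < 3)
    stop("directional subset has fewer than 3 groups; scan aborted")
  med <- medians[groups]
  stopifnot(!anyNA(med))
  permCache <- new.env(parent = emptyenv())
  rows <- list()
  for (loc in names(ft@freqs)) {
    f <- ft@freqs[[loc]][gi, , drop = FALSE]
    nAllelesLocus <- sum(colSums(f > 0, na.rm = TRUE) > 0)
    thr <- if (family == "locus") alpha / max(1, nAllelesLocus) else NA_real_
    for (al in colnames(f)) {
      fv <- f[, al]
      hasData <- !is.na(fv)
      obsGroups <- sum(fv > 0, na.rm = TRUE)
      if (obsGroups == 0) next  # allele absent from this direction: not examined
      status <- "tested"
      r <- p <- NA_real_; trend <- "0"
      if (obsGroups < minInformativeGroups || sum(hasData) < 3 ||
          stats::sd(fv[hasData]) == 0) {
        status <- "insufficient"
      } else {
        A <- valueDistanceMatrix(fv[hasData])
        B <- valueDistanceMatrix(med[hasData])
        if (isTRUE(attr(B, "zero_variance"))) {
          status <- "insufficient"
        } else {
          key <- paste(which(hasData), collapse = ",")
          if (is.null(permCache[[key]]))
            permCache[[key]] <- permutedTriangles(
              B, nPerm, seed = (seed + sum(hasData)) %% .Machine$integer.max)
          res <- mantelAgainstCache(upperVec(A), permCache[[key]], tail)
          if (res$flag != "ok") status <- "insufficient" else {
            r <- res$r; p <- res$p
            # trend against distance *from the origin*, not signed position
            ct <- stats::cor(fv[hasData], abs(med[hasData]))
            trend <- if (ct > 0) "+" else if (ct < 0) "-" else "0"
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, allele = al, direction = direction,
        n_groups = sum(hasData), n_groups_present = obsGroups,
        r = r, p = p, p_threshold = thr,
        significant_raw = !is.na(p) && p < alpha,
        significant_bonf = NA,
        trend_sign = trend, status = status, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(locus = character(), allele = character(),
                      direction = character(), n_groups = integer(),
                      n_groups_present = integer(), r = numeric(), p = numeric(),
                      p_threshold = numeric(), significant_raw = logical(),
                      significant_bonf = logical(), trend_sign = character(),
                      status = character())
  nExamined <- nrow(per)
  if (family == "global" && nExamined > 0)
    per$p_threshold <- alpha / nExamined
  per$significant_bonf <- !is.na(per$p) & per$p < per$p_threshold
  nInsuff <- sum(per$status == "insufficient")
  nRaw <- sum(per$significant_raw)
  nBonf <- sum(per$significant_bonf)
  denomTested <- nExamined - nInsuff
  summary <- data.frame(
    direction = direction,
    n_alleles_examined = nExamined,
    n_insufficient = nInsuff,
    n_significant_raw = nRaw,
    n_significant_bonferroni = nBonf,
    prop_raw_of_examined = if (nExamined) nRaw / nExamined else NA_real_,
    prop_bonf_of_examined = if (nExamined) nBonf / nExamined else NA_real_,
    prop_raw_of_tested = if (denomTested) nRaw / denomTested else NA_real_,
    prop_bonf_of_tested = if (denomTested) nBonf / denomTested else NA_real_,
    stringsAsFactors = FALSE)
  list(perAllele = per, summary = summary)
}

#' Mantel tests of group diversity statistics against path distance
#'
#' Runs a Mantel test of each diversity statistic's absolute-difference
#' matrix against the group median-distance matrix, for the groups given
#' (typically one directional subset). Statistics tested: sum and median
#' of rarefied allelic richness, raw allele-count sum and median per
#' locus, and mean expected heterozygosity. The trend sign is the sign of
#' the plain correlation of the statistic with the group's absolute
#' distance from the origin, so a diversity decline away from the origin
#' reports `"-"` in either direction.
#'
#' @param divSummary data.frame from [diversitySummary()]
#' @param medians named vector of group median distances (km)
#' @param groups group ids (>= 3) to test
#' @param direction label for the output
#' @param alpha significance level (default .05)
#' @param nPerm,seed,tail passed to [mantelTest()]
#' @return data.frame: statistic, direction, n_groups, r, p, trend_sign,
#'   significant
#' @export
gradientTests <- function(divSummary, medians, groups,
                          direction = "unspecified", alpha = 0.05,
                          nPerm = 999, seed = 1,
                          tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  if (length(groups) < 3) stop("insufficient groups: need >= 3 for gradient tests")
  stats_ <- c("sum_rarefied_richness", "median_rarefied_richness",
              "sum_alleles", "median_alleles", "mean_he")
  med <- medians[groups]
  rows <- lapply(seq_along(stats_), function(si) {
    st <- stats_[si]
    v <- stats::setNames(divSummary[[st]], divSummary$group_id)[groups]
    if (sum(!is.na(v)) < 3 || stats::sd(v, na.rm = TRUE) == 0)
      return(data.frame(statistic = st, direction = direction,
                        n_groups = sum(!is.na(v)), r = NA_real_, p = NA_real_,
                        trend_sign = "0", significant = FALSE,
                        stringsAsFactors = FALSE))
    ok <- !is.na(v)
    res <- mantelTest(valueDistanceMatrix(v[ok]), valueDistanceMatrix(med[ok]),
                      nPerm = nPerm, seed = seed + si, tail = tail)
    ct <- stats::cor(v[ok], abs(med[ok]))  # trend vs distance from origin
    data.frame(statistic = st, direction = direction, n_groups = sum(ok),
               r = res$r, p = res$p,
               trend_sign = if (is.na(ct) || ct == 0) "0" else if (ct > 0) "+" else "-",
               significant = !is.na(res$p) && res$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differentiation versus distance from the origin
#'
#' Summarises a pairwise differentiation matrix along the path: each
#' group's mean pairwise statistic against all others, the statistic
#' between each adjacent pair (groups ordered by median distance), and a
#' Mantel test of the differentiation matrix against the path-distance
#' matrix. Rising differentiation toward the range edges is the expected
#' signature of an expansion; a barrier shows up as a spike in the
#' adjacent-pair series.
#'
#' @param diffMatrix symmetric group differentiation matrix (GST or theta)
#' @param medians named vector of group median distances (km)
#' @param nPerm,seed,tail passed to [mantelTest()]
#' @return list: `perGroup` (group_id, median_s_km, mean_pairwise),
#'   `adjacent` (pair, midpoint_km, statistic), `mantel`
#' @export
differentiationVsDistance <- function(diffMatrix, medians, nPerm = 999,
                                      seed = 1,
                                      tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  g <- rownames(diffMatrix)
  med <- medians[g]
  ord <- g[order(med)]
  perGroup <- data.frame(
    group_id = g, median_s_km = as.numeric(med),
    mean_pairwise = vapply(g, function(x)
      mean(diffMatrix[x, setdiff(g, x)], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  adjacent <- do.call(rbind, lapply(seq_len(length(ord) - 1), function(k)
    data.frame(pair = paste(ord[k], ord[k + 1], sep = "-"),
               midpoint_km = mean(medians[c(ord[k], ord[k + 1])]),
               statistic = diffMatrix[ord[k], ord[k + 1]],
               stringsAsFactors = FALSE)))
  mres <- if (length(g) >= 3 && !anyNA(diffMatrix))
    mantelTest(diffMatrix, valueDistanceMatrix(med), nPerm = nPerm,
               seed = seed, tail = tail)
  else list(r = NA_real_, p = NA_real_, nPerm = 0L, flag = "masked")
  list(perGroup = perGroup, adjacent = adjacent, mantel = mres)
}
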