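#' Configuration for the serial-founder stepping-stone simulator
#'
#' Demes sit on a 1-D lattice along a straight synthetic path. Colonization
#' starts from `originIndex`: every `colonizationInterval` generations
#' (per direction) the wavefront deme founds the next empty deme with
#' `founderSize` diploid founders sampled with replacement; each occupied
#' deme then reproduces by Wright-Fisher sampling of `N` offspring from its
#' post-migration gene pool, neighbouring occupied demes exchange a
#' fraction `migrationRate` of their gene pools, and each transmitted
#' allele mutates stepwise (+/- one repeat unit, reflecting at the bounds)
#' with probability `mutationRate`. After both wavefronts reach the lattice
#' ends, `stabilityGenerations` further generations run before sampling.
#'
#' @param nDemes number of demes on the lattice
#' @param demeSpacingKm distance between adjacent demes (km)
#' @param originIndex deme where the introduction occurs
#' @param N carrying capacity (diploid individuals per deme)
#' @param founderSize diploid founders per colonization event
#' @param colonizationInterval generations per deme advance; length 1 or 2
#'   (`west`, `east`)
#' @param migrationRate per-generation gene-pool exchange fraction with
#'   each occupied neighbour, in `[0, 0.5]`
#' @param nLoci,allelesPerLocus loci and founding alleles per locus
#' @param sourceConcentration symmetric-Dirichlet concentration for source
#'   allele frequencies (smaller = more skewed)
#' @param mutationRate per-copy per-generation stepwise mutation
#'   probability
#' @param mutationBuffer extra allele states available on each side of the
#'   founding set for stepwise mutation
#' @param initialFounders diploid founders drawn from the source pool to
#'   seed the origin deme
#' @param stabilityGenerations post-expansion generations before sampling
#' @param nSample diploid individuals sampled per deme at the end
#' @param jitterOffsetKm across-path coordinate jitter (uniform, km)
#' @param spanKm path length for a single-deme (panmictic) configuration
#' @param barrierAfterDeme migration across the boundary between this deme
#'   and the next is suppressed (`NA` = no barrier); colonization still
#'   crosses
#' @param seed RNG seed; identical seeds give bit-identical datasets
#' @return validated config list (class `ExpansionConfig`)
#' @export
expansionConfig <- function(nDemes = 40, demeSpacingKm = 100, originIndex = nDemes,
                            N = 100, founderSize = 10,
                            colonizationInterval = 1, migrationRate = 0.05,
                            nLoci = 25, allelesPerLocus = 12,
                            sourceConcentration = 0.7, mutationRate = 5e-4,
                            mutationBuffer = 5, initialFounders = 50,
                            stabilityGenerations = 30, nSample = 10,
                            jitterOffsetKm = 30, spanKm = 1000,
                            barrierAfterDeme = NA_integer_, seed = 1) {
  cfg <- list(nDemes = as.integer(nDemes), demeSpacingKm = demeSpacingKm,
              originIndex = as.integer(originIndex), N = as.integer(N),
              founderSize = as.integer(founderSize),
              colonizationInterval = as.integer(rep(colonizationInterval,
                                                    length.out = 2)),
              migrationRate = migrationRate, nLoci = as.integer(nLoci),
              allelesPerLocus = as.integer(allelesPerLocus),
              sourceConcentration = sourceConcentration,
              mutationRate = mutationRate,
              mutationBuffer = as.integer(mutationBuffer),
              initialFounders = as.integer(initialFounders),
              stabilityGenerations = as.integer(stabilityGenerations),
              nSample = as.integer(nSample), jitterOffsetKm = jitterOffsetKm,
              spanKm = spanKm, barrierAfterDeme = as.integer(barrierAfterDeme),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nDemes >= 1, N >= 1, founderSize >= 1, founderSize <= N,
              originIndex >= 1, originIndex <= nDemes,
              migrationRate >= 0, migrationRate <= 0.5,
              nLoci >= 1, allelesPerLocus >= 2, mutationRate >= 0,
              stabilityGenerations >= 0, nSample >= 1, nSample <= N,
              initialFounders >= 1)
    if (nDemes > 1 && any(colonizationInterval < 1))
      stop("unreachable configuration: colonizationInterval must be >= 1")
  })
  structure(cfg, class = "ExpansionConfig")
}

#' Draw source-population allele frequencies
#'
#' One symmetric Dirichlet draw per locus, emulating a diverse,
#' well-established source population from which founders are taken.
#'
#' @param K alleles per locus (>= 2)
#' @param concentration Dirichlet concentration parameter
#' @param nLoci number of loci
#' @param seed RNG seed
#' @return matrix `nLoci` x `K` of frequencies (rows sum to 1)
#' @export
simulateSourcePool <- function(K, concentration, nLoci, seed = 1) {
  stopifnot(K >= 2)
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(nLoci * K, shape = concentration), nLoci, K)
    g / rowSums(g)
  })
}

stepwiseMutate <- function(counts, mu) {
  # counts: integer vector over the full allele-state ladder
  nCopies <- sum(counts)
  nMut <- stats::rbinom(1, nCopies, mu)
  if (nMut == 0) return(counts)
  S <- length(counts)
  for (k in seq_len(nMut)) {
    from <- sample.int(S, 1, prob = counts)
    dir <- if (stats::runif(1) < 0.5) -1L else 1L
    to <- from + dir
    if (to < 1L || to > S) to <- from - dir  # reflect at the bounds
    counts[from] <- counts[from] - 1L
    counts[to] <- counts[to] + 1L
  }
  counts
}

#' Simulate a serial-founder range expansion
#'
#' Runs the stepping-stone demographic model of [expansionConfig()] and
#' samples genotypes from every occupied deme at the end, placing samples
#' on a straight synthetic path with along- and across-path coordinate
#' jitter so the projection and offset-filter machinery downstream is
#' exercised. A single-deme configuration is the panmictic null: no
#' structure, samples spread uniformly along the path.
#'
#' @param cfg an `ExpansionConfig` from [expansionConfig()]
#' @return list: `ge` (a [GenotypeExperiment-class]), `truth` (per-deme
#'   colonization generation, true path position km, per-locus source
#'   frequencies, allele code ladder), `path` (a [PathPolyline-class] whose
#'   origin sits at the introduction deme)
#' @export
simulateExpansion <- function(cfg) {
  stopifnot(inherits(cfg, "ExpansionConfig"))
  withr::with_seed(cfg$seed, simulateExpansionImpl(cfg))
}

simulateExpansionImpl <- function(cfg) {
  K <- cfg$allelesPerLocus
  buf <- if (cfg$mutationRate > 0) cfg$mutationBuffer else 0L
  S <- K + 2L * buf                       # allele-state ladder size
  codes <- 100L + seq_len(S)              # integer allele codes (3-digit)
  founding <- buf + seq_len(K)            # slots occupied by source alleles
  src <- matrix(stats::rgamma(cfg$nLoci * K, shape = cfg$sourceConcentration),
                cfg$nLoci, K)
  src <- src / rowSums(src)

  nD <- cfg$nDemes
  # pools[[locus]]: S x nDemes integer copy counts
  pools <- lapply(seq_len(cfg$nLoci), function(i) matrix(0L, S, nD))
  occupied <- rep(FALSE, nD)
  colGen <- rep(NA_integer_, nD)
  origin <- cfg$originIndex
  occupied[origin] <- TRUE; colGen[origin] <- 0L
  for (i in seq_len(cfg$nLoci)) {
    draw <- stats::rmultinom(1, 2L * cfg$initialFounders, src[i, ])
    pools[[i]][founding, origin] <- draw
  }
  westFront <- origin; eastFront <- origin
  gen <- 0L
  ciW <- cfg$colonizationInterval[1]; ciE <- cfg$colonizationInterval[2]
  expanding <- function() westFront > 1 || eastFront < nD

  stepGeneration <- function() {
    # migration: gene-pool exchange between adjacent occupied demes,
    # then Wright-Fisher resampling to 2N copies, then stepwise mutation
    occ <- which(occupied)
    for (i in seq_len(cfg$nLoci)) {
      P <- pools[[i]]
      fr <- vapply(occ, function(d) {
        cs <- P[, d]
        if (sum(cs) == 0) rep(0, S) else cs / sum(cs)
      }, numeric(S))
      mixed <- fr
      if (length(occ) > 1 && cfg$migrationRate > 0) {
        for (k in seq_along(occ)) {
          d <- occ[k]
          nbrs <- c(if (k > 1 && occ[k - 1] == d - 1) k - 1,
                    if (k < length(occ) && occ[k + 1] == d + 1) k + 1)
          if (!is.na(cfg$barrierAfterDeme))
            nbrs <- nbrs[!(pmin(occ[nbrs], d) == cfg$barrierAfterDeme &
                             pmax(occ[nbrs], d) == cfg$barrierAfterDeme + 1L)]
          if (!length(nbrs)) next
          m <- cfg$migrationRate
          mixed[, k] <- (1 - length(nbrs) * m) * fr[, k] +
            m * rowSums(fr[, nbrs, drop = FALSE])
        }
      }
      for (k in seq_along(occ)) {
        cnt <- stats::rmultinom(1, 2L * cfg$N, mixed[, k])[, 1]
        if (cfg$mutationRate > 0)
          cnt <- stepwiseMutate(cnt, cfg$mutationRate)
        P[, occ[k]] <- cnt
      }
      pools[[i]] <<- P
    }
  }

  colonize <- function(from, to) {
    for (i in seq_len(cfg$nLoci)) {
      f <- pools[[i]][, from]
      pools[[i]][, to] <<- stats::rmultinom(1, 2L * cfg$founderSize,
                                            f / sum(f))[, 1]
    }
    occupied[to] <<- TRUE
    colGen[to] <<- gen
  }

  while (expanding()) {
    gen <- gen + 1L
    if (westFront > 1 && ciW > 0 && gen %% ciW == 0L) {
      colonize(westFront, westFront - 1L); westFront <- westFront - 1L
    }
    if (eastFront < nD && ciE > 0 && gen %% ciE == 0L) {
      colonize(eastFront, eastFront + 1L); eastFront <- eastFront + 1L
    }
    stepGeneration()
  }
  for (g in seq_len(cfg$stabilityGenerations)) {
    gen <- gen + 1L
    stepGeneration()
  }

  # geometry: straight east-west path at a fixed latitude
  lat0 <- -35; lon0 <- 115
  kmPerDegLon <- 111.3195 * cos(lat0 * pi / 180)
  span <- if (nD > 1) (nD - 1) * cfg$demeSpacingKm else cfg$spanKm
  demeX <- if (nD > 1) (seq_len(nD) - 1) * cfg$demeSpacingKm
           else cfg$spanKm / 2
  originX <- if (nD > 1) (origin - 1) * cfg$demeSpacingKm else cfg$spanKm / 2
  path <- pathPolyline(
    rbind(c(lon0, lat0), c(lon0 + span / kmPerDegLon, lat0)),
    origin = c(lon0 + originX / kmPerDegLon, lat0))

  ids <- character(); xs <- numeric(); lats <- numeric(); deme <- integer()
  a1 <- matrix(NA_integer_, cfg$nLoci, 0); a2 <- a1
  for (d in which(occupied)) {
    g1 <- matrix(NA_integer_, cfg$nLoci, cfg$nSample)
    g2 <- g1
    for (i in seq_len(cfg$nLoci)) {
      poolVec <- rep(seq_len(S), pools[[i]][, d])
      pick <- sample(poolVec, 2L * cfg$nSample, replace = FALSE)
      g1[i, ] <- codes[pick[seq_len(cfg$nSample)]]
      g2[i, ] <- codes[pick[cfg$nSample + seq_len(cfg$nSample)]]
    }
    a1 <- cbind(a1, g1); a2 <- cbind(a2, g2)
    ids <- c(ids, sprintf("d%02d_s%03d", d, seq_len(cfg$nSample)))
    xAlong <- if (nD > 1)
      demeX[d] + stats::runif(cfg$nSample, -0.5, 0.5) * cfg$demeSpacingKm
    else stats::runif(cfg$nSample, 0, cfg$spanKm)
    xs <- c(xs, pmin(pmax(xAlong, 0), span))
    lats <- c(lats, lat0 + stats::runif(cfg$nSample, -1, 1) *
                cfg$jitterOffsetKm / 111.3195)
    deme <- c(deme, rep(d, cfg$nSample))
  }
  si <- data.frame(sample_id = ids, longitude = lon0 + xs / kmPerDegLon,
                   latitude = lats, cohort = "focal",
                   stringsAsFactors = FALSE)
  ge <- GenotypeExperiment(a1, a2, si,
                           locusNames = sprintf("L%02d", seq_len(cfg$nLoci)))
  metadata(ge)$deme <- deme
  truth <- list(colonization_generation = colGen,
                deme_position_km = demeX - originX,
                deme = deme,
                generations = gen,
                source_frequencies = src,
                allele_codes = codes,
                founding_codes = codes[founding])
  list(ge = ge, truth = truth, path = path)
}

#' Named simulator presets
#'
#' - `panmixia_null`: one deme, no spatial structure; samples are spread
#'   uniformly along the path. The negative control.
#' - `strong_founder_west`: 40 demes colonized westward from the eastern
#'   end with 5 founders per step against a capacity of 100, migration
#'   0.05, 25 loci, 30 stability generations: strong serial founder
#'   effects and surfing.
#' - `bidirectional_asymmetric`: interior origin, a 30-deme west arm and a
#'   12-deme east arm with faster westward colonization, mirroring a
#'   two-front invasion of unequal reach.
#' - `two_cluster_barrier`: migration suppressed across the lattice
#'   midpoint after colonization passes (a desert-barrier analog).
#'
#' @param name preset name
#' @param seed RNG seed stored in the config
#' @param ... overrides passed to [expansionConfig()]
#' @return an `ExpansionConfig`
#' @export
expansionPreset <- function(name = c("panmixia_null", "strong_founder_west",
                                     "bidirectional_asymmetric",
                                     "two_cluster_barrier"),
                            seed = 1, ...) {
  name <- match.arg(name)
  base <- switch(name,
    panmixia_null = list(nDemes = 1, originIndex = 1, N = 400, nSample = 10,
                         nLoci = 20, stabilityGenerations = 30,
                         spanKm = 1000, jitterOffsetKm = 30),
    strong_founder_west = list(nDemes = 40, originIndex = 40, N = 100,
                               founderSize = 5, migrationRate = 0.05,
                               nLoci = 25, stabilityGenerations = 30,
                               colonizationInterval = 1),
    bidirectional_asymmetric = list(nDemes = 43, originIndex = 31, N = 100,
                                    founderSize = 8, migrationRate = 0.05,
                                    nLoci = 25, stabilityGenerations = 30,
                                    colonizationInterval = c(1, 2)),
    two_cluster_barrier = list(nDemes = 12, originIndex = 12, N = 100,
                               founderSize = 10, migrationRate = 0.1,
                               nLoci = 20, stabilityGenerations = 40,
                               barrierAfterDeme = 6, nSample = 15))
  over <- list(...)
  base[names(over)] <- over
  # keep definitional relations when nDemes is overridden alone
  if ("nDemes" %in% names(over) && !"originIndex" %in% names(over))
    base$originIndex <- switch(name,
      panmixia_null = 1L,
      strong_founder_west = base$nDemes,
      bidirectional_asymmetric = max(2L, as.integer(ceiling(base$nDemes * 0.7))),
      two_cluster_barrier = base$nDemes)
  if (name == "two_cluster_barrier" && "nDemes" %in% names(over) &&
      !"barrierAfterDeme" %in% names(over))
    base$barrierAfterDeme <- max(1L, base$nDemes %/% 2L)
  do.call(expansionConfig, c(base, list(seed = seed)))
}
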