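EARTH_RADIUS_KM <- 6371.0088  # mean spherical radius

gcDistKm <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' PathPolyline: invasion-path polyline with origin
#'
#' An ordered sequence of geographic vertices (longitude, latitude; WGS84
#' decimal degrees) describing the path along which a range expansion
#' proceeded, plus the introduction point ("origin"). Signed path distances
#' are measured from the origin; samples nearer the first vertex than the
#' origin get negative distances, so the path's first vertex defines the
#' "west" side of the expansion.
#'
#' @slot vertices two-column matrix (lon, lat), >= 2 rows
#' @slot origin length-2 numeric (lon, lat)
#' @slot cumLengthKm cumulative great-circle length at each vertex (km)
#' @export
setClass("PathPolyline",
         representation(vertices = "matrix", origin = "numeric",
                        cumLengthKm = "numeric"))

setValidity("PathPolyline", function(object) {
  v <- object@vertices
  if (nrow(v) < 2) return("a path needs at least 2 vertices")
  if (ncol(v) != 2) return("vertices must be a lon/lat matrix")
  if (length(object@origin) != 2) return("origin must be (lon, lat)")
  cl <- object@cumLengthKm
  if (length(cl) != nrow(v)) return("cumulative lengths inconsistent with vertices")
  if (any(diff(cl) <= 0)) return("cumulative lengths must be strictly increasing (zero-length segment?)")
  TRUE
})

setMethod("show", "PathPolyline", function(object) {
  cat(sprintf("PathPolyline: %d vertices, %.1f km total\n",
              nrow(object@vertices), max(object@cumLengthKm)))
  cat(sprintf("  origin: (%.4f, %.4f)\n", object@origin[1], object@origin[2]))
})

#' Construct a PathPolyline
#'
#' @param vertices two-column matrix or data.frame of (longitude, latitude)
#' @param origin length-2 numeric (longitude, latitude) of the introduction
#'   point; should lie on or near the path
#' @return a [PathPolyline-class]
#' @export
pathPolyline <- function(vertices, origin) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  colnames(v) <- c("lon", "lat")
  seg <- if (nrow(v) > 1) gcDistKm(v[-nrow(v), , drop = FALSE], v[-1, , drop = FALSE]) else numeric()
  new("PathPolyline", vertices = v, origin = as.numeric(origin),
      cumLengthKm = c(0, cumsum(seg)))
}

#' Read a path and origin from GeoJSON
#'
#' Accepts a GeoJSON file containing a `LineString` (as bare geometry, a
#' `Feature`, or inside a `FeatureCollection`); the origin `Point` may live
#' in the same FeatureCollection or in a second file.
#'
#' @param path GeoJSON file with the LineString (and optionally the Point)
#' @param originPath optional GeoJSON file with the origin Point
#' @return a [PathPolyline-class]
#' @export
readPathGeoJSON <- function(path, originPath = NULL) {
  geoms <- collectGeometries(jsonlite::fromJSON(path, simplifyVector = FALSE))
  line <- Filter(function(g) identical(g$type, "LineString"), geoms)
  if (!length(line)) stop("no LineString geometry in ", path)
  verts <- do.call(rbind, lapply(line[[1]]$coordinates, function(xy) unlist(xy)[1:2]))
  pts <- Filter(function(g) identical(g$type, "Point"), geoms)
  if (!is.null(originPath)) {
    og <- collectGeometries(jsonlite::fromJSON(originPath, simplifyVector = FALSE))
    pts <- Filter(function(g) identical(g$type, "Point"), og)
  }
  if (!length(pts)) stop("no origin Point found")
  pathPolyline(verts, unlist(pts[[1]]$coordinates)[1:2])
}

collectGeometries <- function(x) {
  if (is.null(x$type)) return(list())
  switch(x$type,
    FeatureCollection = unlist(lapply(x$features, collectGeometries), recursive = FALSE),
    Feature = list(x$geometry),
    list(x))
}

#' Write a path and origin as GeoJSON
#'
#' @param path a [PathPolyline-class]
#' @param file output file
#' @return `file`, invisibly
#' @export
writePathGeoJSON <- function(path, file) {
  fc <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(role = "path"),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(path@vertices)),
                                              function(i) as.numeric(path@vertices[i, ])))),
    list(type = "Feature", properties = list(role = "origin"),
         geometry = list(type = "Point", coordinates = as.numeric(path@origin)))))
  jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Project points onto a path polyline
#'
#' For each point, finds the nearest foot on the polyline: per segment a
#' local planar (equirectangular) frame is used to drop a perpendicular,
#' and the perpendicular offset is the great-circle distance from the point
#' to that foot (spherical Earth, sub-km error at continental scales). Ties
#' between equally near segments resolve to the smaller along-path
#' distance.
#'
#' @param points two-column matrix/data.frame of (longitude, latitude)
#' @param path a [PathPolyline-class]
#' @return data.frame with `along_km` (cumulative path distance to the
#'   foot, from the path's first vertex) and `offset_km`
#' @export
projectToPath <- function(points, path) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  v <- path@vertices
  cum <- path@cumLengthKm
  nseg <- nrow(v) - 1
  R <- EARTH_RADIUS_KM
  deg2rad <- pi / 180
  n <- nrow(pts)
  bestOff <- rep(Inf, n); bestAlong <- rep(NA_real_, n)
  for (k in seq_len(nseg)) {
    A <- v[k, ]; B <- v[k + 1, ]
    phi0 <- deg2rad * (A[2] + B[2]) / 2
    ax <- 0; ay <- 0
    bx <- R * cos(phi0) * deg2rad * (B[1] - A[1])
    by <- R * deg2rad * (B[2] - A[2])
    px <- R * cos(phi0) * deg2rad * (pts[, 1] - A[1])
    py <- R * deg2rad * (pts[, 2] - A[2])
    segLen2 <- bx^2 + by^2
    t <- pmin(1, pmax(0, (px * bx + py * by) / segLen2))
    footLon <- A[1] + t * (B[1] - A[1])
    footLat <- A[2] + t * (B[2] - A[2])
    off <- gcDistKm(pts, cbind(footLon, footLat))
    along <- cum[k] + t * (cum[k + 1] - cum[k])
    better <- off < bestOff - 1e-9 |
      (abs(off - bestOff) <= 1e-9 & along < bestAlong)
    bestOff[better] <- off[better]
    bestAlong[better] <- along[better]
  }
  data.frame(along_km = bestAlong, offset_km = bestOff)
}

#' Linearize sample positions onto the invasion path
#'
#' Projects each located sample onto the path and reports its signed path
#' distance from the origin (`s_km`; negative toward the path's first
#' vertex, i.e. the "west" side) and its perpendicular offset. Samples
#' farther than `maxOffsetKm` from the path are marked not retained;
#' unlocated samples are dropped with a warning.
#'
#' @param ge a [GenotypeExperiment-class] with sample coordinates
#' @param path a [PathPolyline-class]
#' @param maxOffsetKm maximum perpendicular distance (km) a sample may lie
#'   from the path and still be analysed (default 150)
#' @return data.frame: `sample_id`, `s_km`, `offset_km`, `retained`
#' @export
linearizeSamples <- function(ge, path, maxOffsetKm = 150) {
  org <- projectToPath(matrix(path@origin, nrow = 1), path)
  if (org$offset_km > maxOffsetKm)
    stop("configuration error: origin is ", round(org$offset_km, 1),
         " km from the path (max offset ", maxOffsetKm, " km)")
  si <- sampleInfo(ge)
  located <- !is.na(si$longitude) & !is.na(si$latitude)
  if (!any(located)) {
    warning("no located samples to linearize")
    return(data.frame(sample_id = character(), s_km = numeric(),
                      offset_km = numeric(), retained = logical()))
  }
  if (any(!located))
    warning(sum(!located), " unlocated sample(s) dropped from linearization")
  pr <- projectToPath(cbind(si$longitude[located], si$latitude[located]), path)
  data.frame(sample_id = si$sample_id[located],
             s_km = pr$along_km - org$along_km,
             offset_km = pr$offset_km,
             retained = pr$offset_km <= maxOffsetKm,
             stringsAsFactors = FALSE)
}

#' Partition linearized samples into equidistant groups
#'
#' Divides the occupied interval `[min s, max s]` into `nSegments`
#' equal-width half-open bins `[lo, hi)` (the last bin closed) and assigns
#' each retained sample to its bin; empty bins are dropped. A sample
#' sitting exactly on an interior boundary belongs to the right-hand bin.
#'
#' @param lin data.frame from [linearizeSamples()] (only `retained` rows
#'   are used)
#' @param nSegments number of equal-width segments (the study protocol used
#'   18)
#' @return a [GroupPartition-class]
#' @export
partitionEquidistant <- function(lin, nSegments = 18) {
  stopifnot(nSegments >= 1)
  s <- lin[lin$retained, , drop = FALSE]
  if (!nrow(s)) stop("no retained samples to partition")
  lo <- min(s$s_km); hi <- max(s$s_km)
  if (lo == hi) {
    warning("all samples at a single path position; one degenerate group")
    breaks <- c(lo, lo)
    idx <- rep(1L, nrow(s))
  } else {
    breaks <- seq(lo, hi, length.out = nSegments + 1)
    idx <- findInterval(s$s_km, breaks, rightmost.closed = TRUE,
                        all.inside = FALSE)
    idx[idx > nSegments] <- nSegments
  }
  used <- sort(unique(idx))
  gid <- sprintf("G%02d", match(idx, used))
  groups <- do.call(rbind, lapply(seq_along(used), function(j) {
    b <- used[j]
    mem <- s$s_km[idx == b]
    data.frame(group_id = sprintf("G%02d", j), n = length(mem),
               median_s_km = stats::median(mem),
               lo_km = breaks[b], hi_km = breaks[b + 1],
               stringsAsFactors = FALSE)
  }))
  new("GroupPartition",
      samples = data.frame(sample_id = s$sample_id, s_km = s$s_km,
                           group_id = gid, stringsAsFactors = FALSE),
      groups = groups)
}

#' Merge small groups into adjacent neighbours
#'
#' Repeatedly takes the smallest group with fewer than `minN` members and
#' merges it into its smaller adjacent neighbour (ties broken toward the
#' neighbour whose median distance is nearer the origin), until every group
#' has at least `minN` members or a single group remains. Merged segment
#' bounds are the union; medians are recomputed. The study protocol merged
#' groups with fewer than 10 individuals, reducing 18 segments to 14
#' groups.
#'
#' @param p a [GroupPartition-class]
#' @param minN minimum group size (default 10)
#' @return a [GroupPartition-class] with `>=` as many members per group
#' @export
mergeSmallGroups <- function(p, minN = 10) {
  g <- p@groups; s <- p@samples
  repeat {
    if (nrow(g) <= 1 || all(g$n >= minN)) break
    small <- which(g$n < minN)
    i <- small[which.min(g$n[small])]
    nbr <- c(if (i > 1) i - 1L, if (i < nrow(g)) i + 1L)
    if (length(nbr) == 2) {
      j <- if (g$n[nbr[1]] < g$n[nbr[2]]) nbr[1]
           else if (g$n[nbr[2]] < g$n[nbr[1]]) nbr[2]
           else nbr[which.min(abs(g$median_s_km[nbr]))]
    } else j <- nbr
    keep <- min(i, j); drop <- max(i, j)
    s$group_id[s$group_id == g$group_id[drop]] <- g$group_id[keep]
    mem <- s$s_km[s$group_id == g$group_id[keep]]
    g$n[keep] <- length(mem)
    g$median_s_km[keep] <- stats::median(mem)
    g$lo_km[keep] <- min(g$lo_km[c(i, j)])
    g$hi_km[keep] <- max(g$hi_km[c(i, j)])
    g <- g[-drop, , drop = FALSE]
  }
  if (nrow(g) == 1 && any(p@groups$n < minN) && nrow(p@groups) > 1)
    warning("merging exhausted: a single group remains")
  # relabel sequentially along the path
  newIds <- sprintf("G%02d", seq_len(nrow(g)))
  s$group_id <- newIds[match(s$group_id, g$group_id)]
  g$group_id <- newIds
  rownames(g) <- NULL
  new("GroupPartition", samples = s, groups = g)
}

#' Median signed path distance per group
#'
#' @param p a [GroupPartition-class]
#' @return named numeric vector of median `s_km` per group (even group
#'   sizes use the mean of the central pair)
#' @export
groupMedianDistance <- function(p) {
  stats::setNames(p@groups$median_s_km, p@groups$group_id)
}

#' Directional subset of groups
#'
#' Returns the group ids on one side of the origin: `"west"` keeps groups
#' with median signed distance `<= 0`, `"east"` those with `>= 0`. The
#' group containing the origin (median nearest zero) belongs to both
#' subsets.
#'
#' @param p a [GroupPartition-class]
#' @param direction `"west"` or `"east"`
#' @export
directionGroups <- function(p, direction = c("west", "east")) {
  direction <- match.arg(direction)
  med <- groupMedianDistance(p)
  ids <- if (direction == "west") names(med)[med <= 0] else names(med)[med >= 0]
  if (!any(med == 0)) {
    nearest <- names(med)[which.min(abs(med))]
    ids <- union(ids, nearest)
  }
  ids[order(med[ids])]
}
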