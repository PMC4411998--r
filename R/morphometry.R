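# Morphometry: compartment volumes from layer-grown masks, skeleton lengths
# from the 26-connected voxel graph, and the derived weekly statistics
# (relative growth rates of volume, length increments).

#' Root volume per compartment
#'
#' Volume = voxel count x voxel volume (dx dy dz). Stem-seed voxels are
#' never part of a \linkS4class{RootMask}, so they contribute nothing.
#'
#' @param mask a \linkS4class{RootMask}.
#' @param compartment "lower", "upper", "combined", or "all" for a named
#'   vector of the three.
#' @return volume(s) in mm^3; an empty compartment gives 0.
#' @export
compartmentVolume <- function(mask, compartment = "all") {
  stopifnot(is(mask, "RootMask"))
  vox <- prod(mask@spacing)
  inmask <- mask@layer >= 0L
  lower <- sum(inmask & mask@compartment == 1L) * vox
  upper <- sum(inmask & mask@compartment == 2L) * vox
  out <- c(lower = lower, upper = upper, combined = lower + upper)
  if (compartment == "all") out else unname(out[compartment])
}

#' Relative growth rate between consecutive weekly volumes
#'
#' \deqn{(V_{t+1} - V_t) / V_t}
#'
#' @param vol_t volume at week t, mm^3; must be > 0.
#' @param vol_t1 volume at week t + 1, mm^3.
#' @return dimensionless rate.
#' @examples
#' relativeGrowthRate(10, 15)  # 0.5
#' @export
relativeGrowthRate <- function(vol_t, vol_t1) {
  if (is.na(vol_t) || vol_t <= 0)
    stop("relative growth rate undefined: week-t volume must be > 0")
  (vol_t1 - vol_t) / vol_t
}

#' Skeleton length per compartment
#'
#' The skeleton graph (voxels adjacent under 26-connectivity) is decomposed
#' into maximal unbranched runs between endpoints and branch voxels; each
#' run's length is the sum of Euclidean chords between voxel centers spaced
#' \code{chord} voxels apart along the run (anisotropic spacing respected),
#' plus the remainder chord. Each skeleton edge contributes to exactly one
#' run, so branch points are never double counted. With \code{chord = 1}
#' this reduces to the plain per-edge sum, which systematically
#' overestimates the length of digitized curves by the staircase effect;
#' the default window of 4 voxels removes most of that bias while leaving
#' straight axis-aligned and single-diagonal paths exact.
#'
#' @param skel a 1-voxel-thick \linkS4class{SkeletonGraph}.
#' @param compartment "lower", "upper", "combined", "all" (named vector),
#'   or "any" to ignore labels.
#' @param chord chord window in voxels (>= 1).
#' @return length(s) in mm.
#' @export
skeletonLength <- function(skel, compartment = "all", chord = 4L) {
  stopifnot(is(skel, "SkeletonGraph"), chord >= 1L)
  validObject(skel)  # enforces 1-voxel thickness
  measure <- function(rows) {
    if (length(rows) < 2L) return(0)
    coords <- skel@coords[rows, , drop = FALSE]
    edges <- cpp_adjacency_pairs(coords - 1L, as.integer(skel@dims))
    if (!nrow(edges)) return(0)
    pos <- sweep(coords - 0.5, 2, skel@spacing, "*")
    .pathChordLength(nrow(coords), edges, pos, chord)
  }
  if (compartment == "any") return(measure(seq_len(nrow(skel@coords))))
  lo <- measure(which(skel@compartment %in% "lower"))
  up <- measure(which(skel@compartment %in% "upper"))
  out <- c(lower = lo, upper = up, combined = lo + up)
  if (compartment == "all") out else unname(out[compartment])
}

# decompose an undirected voxel graph into maximal degree-2 runs and sum
# chord-resampled lengths; cycles without junctions are walked from an
# arbitrary voxel
.pathChordLength <- function(n, edges, pos, chord) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  chord_len <- function(path) {
    m <- length(path)
    anchors <- unique(c(seq(1L, m, by = chord), m))
    p <- pos[path[anchors], , drop = FALSE]
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  used_env <- new.env(hash = TRUE, parent = emptyenv())
  total <- 0
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = used_env)
    prev <- start; cur <- nxt
    while (deg[cur] == 2L) {
      nn <- setdiff(adj[[cur]], prev)
      if (!length(nn)) break
      if (exists(ekey(cur, nn[1]), envir = used_env, inherits = FALSE)) break
      assign(ekey(cur, nn[1]), TRUE, envir = used_env)
      path <- c(path, nn[1])
      prev <- cur; cur <- nn[1]
    }
    path
  }
  junctions <- which(deg != 2L & deg > 0L)
  for (j in junctions) for (nb in adj[[j]]) {
    if (!exists(ekey(j, nb), envir = used_env, inherits = FALSE))
      total <- total + chord_len(walk(j, nb))
  }
  # leftover pure cycles (every voxel degree 2)
  for (v in which(deg == 2L)) for (nb in adj[[v]]) {
    if (!exists(ekey(v, nb), envir = used_env, inherits = FALSE))
      total <- total + chord_len(walk(v, nb))
  }
  total
}

#' Root length increment between consecutive weeks
#'
#' @param len_t,len_t1 total root lengths (mm) at weeks t and t + 1,
#'   both >= 0.
#' @return \code{len_t1 - len_t} in mm; a negative increment is allowed
#'   but triggers a warning (roots should not shrink).
#' @examples
#' lengthIncrement(100, 130)  # 30
#' @export
lengthIncrement <- function(len_t, len_t1) {
  if (len_t < 0 || len_t1 < 0) stop("lengths must be >= 0")
  inc <- len_t1 - len_t
  if (inc < 0)
    warning("negative length increment (", inc, " mm): measured root ",
            "length decreased between weeks")
  inc
}
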