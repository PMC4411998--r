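# Root isolation: threshold segmentation, 3-D thinning, compartment and
# order labeling, and HU-gated layer growing. Roots are radiolucent
# relative to dry sand, so they sit far below the sand HU peak; primary
# roots are grown up to four 26-neighbor layers at <= 850 HU and secondary
# roots up to two layers at <= 950 HU, with the stem-seed region excluded.

.COMP_CODE <- c(lower = 1L, upper = 2L, `stem-seed` = 3L)
.ORD_CODE <- c(primary = 1L, secondary = 2L)

#' Segment low-attenuation root material from a CT volume
#'
#' Thresholds the volume at \code{hu_max} and keeps 26-connected components
#' of at least \code{min_component} voxels, discarding speckle.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param hu_max inclusive HU ceiling for root material (default 850).
#' @param min_component smallest component size kept, in voxels.
#' @return logical 3-D array mask.
#' @export
segmentRootMaterial <- function(grid, hu_max = 850, min_component = 50) {
  stopifnot(is(grid, "VoxelGrid"))
  v <- gridValues(grid)
  mask <- v <= hu_max
  if (!any(mask)) {
    warning("segmentation produced an empty mask at hu_max = ", hu_max)
    return(array(FALSE, dim(v)))
  }
  if (min_component > 1) {
    lab <- cpp_label_components26(as.logical(mask), as.integer(dim(v)))
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component)
    mask <- array(lab %in% keep & lab > 0L, dim(v))
    if (!any(mask))
      warning("all components smaller than min_component = ", min_component)
  }
  mask
}

#' Thin a binary mask to a 1-voxel skeleton
#'
#' Topology-preserving 3-D thinning: each pass peels voxels that are simple
#' in the (26, 6) sense over the eight parity subfields, preserving curve
#' endpoints, with sequential re-checks so the number of 26-connected
#' components never changes. Short terminal spurs (a thinning artifact on
#' thick branches) are then pruned.
#'
#' @param mask logical 3-D array (non-empty).
#' @param spacing voxel spacing in mm carried into the skeleton.
#' @param prune_spurs prune terminal branches shorter than this many voxels
#'   (0 disables pruning).
#' @return an unlabeled \linkS4class{SkeletonGraph}.
#' @export
skeletonizeMask <- function(mask, spacing = c(0.35, 0.35, 0.4),
                            prune_spurs = 5L) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D logical array")
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  dims <- dim(mask)
  cur <- as.logical(mask)
  # thinning and pruning alternate to a fixed point: pruning a frozen spur
  # exposes voxels that become simple, and re-thinning removes them
  repeat {
    thin <- cpp_thin3d(cur, as.integer(dims))
    coords <- which(array(thin, dims), arr.ind = TRUE)
    colnames(coords) <- NULL
    mode(coords) <- "integer"
    if (prune_spurs <= 0L) break
    pruned <- .pruneSpurs(coords, dims, prune_spurs)
    if (nrow(pruned) == nrow(coords)) break
    coords <- pruned
    cur <- array(FALSE, dims)
    cur[coords] <- TRUE
    cur <- as.logical(cur)
  }
  new("SkeletonGraph", coords = coords, dims = as.integer(dims),
      spacing = as.numeric(spacing),
      compartment = rep(NA_character_, nrow(coords)),
      order = rep(NA_character_, nrow(coords)),
      attachments = integer())
}

# remove terminal branches of fewer than min_spur voxels (measured from a
# branch voxel, exclusive); iterates because pruning can expose new spurs
.pruneSpurs <- function(coords, dims, min_spur) {
  repeat {
    n <- nrow(coords)
    if (n < 3L) return(coords)
    edges <- cpp_adjacency_pairs(coords - 1L, as.integer(dims))
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    drop <- logical(n)
    for (ep in which(deg == 1L)) {
      path <- ep
      cur <- ep; prev <- 0L
      while (length(path) <= min_spur) {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        if (length(nxt) != 1L) break  # reached a branch point or isolation
        prev <- cur; cur <- nxt
        if (deg[cur] >= 3L) { drop[path] <- TRUE; break }
        path <- c(path, cur)
      }
    }
    if (!any(drop)) return(coords)
    coords <- coords[!drop, , drop = FALSE]
  }
}

#' Stem-seed exclusion region
#'
#' The below-ground stem is modeled as a vertical cylinder around the stem
#' axis down to the seed, plus a ball around the seed. The region is
#' excluded from all root measures (the stem and seed are not roots).
#'
#' @param dims grid dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param stem_center (x, y) of the stem axis in mm.
#' @param seed_z seed depth in mm.
#' @param stem_radius cylinder radius in mm.
#' @param seed_radius seed-ball radius in mm.
#' @return logical 3-D array, TRUE inside the stem-seed region.
#' @export
stemSeedRegion <- function(dims, spacing, stem_center, seed_z,
                           stem_radius = 2, seed_radius = 3) {
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  r2 <- outer((cx - stem_center[1])^2, (cy - stem_center[2])^2, "+")
  reg <- array(FALSE, dims)
  in_cyl <- r2 <= stem_radius^2
  for (k in which(cz <= seed_z)) reg[, , k] <- in_cyl
  # seed capsule: radius seed_radius around the stem axis from a little
  # above the seed down to the seed, with spherical caps
  z_hi <- seed_z; z_lo <- seed_z - 2
  for (k in seq_len(dims[3])) {
    dz <- if (cz[k] > z_hi) cz[k] - z_hi else if (cz[k] < z_lo) z_lo - cz[k] else 0
    if (dz <= seed_radius)
      reg[, , k] <- reg[, , k] | (r2 <= seed_radius^2 - dz^2)
  }
  reg
}

#' Label skeleton voxels by compartment and branching order
#'
#' Voxels inside the stem-seed region are labeled \code{stem-seed}. Each
#' remaining 26-connected component is traced from its attachment point
#' (a voxel adjacent to the stem-seed region): components attaching above
#' the seed (smaller z, the pot being scanned stem first) become
#' \code{upper}, the rest \code{lower}. Within a component the primary path
#' is the maximal-length geodesic from the attachment point (ties broken by
#' longer physical path, then lowest voxel index); voxels on it are
#' \code{primary}, branches off it \code{secondary}. Components with no
#' attachment are labeled orphan (NA) and excluded, with a warning.
#'
#' @param skel an unlabeled \linkS4class{SkeletonGraph}.
#' @param stem_center (x, y) of the stem axis, mm.
#' @param seed_z seed depth, mm.
#' @param stem_radius,seed_radius stem-seed region geometry, mm.
#' @return the labeled \linkS4class{SkeletonGraph}.
#' @export
classifyCompartments <- function(skel, stem_center, seed_z,
                                 stem_radius = 2, seed_radius = 3) {
  coords <- skel@coords
  n <- nrow(coords)
  if (!n) stop("empty skeleton")
  sp <- skel@spacing
  pos <- sweep(coords - 0.5, 2, sp, "*")  # voxel centers in mm

  region <- stemSeedRegion(skel@dims, sp, stem_center, seed_z,
                           stem_radius, seed_radius)
  idx <- coords[, 1] + skel@dims[1] * (coords[, 2] - 1L) +
         prod(skel@dims[1:2]) * (coords[, 3] - 1L)
  is_stem <- region[idx]

  compartment <- rep(NA_character_, n)
  ord <- rep(NA_character_, n)
  compartment[is_stem] <- "stem-seed"
  ord[is_stem] <- "primary"

  edges <- skeletonEdges(skel)
  # attachment voxels: non-stem voxels 26-adjacent to a stem voxel
  att <- logical(n)
  if (nrow(edges)) {
    a <- edges[, 1]; b <- edges[, 2]
    att[a[!is_stem[a] & is_stem[b]]] <- TRUE
    att[b[!is_stem[b] & is_stem[a]]] <- TRUE
  }

  # components of the non-stem subgraph
  keep <- which(!is_stem)
  if (length(keep)) {
    sub_e <- edges[!is_stem[edges[, 1]] & !is_stem[edges[, 2]], , drop = FALSE]
    remap <- integer(n); remap[keep] <- seq_along(keep)
    w <- sqrt(rowSums((pos[sub_e[, 1], , drop = FALSE] -
                       pos[sub_e[, 2], , drop = FALSE])^2))
    g <- igraph::make_empty_graph(length(keep), directed = FALSE)
    if (nrow(sub_e))
      g <- igraph::add_edges(g, rbind(remap[sub_e[, 1]], remap[sub_e[, 2]]))
    comp_id <- igraph::components(g)$membership
    orphans <- 0L
    for (cid in unique(comp_id)) {
      members <- keep[comp_id == cid]
      catt <- members[att[members]]
      if (!length(catt)) {
        orphans <- orphans + 1L
        next
      }
      # component graph with physical edge weights
      msel <- comp_id[remap[sub_e[, 1]]] == cid
      ce <- sub_e[msel, , drop = FALSE]
      cw <- w[msel]
      lmap <- integer(n); lmap[members] <- seq_along(members)
      gc <- igraph::make_empty_graph(length(members), directed = FALSE)
      if (nrow(ce)) {
        gc <- igraph::add_edges(gc, rbind(lmap[ce[, 1]], lmap[ce[, 2]]))
        igraph::E(gc)$weight <- cw
      }
      # primary = the maximal geodesic from each attachment point (ties:
      # longer physical path, then lowest voxel index)
      ord[members] <- "secondary"
      d_hop_all <- igraph::distances(gc, v = lmap[catt], weights = NA)
      d_len_all <- igraph::distances(gc, v = lmap[catt])
      # compartment per voxel from the side of the seed its geodesically
      # nearest attachment sits on (z points down: above the seed =
      # smaller z); a component fusing upper and lower roots is thereby
      # split along the junction rather than mislabeled wholesale
      att_side <- ifelse(pos[catt, 3] < seed_z, "upper", "lower")
      if (length(catt) == 1L) {
        compartment[members] <- att_side
      } else {
        nearest <- apply(d_len_all, 2, which.min)
        compartment[members] <- att_side[nearest]
      }
      is_primary <- logical(length(members))
      # longest axes first; each subsequent attachment aims for the
      # farthest voxel not yet claimed by a primary path, so merged axes
      # are each traced from their own attachment
      for (ai in order(-apply(d_len_all, 1, function(d) max(d[is.finite(d)])),
                       catt)) {
        d_hop <- d_hop_all[ai, ]; d_len <- d_len_all[ai, ]
        cand <- which(is.finite(d_hop) & !is_primary)
        if (!length(cand)) cand <- which(is.finite(d_hop))
        far <- cand[d_hop[cand] == max(d_hop[cand])]
        if (length(far) > 1L) far <- far[order(-d_len[far], members[far])][1L]
        path <- igraph::shortest_paths(gc, from = lmap[catt[ai]], to = far[1L],
                                       weights = NA)$vpath[[1L]]
        is_primary[as.integer(path)] <- TRUE
      }
      ord[members[is_primary]] <- "primary"
    }
    if (orphans > 0L)
      warning(orphans, " skeleton component(s) have no attachment to the ",
              "stem and were excluded as orphans")
  }

  new("SkeletonGraph", coords = coords, dims = skel@dims, spacing = sp,
      compartment = compartment, order = ord,
      attachments = which(att & !is.na(compartment)))
}

#' Grow a labeled skeleton into root volumes by HU-gated layer growing
#'
#' Iterative dilation, one 26-neighbor layer at a time: layer L + 1 admits
#' voxels adjacent to layer <= L of the same order whose HU does not exceed
#' that order's ceiling, up to the order's layer cap (primary: 4 layers at
#' 850 HU; secondary: 2 layers at 950 HU). The stem-seed region and orphan
#' voxels are excluded; within a layer the lowest-index claim wins.
#'
#' @param skel a labeled \linkS4class{SkeletonGraph}.
#' @param grid the \linkS4class{VoxelGrid} the skeleton came from.
#' @param rules list with \code{primary} and \code{secondary} entries, each
#'   \code{list(max_layers =, hu_max =)}.
#' @param exclude optional extra logical exclusion array (e.g. the
#'   stem-seed region from \code{\link{stemSeedRegion}}).
#' @return a \linkS4class{RootMask}.
#' @export
expandSkeleton <- function(skel, grid,
                           rules = list(primary = list(max_layers = 4, hu_max = 850),
                                        secondary = list(max_layers = 2, hu_max = 950)),
                           exclude = NULL) {
  stopifnot(is(skel, "SkeletonGraph"), is(grid, "VoxelGrid"))
  if (!identical(as.integer(skel@dims), as.integer(gridDims(grid))))
    stop("skeleton and volume dimensions differ")
  labeled <- !is.na(skel@compartment)
  if (!any(labeled & skel@compartment != "stem-seed"))
    stop("skeleton must be labeled (run classifyCompartments first)")
  dims <- skel@dims
  comp <- array(0L, dims); ordr <- array(0L, dims); layer <- array(-1L, dims)
  excl <- if (is.null(exclude)) array(FALSE, dims) else exclude
  idx <- skel@coords[, 1] + dims[1] * (skel@coords[, 2] - 1L) +
         prod(dims[1:2]) * (skel@coords[, 3] - 1L)
  root_vox <- labeled & skel@compartment %in% c("lower", "upper")
  comp[idx[root_vox]] <- .COMP_CODE[skel@compartment[root_vox]]
  ordr[idx[root_vox]] <- .ORD_CODE[skel@order[root_vox]]
  layer[idx[root_vox]] <- 0L
  excl[idx[skel@compartment %in% "stem-seed"]] <- TRUE
  excl[idx[!labeled]] <- TRUE  # orphans

  res <- cpp_expand_layers(as.numeric(gridValues(grid)), as.integer(comp),
                           as.integer(ordr), as.integer(layer),
                           as.logical(excl), as.integer(dims),
                           c(rules$primary$hu_max, rules$secondary$hu_max),
                           as.integer(c(rules$primary$max_layers,
                                        rules$secondary$max_layers)))
  new("RootMask",
      compartment = array(res$compartment, dims),
      order = array(res$order, dims),
      layer = array(res$layer, dims),
      spacing = skel@spacing,
      provenance = sprintf("expandSkeleton: %d skeleton voxels, primary <= %d layers @ %g HU, secondary <= %d layers @ %g HU",
                           sum(root_vox), rules$primary$max_layers,
                           rules$primary$hu_max, rules$secondary$max_layers,
                           rules$secondary$hu_max))
}
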