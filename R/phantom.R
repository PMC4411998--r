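# Synthetic root-architecture generator and CT phantom renderer.
# The generator emulates the study system: a corn seedling in a sand-filled
# pot, scanned weekly for three weeks; embryonic lower and upper primary
# axes plus secondary laterals; under salt stress the upper axes initiate a
# week late and elongation/branching are reduced.

#' Growth-model parameters for the architecture simulator
#'
#' @param n_lower_axes number of lower (below-seed) primary axes.
#' @param n_upper_axes number of upper (above-seed) primary axes.
#' @param elongation_rate primary-axis tip speed, mm per week.
#' @param lateral_elongation_rate secondary-axis tip speed, mm per week.
#' @param branch_rate expected laterals per mm of eligible parent axis per
#'   week (Poisson intensity).
#' @param branch_delay weeks a parent segment must age before laterals
#'   appear on it.
#' @param upper_onset_week week index at which upper axes initiate (>= 1).
#' @param gravitropism downward bias of tip growth, in [0, 1].
#' @param radius_primary,radius_secondary root radii in mm.
#' @param rng_seed integer seed for the architecture RNG stream.
#' @return a validated list of class \code{GrowthParams}.
#' @export
growthParams <- function(n_lower_axes = 3, n_upper_axes = 2,
                         elongation_rate = 15, lateral_elongation_rate = 5,
                         branch_rate = 0.08, branch_delay = 1,
                         upper_onset_week = 1, gravitropism = 0.6,
                         radius_primary = 0.7, radius_secondary = 0.4,
                         rng_seed = 1L) {
  p <- list(n_lower_axes = n_lower_axes, n_upper_axes = n_upper_axes,
            elongation_rate = elongation_rate,
            lateral_elongation_rate = lateral_elongation_rate,
            branch_rate = branch_rate, branch_delay = branch_delay,
            upper_onset_week = upper_onset_week, gravitropism = gravitropism,
            radius_primary = radius_primary,
            radius_secondary = radius_secondary,
            rng_seed = as.integer(rng_seed))
  rates <- c(p$elongation_rate, p$lateral_elongation_rate, p$branch_rate)
  if (any(rates < 0)) stop("growth rates must be >= 0")
  if (p$upper_onset_week < 1) stop("upper_onset_week must be >= 1")
  if (p$radius_primary <= 0 || p$radius_secondary <= 0)
    stop("radii must be > 0 mm")
  if (p$gravitropism < 0 || p$gravitropism > 1)
    stop("gravitropism must lie in [0, 1]")
  class(p) <- "GrowthParams"
  p
}

#' Treatment presets for the simulator
#'
#' \code{controlPreset} emulates optimally watered seedlings: upper axes
#' present from week 1 and full elongation/branching. \code{saltPreset}
#' emulates a 100 mM NaCl salt shock: upper-axis onset delayed to week 2,
#' with reduced elongation and lateral branching.
#'
#' @param rng_seed integer seed for the architecture RNG stream.
#' @return a \code{GrowthParams} list.
#' @export
controlPreset <- function(rng_seed = 1L) growthParams(rng_seed = rng_seed)

#' @rdname controlPreset
#' @export
saltPreset <- function(rng_seed = 1L) {
  growthParams(elongation_rate = 9, lateral_elongation_rate = 3.5,
               branch_rate = 0.03, upper_onset_week = 2,
               rng_seed = rng_seed)
}

#' CT phantom rendering specification
#'
#' Default HU means put root material well below the 850 HU primary-root
#' threshold and dry sand well above the 950 HU secondary-root threshold,
#' so that threshold-gated layer growing separates the classes.
#'
#' @param dims grid dimensions (nx, ny, nz) in voxels; desk-scale default
#'   128 x 128 x 150 (the full clinical 512 x 512 x 300 is supported).
#' @param spacing voxel spacing in mm.
#' @param hu_root mean HU of root material.
#' @param hu_sand mean HU of the sand matrix.
#' @param noise_sd sensor noise standard deviation, HU.
#' @param partial_volume logical; blend HU linearly across the root-sand
#'   interface (one half-voxel shell) instead of a hard edge.
#' @return a validated list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(dims = c(128L, 128L, 150L),
                        spacing = c(0.35, 0.35, 0.4),
                        hu_root = 200, hu_sand = 1200, noise_sd = 60,
                        partial_volume = FALSE) {
  s <- list(dims = as.integer(dims), spacing = as.numeric(spacing),
            hu_root = hu_root, hu_sand = hu_sand, noise_sd = noise_sd,
            partial_volume = isTRUE(partial_volume))
  if (!(s$hu_root < 850 && 950 < s$hu_sand))
    stop("need hu_root < 850 and hu_sand > 950 for the isolation thresholds ",
         "to separate root from sand")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(s$dims) != 3L || any(s$dims < 1L)) stop("dims must be 3 positive integers")
  class(s) <- "PhantomSpec"
  s
}

# evaluate expr under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

#' Grow a stochastic root architecture with weekly snapshots
#'
#' Discrete weekly elongation of axis tips along a heading vector with a
#' gravitropic downward bias plus angular jitter; secondary laterals are
#' spawned as a Poisson process along primary segments older than
#' \code{branch_delay}. Lower axes start at the seed at week 1; upper axes
#' start on the below-ground stem above the seed at \code{upper_onset_week}.
#' The same seed always yields the same tree, and snapshots are nested
#' (roots only grow).
#'
#' The z axis points downward (slice 1 = top of pot, stem end), so "above
#' the seed" means smaller z.
#'
#' @param params a \code{\link{growthParams}} list.
#' @param n_weeks number of weekly snapshots (>= 1).
#' @param extent physical grid extent (mm) the tree must stay inside;
#'   tips are deflected at a margin inside the boundary.
#' @param seed_depth seed depth below the top of the grid, mm.
#' @return an \linkS4class{ArchitectureTree}.
#' @export
growArchitecture <- function(params, n_weeks = 3,
                             extent = c(44.8, 44.8, 60),
                             seed_depth = 10) {
  stopifnot(inherits(params, "GrowthParams"), n_weeks >= 1)
  .withSeed(params$rng_seed, .growArchitecture(params, n_weeks, extent, seed_depth))
}

.growArchitecture <- function(p, n_weeks, extent, seed_depth) {
  cx <- extent[1] / 2; cy <- extent[2] / 2
  margin <- 2 * p$radius_primary + 0.8
  step <- 1.5      # mm per growth step
  jitter_sd <- 0.22  # rad-scale angular jitter per step

  nodes <- data.frame(id = integer(), compartment = character(),
                      order = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(), parent = integer(),
                      birth_week = integer(), stringsAsFactors = FALSE)
  add_node <- function(compartment, order, pos, radius, parent, week) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, compartment, order, pos[1], pos[2], pos[3],
                         radius, parent, as.integer(week))
    id
  }

  # stem-seed chain: below-ground stem from near the top down to the seed
  seed_r <- 2.5
  stem_top <- c(cx, cy, 1.5)
  root_id <- add_node("stem-seed", "primary", stem_top, 1.2, NA_integer_, 1L)
  stem_ids <- root_id
  nz_steps <- seq(stem_top[3] + 2, seed_depth - 2, by = 2)
  for (z in nz_steps)
    stem_ids <- c(stem_ids, add_node("stem-seed", "primary", c(cx, cy, z),
                                     1.2, stem_ids[length(stem_ids)], 1L))
  # the seed itself, a thicker ball at seed_depth
  stem_ids <- c(stem_ids, add_node("stem-seed", "primary",
                                   c(cx, cy, seed_depth), seed_r,
                                   stem_ids[length(stem_ids)], 1L))
  seed_id <- stem_ids[length(stem_ids)]

  # active tips: list of (node id, heading, compartment, order, rate)
  tips <- list()
  new_axis <- function(at_id, heading, compartment, order, rate, week) {
    tips[[length(tips) + 1L]] <<- list(id = at_id, heading = .unit(heading),
                                       compartment = compartment,
                                       order = order, rate = rate,
                                       born = week)
  }

  spawn_primaries <- function(compartment, n_axes, week) {
    if (n_axes < 1 || p$elongation_rate <= 0) return()
    for (a in seq_len(n_axes)) {
      # evenly spaced azimuths (jittered) keep the axes from colliding
      phi <- 2 * pi * (a - 1) / n_axes + runif(1, -0.3, 0.3) +
             (if (compartment == "upper") pi / n_axes else 0)
      if (compartment == "lower") {
        # downward cone from the seed; an anchor node just outside the
        # seed ball keeps neighboring axes from fusing at their exits
        tilt <- runif(1, 0.25, 0.55)
        h <- c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
        seed_pos <- unlist(nodes[seed_id, c("x", "y", "z")], use.names = FALSE)
        anchor <- add_node("lower", "primary", seed_pos + 3.4 * h,
                           p$radius_primary, seed_id, week)
        new_axis(anchor, h, "lower", "primary", p$elongation_rate, week)
      } else {
        # outward, near-horizontal, from the stem above the seed; upper
        # axes form a shallow distinct system
        at <- stem_ids[max(1L, length(stem_ids) - 2L)]
        h <- c(cos(phi), sin(phi), 0.12)
        new_axis(at, h, "upper", "primary", p$elongation_rate, week)
      }
    }
  }

  grow_tip <- function(tip, week) {
    pos <- unlist(nodes[tip$id, c("x", "y", "z")], use.names = FALSE)
    heading <- tip$heading
    radius <- if (tip$order == "primary") p$radius_primary else p$radius_secondary
    n_steps <- max(0L, round(tip$rate / step))
    parent <- tip$id
    for (s in seq_len(n_steps)) {
      # upper axes are only weakly gravitropic, keeping the two embryonic
      # systems spatially distinct
      g <- if (tip$compartment == "upper") p$gravitropism / 5
           else if (tip$order == "primary") p$gravitropism
           else p$gravitropism / 2
      heading <- .unit((1 - g) * heading + g * c(0, 0, 1) +
                       rnorm(3, 0, jitter_sd))
      cand <- pos + step * heading
      # deflect away from the boundary
      for (ax in 1:3) {
        if (cand[ax] < margin) { heading[ax] <- abs(heading[ax]); }
        if (cand[ax] > extent[ax] - margin) { heading[ax] <- -abs(heading[ax]) }
      }
      # the upper system stays shallow (distinct from the lower system):
      # deflect upper tips that descend past the seed level
      if (tip$compartment == "upper" && cand[3] > seed_depth + 2)
        heading[3] <- -abs(heading[3])
      # roots do not grow into the stem: radial repulsion near the stem
      # axis above the seed
      radial <- cand[1:2] - c(cx, cy)
      rd <- sqrt(sum(radial^2))
      if (cand[3] < seed_depth + 2 && rd < 3.5)
        heading <- .unit(heading + c(0.8 * radial / max(rd, 0.5), 0))
      heading <- .unit(heading)
      pos <- pmin(pmax(pos + step * heading, margin), extent - margin)
      parent <- add_node(tip$compartment, tip$order, pos, radius, parent, week)
    }
    tip$id <- parent
    tip$heading <- heading
    tip
  }

  for (week in seq_len(n_weeks)) {
    if (week == 1L) spawn_primaries("lower", p$n_lower_axes, week)
    if (week == p$upper_onset_week) spawn_primaries("upper", p$n_upper_axes, week)

    # elongate every active tip
    tips <- lapply(tips, grow_tip, week = week)

    # laterals on primary segments old enough to branch
    if (p$branch_rate > 0) {
      prim <- nodes[nodes$order == "primary" &
                    nodes$compartment %in% c("lower", "upper") &
                    nodes$birth_week <= week - p$branch_delay, , drop = FALSE]
      for (r in seq_len(nrow(prim))) {
        par_row <- prim[r, ]
        pid <- par_row$parent
        if (is.na(pid)) next
        seg_len <- sqrt(sum((unlist(par_row[c("x", "y", "z")]) -
                             unlist(nodes[pid, c("x", "y", "z")]))^2))
        n_lat <- rpois(1, p$branch_rate * seg_len)
        for (l in seq_len(n_lat)) {
          phi <- runif(1, 0, 2 * pi)
          # laterals of the shallow upper system stay near-horizontal
          zb <- if (par_row$compartment == "upper") runif(1, -0.1, 0.3)
                else runif(1, 0.1, 0.8)
          h <- .unit(c(cos(phi), sin(phi), zb))
          new_axis(par_row$id, h, par_row$compartment, "secondary",
                   p$lateral_elongation_rate, week)
        }
      }
    }
  }

  new("ArchitectureTree", nodes = nodes)
}

#' Extract the node table of a weekly snapshot
#'
#' @param tree an \linkS4class{ArchitectureTree}.
#' @param week week index; nodes with \code{birth_week <= week} exist.
#' @return data.frame of nodes present at that week.
#' @export
treeSnapshot <- function(tree, week) {
  nd <- treeNodes(tree)
  nd[nd$birth_week <= week, , drop = FALSE]
}

#' Ground-truth root length of a snapshot
#'
#' Sum of segment lengths whose child node belongs to a root compartment,
#' including the attachment segment from the stem.
#'
#' @param tree an \linkS4class{ArchitectureTree}.
#' @param week week index.
#' @param compartment "lower", "upper", or "both".
#' @return length in mm.
#' @export
trueLength <- function(tree, week, compartment = "both") {
  nd <- treeSnapshot(tree, week)
  keep <- nd$compartment %in% (if (compartment == "both") c("lower", "upper")
                               else compartment)
  nd2 <- nd[keep & !is.na(nd$parent), , drop = FALSE]
  if (!nrow(nd2)) return(0)
  pp <- match(nd2$parent, nd$id)
  sqrt((nd2$x - nd$x[pp])^2 + (nd2$y - nd$y[pp])^2 +
       (nd2$z - nd$z[pp])^2) |> sum()
}

#' Render a tree snapshot into a CT phantom
#'
#' Voxels whose center lies within the local root radius of any root
#' segment receive HU drawn from Normal(hu_root, noise_sd); all other
#' voxels from Normal(hu_sand, noise_sd). Truth labels record compartment
#' (1 lower, 2 upper, 3 stem-seed) and order (1 primary, 2 secondary) per
#' claimed voxel; the stem-seed region is rendered and labeled separately
#' and overlapping claims go to the earlier node (stem first).
#'
#' The noise RNG stream is separate from the architecture stream, so the
#' same plant can be re-imaged with fresh noise.
#'
#' @param tree an \linkS4class{ArchitectureTree}.
#' @param week snapshot to render.
#' @param spec a \code{\link{phantomSpec}} list.
#' @param rng_seed integer seed for the noise stream.
#' @return list with elements \code{grid} (a \linkS4class{VoxelGrid}),
#'   \code{compartment} and \code{order} (integer truth-label arrays).
#' @export
voxelizePhantom <- function(tree, week, spec = phantomSpec(), rng_seed = 1L) {
  stopifnot(is(tree, "ArchitectureTree"), inherits(spec, "PhantomSpec"))
  nd <- treeSnapshot(tree, week)
  dims <- spec$dims; sp <- spec$spacing
  ext <- dims * sp

  out <- nd$x - nd$radius < 0 | nd$y - nd$radius < 0 | nd$z - nd$radius < 0 |
         nd$x + nd$radius > ext[1] | nd$y + nd$radius > ext[2] |
         nd$z + nd$radius > ext[3]
  if (any(out))
    stop("tree extends outside the grid extent; offending node ids: ",
         paste(nd$id[out], collapse = ", "))

  comp <- array(0L, dims)
  ord <- array(0L, dims)
  comp_code <- c(lower = 1L, upper = 2L, `stem-seed` = 3L)
  ord_code <- c(primary = 1L, secondary = 2L)

  # render stem-seed nodes first so they take precedence at junctions
  nd <- nd[order(match(nd$compartment, c("stem-seed", "lower", "upper")),
                 nd$id), , drop = FALSE]
  for (r in seq_len(nrow(nd))) {
    row <- nd[r, ]
    pid <- row$parent
    p1 <- c(row$x, row$y, row$z)
    p0 <- if (is.na(pid)) p1 else {
      pr <- treeNodes(tree)[pid, ]
      c(pr$x, pr$y, pr$z)
    }
    hit <- .capsuleVoxels(p0, p1, row$radius, dims, sp)
    if (!nrow(hit)) next
    idx <- hit[, 1] + dims[1] * (hit[, 2] - 1L) +
           dims[1] * dims[2] * (hit[, 3] - 1L)
    fresh <- comp[idx] == 0L
    comp[idx[fresh]] <- comp_code[[row$compartment]]
    ord[idx[fresh]] <- ord_code[[row$order]]
  }

  vals <- .withSeed(rng_seed, {
    v <- array(rnorm(prod(dims), spec$hu_sand, spec$noise_sd), dims)
    inroot <- comp > 0L
    v[inroot] <- v[inroot] - spec$hu_sand + spec$hu_root
    if (spec$partial_volume) {
      # one-shell linear blend across the interface
      shell <- .dilate26(inroot, dims) & !inroot
      v[shell] <- v[shell] - (spec$hu_sand - spec$hu_root) / 2
    }
    v
  })
  list(grid = VoxelGrid(vals, spacing = sp), compartment = comp, order = ord)
}

# voxel centers within `radius` of segment p0-p1; returns (i, j, k) rows
.capsuleVoxels <- function(p0, p1, radius, dims, sp) {
  lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
  i0 <- pmax(1L, floor(lo / sp + 0.5)); i1 <- pmin(dims, ceiling(hi / sp + 0.5))
  if (any(i0 > i1)) return(matrix(integer(), 0, 3))
  gx <- (i0[1]:i1[1] - 0.5) * sp[1]
  gy <- (i0[2]:i1[2] - 0.5) * sp[2]
  gz <- (i0[3]:i1[3] - 0.5) * sp[3]
  g <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 < 1e-18) {
    dist2 <- (g$x - p0[1])^2 + (g$y - p0[2])^2 + (g$z - p0[3])^2
  } else {
    t <- ((g$x - p0[1]) * d[1] + (g$y - p0[2]) * d[2] + (g$z - p0[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (g$x - (p0[1] + t * d[1]))^2 + (g$y - (p0[2] + t * d[2]))^2 +
             (g$z - (p0[3] + t * d[3]))^2
  }
  keep <- dist2 <= radius^2
  if (!any(keep)) return(matrix(integer(), 0, 3))
  ii <- expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2], k = i0[3]:i1[3],
                    KEEP.OUT.ATTRS = FALSE)
  as.matrix(ii[keep, , drop = FALSE])
}

.dilate26 <- function(mask, dims) {
  out <- mask
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src <- mask[max(1, 1 - di):min(dims[1], dims[1] - di),
                max(1, 1 - dj):min(dims[2], dims[2] - dj),
                max(1, 1 - dk):min(dims[3], dims[3] - dk), drop = FALSE]
    out[max(1, 1 + di):min(dims[1], dims[1] + di),
        max(1, 1 + dj):min(dims[2], dims[2] + dj),
        max(1, 1 + dk):min(dims[3], dims[3] + dk)] <-
      out[max(1, 1 + di):min(dims[1], dims[1] + di),
          max(1, 1 + dj):min(dims[2], dims[2] + dj),
          max(1, 1 + dk):min(dims[3], dims[3] + dk)] | src
  }
  out
}
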