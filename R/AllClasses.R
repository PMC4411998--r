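#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib rootCT, .registration = TRUE
NULL

.COMPARTMENTS <- c("lower", "upper", "stem-seed")
.ORDERS <- c("primary", "secondary")

#' VoxelGrid: a 3-D CT volume in Hounsfield units
#'
#' Dense 3-D scalar field of CT numbers with anisotropic voxel spacing.
#' Values are stored as a numeric array; on disk the native scalar type is
#' signed 16-bit integer, matching clinical CT convention and the HU range.
#' The z axis increases with slice index; slice 1 is the first reconstructed
#' slice (the stem end of a pot scanned stem-first).
#'
#' @slot values 3-D numeric array of CT numbers (HU), all finite.
#' @slot spacing numeric(3), voxel edge lengths (dx, dy, dz) in mm, all > 0.
#'   Default \code{c(0.35, 0.35, 0.4)}.
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(0.35, 0.35, 0.4))
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite numbers (mm)")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "HU values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values 3-D numeric array of CT numbers in HU.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' vg <- VoxelGrid(array(0, c(8, 8, 4)))
#' gridDims(vg)
#' @export
VoxelGrid <- function(values, spacing = c(0.35, 0.35, 0.4)) {
  new("VoxelGrid", values = values, spacing = as.numeric(spacing))
}

#' ArchitectureTree: ground-truth root architecture with weekly snapshots
#'
#' SWC-style node table describing a simulated root system. Each node has a
#' position (mm), radius (mm), a compartment (lower / upper / stem-seed), a
#' branching order (primary / secondary) and the week index at which it first
#' exists. Snapshots are nested: the node set at week t is a subset of the
#' node set at week t + 1.
#'
#' @slot nodes data.frame with columns id, compartment, order, x, y, z,
#'   radius, parent (NA for the seed root node), birth_week.
#' @export
setClass("ArchitectureTree", representation(nodes = "data.frame"))

setValidity("ArchitectureTree", function(object) {
  nd <- object@nodes
  need <- c("id", "compartment", "order", "x", "y", "z", "radius", "parent",
            "birth_week")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (sum(is.na(nd$parent)) != 1L)
    msg <- c(msg, "exactly one root node (parent NA) required")
  kid <- which(!is.na(nd$parent))
  if (length(kid) && any(nd$parent[kid] >= nd$id[kid]))
    msg <- c(msg, "parent id must precede child id")
  if (length(kid) && any(nd$radius[kid] <= 0))
    msg <- c(msg, "non-seed nodes must have radius > 0")
  if (!all(nd$compartment %in% .COMPARTMENTS))
    msg <- c(msg, "unknown compartment label")
  if (length(kid)) {
    pw <- nd$birth_week[match(nd$parent[kid], nd$id)]
    if (any(nd$birth_week[kid] < pw))
      msg <- c(msg, "a child cannot be born before its parent (growth only)")
  }
  if (length(msg)) msg else TRUE
})

#' SkeletonGraph: a 1-voxel-thick labeled root skeleton
#'
#' Voxel-set representation of a skeletonized root system. Voxels are stored
#' as 1-based (i, j, k) grid coordinates; edges connect voxels adjacent under
#' 26-connectivity. Compartment and order labels and the attachment points
#' (voxels where a root meets the stem-seed region) are carried per voxel.
#'
#' @slot coords integer matrix (n x 3) of 1-based voxel coordinates.
#' @slot dims integer(3), the grid dimensions the coordinates live in.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot compartment character vector, one of "lower", "upper", "stem-seed",
#'   or NA when unlabeled.
#' @slot order character vector, "primary"/"secondary" or NA.
#' @slot attachments integer vector of row indices of attachment voxels.
#' @export
setClass("SkeletonGraph",
  representation(coords = "matrix", dims = "integer", spacing = "numeric",
                 compartment = "character", order = "character",
                 attachments = "integer")
)

setValidity("SkeletonGraph", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (n > 0 && (any(object@coords < 1L) ||
      any(object@coords > matrix(object@dims, n, 3, byrow = TRUE))))
    msg <- c(msg, "coords out of grid bounds")
  if (length(object@compartment) != n || length(object@order) != n)
    msg <- c(msg, "label vectors must match the number of voxels")
  if (length(object@attachments) &&
      (any(object@attachments < 1L) || any(object@attachments > n)))
    msg <- c(msg, "attachment indices out of range")
  if (n > 0 && .hasFullBlock(object@coords))
    msg <- c(msg, "skeleton is not 1 voxel thick (contains a full 2x2x2 block)")
  if (length(msg)) msg else TRUE
})

# TRUE if some 2x2x2 block of the grid is fully occupied by `coords`.
.hasFullBlock <- function(coords) {
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  have <- new.env(hash = TRUE, parent = emptyenv())
  ks <- key(coords)
  for (k in ks) assign(k, TRUE, envir = have)
  off <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)[-1, ]
  for (v in seq_len(nrow(coords))) {
    ok <- TRUE
    for (o in seq_len(nrow(off))) {
      k <- paste(coords[v, 1] + off$di[o], coords[v, 2] + off$dj[o],
                 coords[v, 3] + off$dk[o])
      if (!exists(k, envir = have, inherits = FALSE)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' RootMask: layer-grown root volumes per compartment and order
#'
#' Labeled voxel volume produced by growing a skeleton outwards, one
#' 26-neighbor layer at a time, gated by order-specific HU thresholds.
#' Layer 0 marks the skeleton itself; grown voxels carry the layer at which
#' they were claimed. Stem-seed voxels are never part of the mask.
#'
#' @slot compartment integer array (0 none, 1 lower, 2 upper).
#' @slot order integer array (0 none, 1 primary, 2 secondary).
#' @slot layer integer array (-1 none, 0 skeleton, >= 1 grown layer).
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot provenance character, free-text note on the skeleton it grew from.
#' @export
setClass("RootMask",
  representation(compartment = "array", order = "array", layer = "array",
                 spacing = "numeric", provenance = "character")
)

setValidity("RootMask", function(object) {
  msg <- character()
  if (!identical(dim(object@compartment), dim(object@layer)) ||
      !identical(dim(object@order), dim(object@layer)))
    msg <- c(msg, "compartment, order and layer arrays must share dimensions")
  inmask <- object@layer >= 0L
  if (any(object@compartment[inmask] == 0L) || any(object@order[inmask] == 0L))
    msg <- c(msg, "every mask voxel needs compartment and order labels")
  if (any(object@compartment[inmask] == 3L))
    msg <- c(msg, "stem-seed voxels may not be part of a root mask")
  if (length(msg)) msg else TRUE
})

#' FractalFit: a cube-counting fractal dimension estimate
#'
#' Ordinary least-squares fit of log N(s) on log(1/s) over a retained subset
#' of cube sidelengths; the slope is the fractal dimension.
#'
#' @slot sidelengths_used integer vector of retained sidelengths (voxels).
#' @slot fd numeric, the slope estimate (fractal dimension).
#' @slot intercept numeric, the fitted intercept k.
#' @slot r_squared numeric in [0, 1].
#' @export
setClass("FractalFit",
  representation(sidelengths_used = "integer", fd = "numeric",
                 intercept = "numeric", r_squared = "numeric")
)

setValidity("FractalFit", function(object) {
  msg <- character()
  if (length(object@sidelengths_used) < 3L)
    msg <- c(msg, "at least 3 sidelengths are required for a fit")
  if (!is.finite(object@fd)) msg <- c(msg, "fd must be finite")
  if (object@r_squared < -1e-12 || object@r_squared > 1 + 1e-12)
    msg <- c(msg, "r_squared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid: %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  HU range: [%g, %g]\n", min(object@values), max(object@values)))
})

setMethod("show", "ArchitectureTree", function(object) {
  nd <- object@nodes
  cat(sprintf("ArchitectureTree: %d nodes over weeks %d..%d\n",
              nrow(nd), min(nd$birth_week), max(nd$birth_week)))
  tb <- table(nd$compartment, nd$order)
  print(tb)
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d voxels in a %s grid\n",
              nrow(object@coords), paste(object@dims, collapse = " x ")))
  if (nrow(object@coords)) {
    cat("  compartments:", paste(names(table(object@compartment)),
        table(object@compartment), sep = "=", collapse = ", "), "\n")
    cat(sprintf("  attachment points: %d\n", length(object@attachments)))
  }
})

setMethod("show", "RootMask", function(object) {
  n <- sum(object@layer >= 0L)
  cat(sprintf("RootMask: %d voxels (%d skeleton, %d grown)\n",
              n, sum(object@layer == 0L), sum(object@layer >= 1L)))
})

setMethod("show", "FractalFit", function(object) {
  cat(sprintf("FractalFit: FD = %.4f (k = %.3f, R^2 = %.4f) over s = {%s}\n",
              object@fd, object@intercept, object@r_squared,
              paste(object@sidelengths_used, collapse = ", ")))
})
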