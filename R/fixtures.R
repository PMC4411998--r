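# Deterministic voxel-skeleton fixtures with analytically known reference
# values, used to validate cube counting (a digitized straight line has
# dimension 1, a filled sheet dimension 2) and skeleton length measurement.

#' Deterministic skeleton fixtures of known dimension and length
#'
#' \describe{
#'   \item{line}{\code{n} collinear voxels along x; reference FD 1,
#'     reference length \code{(n - 1) * spacing[1]}.}
#'   \item{plane}{an \code{n x n} voxel sheet in the z = 1 plane;
#'     reference FD 2.}
#'   \item{cross}{two orthogonal in-plane lines of \code{n} voxels sharing
#'     a center voxel; reference FD 1, length by summation of its edges.}
#'   \item{binary-tree}{a trunk of \code{n} voxels splitting twice into
#'     diagonal branches; reference length accumulated segment by segment
#'     during construction.}
#' }
#'
#' @param kind one of "line", "plane", "cross", "binary-tree".
#' @param n fixture size in voxels.
#' @param spacing voxel spacing in mm.
#' @return list with \code{skeleton} (a \linkS4class{SkeletonGraph}),
#'   \code{fd_ref} (NA when not applicable) and \code{length_ref} in mm
#'   (NA for the plane).
#' @examples
#' fx <- makeFixture("line", 256)
#' nrow(skeletonCoords(fx$skeleton))  # 256
#' @export
makeFixture <- function(kind = c("line", "plane", "cross", "binary-tree"),
                        n = 256, spacing = c(0.35, 0.35, 0.4)) {
  kind <- match.arg(kind)
  if (n < 2) stop("fixture size n must be >= 2")
  if (kind == "line") {
    coords <- cbind(seq_len(n), 1L, 1L)
    fd <- 1
    len <- (n - 1) * spacing[1]
  } else if (kind == "plane") {
    coords <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = 1L))
    fd <- 2
    len <- NA_real_
  } else if (kind == "cross") {
    mid <- (n + 1L) %/% 2L
    coords <- rbind(cbind(seq_len(n), mid, 1L),
                    cbind(mid, seq_len(n), 1L))
    coords <- coords[!duplicated(coords), , drop = FALSE]
    fd <- 1
    len <- (n - 1) * spacing[1] + (n - 1) * spacing[2]
  } else {
    # trunk up the k axis, two diagonal splits; accumulate edge lengths
    half <- max(2L, n %/% 2L); quarter <- max(2L, n %/% 4L)
    size <- 2L * n
    mid <- size %/% 2L
    pts <- list()
    len <- 0
    push <- function(path) {
      for (r in 2:nrow(path)) {
        d <- (path[r, ] - path[r - 1, ]) * spacing
        len <<- len + sqrt(sum(d^2))
      }
      pts[[length(pts) + 1L]] <<- path
    }
    trunk <- cbind(mid, mid, seq_len(n))
    push(trunk)
    top <- trunk[n, ]
    for (s1 in c(-1L, 1L)) {
      b1 <- t(vapply(seq_len(half), function(t)
        top + c(s1 * t, 0L, t), numeric(3)))
      push(rbind(top, b1))
      tip1 <- b1[half, ]
      for (s2 in c(-1L, 1L)) {
        b2 <- t(vapply(seq_len(quarter), function(t)
          tip1 + c(0L, s2 * t, t), numeric(3)))
        push(rbind(tip1, b2))
      }
    }
    coords <- do.call(rbind, pts)
    coords <- coords[!duplicated(coords), , drop = FALSE]
    fd <- NA_real_
    len <- len
  }
  mode(coords) <- "integer"
  dims <- as.integer(apply(coords, 2, max))
  skel <- new("SkeletonGraph", coords = coords, dims = dims,
              spacing = as.numeric(spacing),
              compartment = rep(NA_character_, nrow(coords)),
              order = rep(NA_character_, nrow(coords)),
              attachments = integer())
  list(skeleton = skel, fd_ref = fd, length_ref = len)
}
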