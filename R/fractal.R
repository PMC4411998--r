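# 3-D cube counting and fractal dimension estimation.
#
# The structural complexity of a skeletal root system is summarized by the
# slope FD of the ordinary least-squares fit
#     log N(s) = k + FD * log(1/s)
# where N(s) counts grid-aligned cubes of edge s (voxels) intersecting the
# skeleton and log is natural. Only a middle subset of the available cube
# sidelengths enters the fit: the smallest cubes see digitization, the
# largest see the finite footprint, and both bias the slope.

#' Dyadic cube-sidelength ladder for a grid
#'
#' Returns powers of two 2^0, 2^1, ... as cube sidelengths. Grids whose
#' largest dimension reaches 512 voxels get the full nine-rung ladder
#' 1..256; smaller grids get rungs up to \code{2^floor(log2(max_dim))}.
#'
#' @param max_dim largest grid dimension in voxels.
#' @return integer vector of sidelengths.
#' @examples
#' dyadicLadder(512)  # 1 2 4 ... 256 (nine sidelengths)
#' @export
dyadicLadder <- function(max_dim) {
  if (max_dim < 2) stop("grid too small for a sidelength ladder")
  emax <- if (max_dim >= 512) 8L else as.integer(floor(log2(max_dim)))
  as.integer(2^(0:emax))
}

#' Count cubes of each sidelength intersecting a skeleton
#'
#' The cube partition is anchored at the grid origin: a voxel at 1-based
#' coordinate c falls into cube index \code{floor((c - 1)/s)}. N(s) is the
#' number of distinct cubes holding at least one skeleton voxel; N(1) is the
#' voxel count and N is non-increasing in s.
#'
#' @param skeleton a \linkS4class{SkeletonGraph} or an n x 3 matrix of
#'   1-based voxel coordinates.
#' @param sidelengths positive integer cube edges (voxels).
#' @return data.frame with columns \code{s} and \code{N}.
#' @export
cubeCounts <- function(skeleton, sidelengths) {
  coords <- if (is(skeleton, "SkeletonGraph")) skeletonCoords(skeleton)
            else as.matrix(skeleton)
  if (!nrow(coords)) stop("empty skeleton: cube counting undefined")
  s <- as.integer(sidelengths)
  if (any(s < 1L)) stop("sidelengths must be positive integers")
  n <- vapply(s, function(si) {
    ci <- (coords - 1L) %/% si
    # encode cube index triplets injectively
    m <- apply(ci, 2, max) + 1
    length(unique(ci[, 1] + m[1] * (ci[, 2] + m[2] * ci[, 3])))
  }, numeric(1))
  data.frame(s = s, N = as.integer(n))
}

#' Select the sidelength subset used in the fractal fit
#'
#' \code{fixed-middle} (the default rule) discards the \code{discard_small}
#' smallest and \code{discard_large} largest sidelengths; with a nine-rung
#' ladder and the default discards of three per end, the middle three remain.
#' For shorter ladders the discards scale down to \code{floor(n/3)} per end
#' when left at their defaults. \code{best-subset} scans every contiguous
#' run of \code{subset_sizes} sidelengths that excludes the extreme rungs
#' and keeps the run maximizing the R-squared of the log-log fit.
#'
#' @param table a \code{\link{cubeCounts}} data.frame.
#' @param mode "fixed-middle" or "best-subset".
#' @param discard_small,discard_large rungs dropped per end in fixed-middle
#'   mode; NULL means the scaled default.
#' @param subset_sizes candidate run lengths for best-subset mode.
#' @return integer vector of retained sidelengths.
#' @export
selectSidelengths <- function(table, mode = c("fixed-middle", "best-subset"),
                              discard_small = NULL, discard_large = NULL,
                              subset_sizes = 3:5) {
  mode <- match.arg(mode)
  s <- as.integer(sort(table$s))
  n <- length(s)
  if (mode == "fixed-middle") {
    ds <- if (is.null(discard_small)) min(3L, n %/% 3L) else discard_small
    dl <- if (is.null(discard_large)) min(3L, n %/% 3L) else discard_large
    if (n < ds + dl + 3L)
      stop("fixed-middle needs at least ", ds + dl + 3L,
           " sidelengths (have ", n, ")")
    s[(ds + 1L):(n - dl)]
  } else {
    if (n < 5L) stop("best-subset needs at least 5 sidelengths (have ", n, ")")
    best <- NULL; best_r2 <- -Inf
    for (len in subset_sizes) {
      if (n - len < 2L) next
      # runs excluding the extreme rungs
      for (start in 2:(n - len)) {
        run <- s[start:(start + len - 1L)]
        fit <- fitFractalDimension(table, run)
        if (fit@r_squared > best_r2 + 1e-12) {
          best_r2 <- fit@r_squared; best <- run
        }
      }
    }
    best
  }
}

#' Fit the fractal dimension over a sidelength subset
#'
#' Ordinary least squares of \code{log N(s)} on \code{log(1/s)} (natural
#' logarithms): the slope is the fractal dimension, the intercept is k.
#'
#' @param table a \code{\link{cubeCounts}} data.frame.
#' @param subset sidelengths to use (must appear in the table, >= 3 of
#'   them, all with N >= 1).
#' @return a \linkS4class{FractalFit}.
#' @examples
#' tab <- data.frame(s = c(2, 4, 8), N = c(128, 64, 32))
#' fractalDim(fitFractalDimension(tab, c(2, 4, 8)))  # exactly 1
#' @export
fitFractalDimension <- function(table, subset = table$s) {
  rows <- match(subset, table$s)
  if (anyNA(rows)) stop("subset contains sidelengths absent from the table")
  if (length(rows) < 3L) stop("need at least 3 sidelengths to fit")
  N <- table$N[rows]; s <- table$s[rows]
  if (any(N < 1)) stop("cube count of zero in the subset; fit undefined")
  x <- log(1 / s); y <- log(N)
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-24) 1
        else max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
  new("FractalFit", sidelengths_used = as.integer(sort(s)),
      fd = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
      r_squared = r2)
}

#' Estimate the fractal dimension of a skeleton end to end
#'
#' Convenience wrapper: dyadic ladder from the grid footprint, cube counts,
#' subset selection, OLS fit.
#'
#' @param skeleton a \linkS4class{SkeletonGraph} or coordinate matrix.
#' @param mode subset rule, see \code{\link{selectSidelengths}}.
#' @param footprint optional grid footprint (largest dimension in voxels)
#'   for the ladder; defaults to the skeleton's own extent.
#' @return a \linkS4class{FractalFit}.
#' @export
estimateFD <- function(skeleton, mode = "fixed-middle", footprint = NULL) {
  coords <- if (is(skeleton, "SkeletonGraph")) skeletonCoords(skeleton)
            else as.matrix(skeleton)
  if (is.null(footprint)) footprint <- max(coords)
  ladder <- dyadicLadder(footprint)
  tab <- cubeCounts(coords, ladder)
  keep <- selectSidelengths(tab, mode = mode)
  fitFractalDimension(tab, keep)
}

#' Ratios of later-week fractal dimensions to week 1
#'
#' @param fd_by_week numeric vector of FD estimates ordered by week.
#' @return numeric vector \code{(FD_2/FD_1, FD_3/FD_1, ...)}.
#' @examples
#' fdRatios(c(1.0, 1.25, 1.5))  # 1.25 1.50
#' @export
fdRatios <- function(fd_by_week) {
  if (length(fd_by_week) < 2L) stop("need FD estimates for at least 2 weeks")
  if (is.na(fd_by_week[1]) || fd_by_week[1] <= 0)
    stop("week-1 FD must be positive to form ratios")
  fd_by_week[-1] / fd_by_week[1]
}
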