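# Independent oracles and fixture builders used across the suite.

# brute-force cube counting: enumerate every cube of the origin-anchored
# partition and test occupancy on a dense array (mechanism independent of
# the coordinate floor-division used by cubeCounts)
bruteForceCubeCount <- function(coords, grid, s) {
  occ <- array(FALSE, c(grid, grid, grid))
  occ[coords] <- TRUE
  nc <- ceiling(grid / s)
  count <- 0L
  for (a in seq_len(nc)) for (b in seq_len(nc)) for (cc in seq_len(nc)) {
    ix <- ((a - 1) * s + 1):min(a * s, grid)
    iy <- ((b - 1) * s + 1):min(b * s, grid)
    iz <- ((cc - 1) * s + 1):min(cc * s, grid)
    if (any(occ[ix, iy, iz])) count <- count + 1L
  }
  count
}

# closed-form two-variable OLS via the normal equations
olsOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# split-plot sums of squares assembled directly from cell and marginal
# means (independent of stats::aov)
splitPlotOracle <- function(value, subject, group, time) {
  subject <- as.character(subject); group <- as.character(group)
  time <- as.character(time)
  M <- mean(value)
  k <- length(unique(time)); g <- length(unique(group))
  subj_mean <- tapply(value, subject, mean)
  subj_group <- tapply(group, subject, function(x) x[1])
  grp_mean <- tapply(value, group, mean)
  time_mean <- tapply(value, time, mean)
  cell_mean <- tapply(value, list(group, time), mean)
  n <- length(unique(subject)) / g   # subjects per group (balanced)
  N <- length(unique(subject))

  ss_between <- k * sum((subj_mean - M)^2)
  ss_group <- n * k * sum((grp_mean - M)^2)
  ss_subj <- ss_between - ss_group
  ss_time <- g * n * sum((time_mean - M)^2)
  ss_cells <- n * sum((cell_mean - M)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_total <- sum((value - M)^2)
  ss_err <- ss_total - ss_between - ss_time - ss_int

  df_group <- g - 1; df_subj <- N - g
  df_time <- k - 1; df_int <- (g - 1) * (k - 1); df_err <- (k - 1) * (N - g)
  c(F_group = (ss_group / df_group) / (ss_subj / df_subj),
    F_time = (ss_time / df_time) / (ss_err / df_err),
    F_int = (ss_int / df_int) / (ss_err / df_err))
}

# Greenhouse-Geisser epsilon through the classical summation formula
# (no eigendecomposition)
epsilonSummationOracle <- function(S) {
  k <- nrow(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  row_means <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  min(max(num / den, 1 / (k - 1)), 1)
}

# random sparse voxel skeleton in a cubic grid
randomSkeleton <- function(grid, n_vox, seed) {
  set.seed(seed)
  coords <- unique(cbind(sample.int(grid, n_vox, replace = TRUE),
                         sample.int(grid, n_vox, replace = TRUE),
                         sample.int(grid, n_vox, replace = TRUE)))
  mode(coords) <- "integer"
  coords
}

# balanced two-group repeated-measures dataset
randomRMDesign <- function(n_per_group, k, seed, group_shift = 0) {
  set.seed(seed)
  subj <- rep(seq_len(2 * n_per_group), each = k)
  grp <- rep(rep(c("A", "B"), each = n_per_group), each = k)
  tim <- rep(seq_len(k), 2 * n_per_group)
  y <- rnorm(2 * n_per_group * k) + ifelse(grp == "B", group_shift, 0) +
    0.3 * tim
  repeatedMeasuresData(y, subj, grp, tim)
}

# single tilted tube phantom with a stem-seed cap, for recovery tests
tubePhantom <- function(direction, length_mm = 30, radius = 0.7,
                        noise_sd = 0, seed = 1) {
  d <- direction / sqrt(sum(direction^2))
  p0 <- c(22.4, 22.4, 12); p1 <- p0 + length_mm * d
  nodes <- data.frame(id = 1:3,
                      compartment = c("stem-seed", "lower", "lower"),
                      order = "primary",
                      x = c(22.4, p0[1], p1[1]), y = c(22.4, p0[2], p1[2]),
                      z = c(10, p0[3], p1[3]),
                      radius = c(1, radius, radius),
                      parent = c(NA, 1L, 2L), birth_week = 1L)
  tree <- new("ArchitectureTree", nodes = nodes)
  spec <- phantomSpec(noise_sd = noise_sd)
  list(tree = tree, spec = spec,
       phantom = voxelizePhantom(tree, 1, spec, rng_seed = seed))
}
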