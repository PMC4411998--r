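test_that("compartment volume is voxel count times voxel volume", {
  dims <- c(20L, 20L, 20L)
  comp <- array(0L, dims); ord <- array(0L, dims); layer <- array(-1L, dims)
  comp[1:10, 1:10, 1:10] <- 1L; ord[1:10, 1:10, 1:10] <- 1L
  layer[1:10, 1:10, 1:10] <- 1L
  rm <- new("RootMask", compartment = comp, order = ord, layer = layer,
            spacing = c(0.35, 0.35, 0.4), provenance = "test")
  expect_equal(compartmentVolume(rm, "lower"), 1000 * 0.049)
  expect_equal(compartmentVolume(rm, "upper"), 0)
  v <- compartmentVolume(rm)
  expect_equal(unname(v["combined"]), unname(v["lower"] + v["upper"]))

  # empty mask
  rm0 <- new("RootMask", compartment = array(0L, dims),
             order = array(0L, dims), layer = array(-1L, dims),
             spacing = c(0.35, 0.35, 0.4), provenance = "test")
  expect_equal(compartmentVolume(rm0, "combined"), 0)
})

test_that("stem-seed voxels are rejected from root masks by construction", {
  dims <- c(5L, 5L, 5L)
  comp <- array(0L, dims); ord <- array(0L, dims); layer <- array(-1L, dims)
  comp[1, 1, 1] <- 3L; ord[1, 1, 1] <- 1L; layer[1, 1, 1] <- 0L
  expect_error(validObject(
    new("RootMask", compartment = comp, order = ord, layer = layer,
        spacing = c(0.35, 0.35, 0.4), provenance = "test")), "stem-seed")
})

test_that("relative growth rate is exact arithmetic with a guarded zero", {
  expect_identical(relativeGrowthRate(10, 15), 0.5)
  expect_identical(relativeGrowthRate(7.3, 7.3), 0)
  expect_error(relativeGrowthRate(0, 5), "undefined")
  expect_error(relativeGrowthRate(NA, 5), "undefined")
})

test_that("length increment is exact and warns when roots shrink", {
  expect_identical(lengthIncrement(100, 130), 30)
  expect_identical(lengthIncrement(55, 55), 0)
  expect_warning(inc <- lengthIncrement(130, 100), "decreased")
  expect_identical(inc, -30)
  expect_error(lengthIncrement(-1, 5))
})

test_that("skeleton length handles axial, diagonal and labeled paths", {
  mk <- function(coords, comp) {
    new("SkeletonGraph", coords = coords, dims = apply(coords, 2, max),
        spacing = c(0.35, 0.35, 0.4), compartment = comp,
        order = rep("primary", nrow(coords)), attachments = integer())
  }
  co <- cbind(1L, 1L, 1:11)
  expect_equal(skeletonLength(mk(co, rep("lower", 11)), "lower"), 4)
  co2 <- rbind(c(1L, 1L, 1L), c(2L, 2L, 1L))
  expect_equal(skeletonLength(mk(co2, rep("lower", 2)), "lower"),
               sqrt(2 * 0.35^2), tolerance = 1e-12)
  # combined = lower + upper exactly, even when the two touch
  co3 <- cbind(1L, 1L, 1:10)
  lab <- c(rep("lower", 5), rep("upper", 5))
  lens <- skeletonLength(mk(co3, lab))
  expect_identical(unname(lens["combined"]),
                   unname(lens["lower"] + lens["upper"]))
})

test_that("measured lengths track SWC truth within 5% on unbranched axes", {
  spec <- phantomSpec(noise_sd = 0)
  cen <- spec$dims[1:2] * spec$spacing[1:2] / 2
  for (seed in c(1L, 3L)) {
    p <- growthParams(branch_rate = 0, n_upper_axes = 0, rng_seed = seed)
    tr <- growArchitecture(p, 3)
    ph <- voxelizePhantom(tr, 3, spec, rng_seed = 1)
    sk <- skeletonizeMask(segmentRootMaterial(ph$grid), spec$spacing)
    lab <- suppressWarnings(classifyCompartments(sk, cen, 10))
    measured <- skeletonLength(lab, "lower")
    # truth: per-segment length outside the stem-seed exclusion region
    nd <- treeSnapshot(tr, 3)
    nd2 <- nd[nd$compartment == "lower" & !is.na(nd$parent), ]
    pp <- match(nd2$parent, nd$id)
    truth <- 0
    for (r in seq_len(nrow(nd2))) {
      a <- c(nd$x[pp[r]], nd$y[pp[r]], nd$z[pp[r]])
      b <- c(nd2$x[r], nd2$y[r], nd2$z[r])
      tt <- seq(0, 1, length.out = 400)
      pts <- outer(tt, b - a) + matrix(a, 400, 3, byrow = TRUE)
      inreg <- (sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2 +
                     pmax(pts[, 3] - 10, 8 - pts[, 3], 0)^2) <= 3) |
               (pts[, 3] <= 10 &
                sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2) <= 2)
      truth <- truth + sqrt(sum((b - a)^2)) * mean(!inreg)
    }
    expect_lt(abs(measured - truth) / truth, 0.05)
    expect_gte(truth, 20)  # axes well past the 20 mm regime
  }
})

test_that("phantom volumes and lengths grow monotonically week over week", {
  spec <- phantomSpec(noise_sd = 0)
  tr <- growArchitecture(controlPreset(13), 3)
  vols <- lens <- numeric(3)
  for (w in 1:3) {
    ph <- voxelizePhantom(tr, w, spec, rng_seed = 4)
    sk <- skeletonizeMask(segmentRootMaterial(ph$grid), spec$spacing)
    lab <- suppressWarnings(classifyCompartments(sk, c(22.4, 22.4), 10))
    rmask <- expandSkeleton(lab, ph$grid,
                            exclude = stemSeedRegion(spec$dims, spec$spacing,
                                                     c(22.4, 22.4), 10))
    vols[w] <- compartmentVolume(rmask, "combined")
    lens[w] <- sum(skeletonLength(lab)[c("lower", "upper")])
  }
  expect_true(all(diff(vols) > 0))
  expect_true(all(diff(lens) > 0))
})
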