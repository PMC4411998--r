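test_that("threshold segmentation keeps large low-HU components only", {
  sand <- VoxelGrid(array(1200, c(10, 10, 10)))
  expect_warning(m <- segmentRootMaterial(sand, 850), "empty")
  expect_false(any(m))

  # two components, sizes 5 and 500: min_component = 50 keeps the big one
  v <- array(1200, c(30, 30, 10))
  v[2:6, 2, 2] <- 200                 # 5 voxels
  v[10:29, 10:14, 3:7] <- 200         # 500 voxels
  g <- VoxelGrid(v)
  m <- segmentRootMaterial(g, 850, min_component = 50)
  expect_equal(sum(m), 500L)
  expect_false(any(m[2:6, 2, 2]))
})

test_that("thinning yields 1-voxel skeletons preserving topology", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  sk1 <- skeletonizeMask(one)
  expect_equal(nrow(skeletonCoords(sk1)), 1L)
  expect_equal(unname(skeletonCoords(sk1)[1, ]), c(2L, 2L, 2L))

  # solid 3x3x40 bar -> a single path with two endpoints on the bar axis
  bar <- array(FALSE, c(9, 9, 44)); bar[4:6, 4:6, 3:42] <- TRUE
  skb <- skeletonizeMask(bar)
  co <- skeletonCoords(skb)
  ed <- skeletonEdges(skb)
  deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(co))
  expect_equal(sum(deg == 1L), 2L)
  expect_true(all(deg <= 2L))
  expect_equal(nrow(unique(co[, 1:2, drop = FALSE])), 1L)  # collinear, on axis
  expect_equal(unique(co[, 1]), 5L)

  # two disjoint bars stay two components
  two <- array(FALSE, c(20, 9, 44))
  two[3:5, 4:6, 3:42] <- TRUE; two[14:16, 4:6, 3:42] <- TRUE
  skt <- skeletonizeMask(two)
  lab <- rootCT:::cpp_label_components26(
    {
      a <- array(FALSE, dim(two)); a[skeletonCoords(skt)] <- TRUE; as.logical(a)
    }, as.integer(dim(two)))
  expect_equal(max(lab), 2L)

  expect_error(skeletonizeMask(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("noiseless default phantom is segmented with precision/recall >= 0.95", {
  tr <- growArchitecture(controlPreset(11), 3)
  spec <- phantomSpec(noise_sd = 0)
  ph <- voxelizePhantom(tr, 3, spec, rng_seed = 2)
  m <- segmentRootMaterial(ph$grid, 850)
  truth <- ph$compartment > 0L
  precision <- sum(m & truth) / sum(m)
  recall <- sum(m & truth) / sum(truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("compartment labels follow the attachment side of the seed", {
  # single tube below the seed: everything lower, nothing upper
  tube <- tubePhantom(c(0.3, -0.2, 1), length_mm = 25)
  sk <- skeletonizeMask(segmentRootMaterial(tube$phantom$grid),
                        tube$spec$spacing)
  lab <- classifyCompartments(sk, c(22.4, 22.4), 10)
  tab <- table(lab@compartment)
  expect_gt(tab[["lower"]], 0L)
  expect_false("upper" %in% names(tab))
  expect_gt(length(lab@attachments), 0L)
})

test_that("phantom compartment labels match ground truth >= 95%", {
  spec <- phantomSpec()
  for (seed in c(17L, 29L)) {
    tr <- growArchitecture(controlPreset(seed), 3)
    ph <- voxelizePhantom(tr, 3, spec, rng_seed = seed + 1L)
    sk <- skeletonizeMask(segmentRootMaterial(ph$grid), spec$spacing)
    lab <- suppressWarnings(classifyCompartments(sk, c(22.4, 22.4), 10))
    idx <- lab@coords[, 1] + spec$dims[1] * (lab@coords[, 2] - 1L) +
      prod(spec$dims[1:2]) * (lab@coords[, 3] - 1L)
    truth <- ph$compartment[idx]
    pred <- c(lower = 1L, upper = 2L, `stem-seed` = 3L)[lab@compartment]
    ok <- !is.na(pred) & truth > 0L
    expect_gte(mean(pred[ok] == truth[ok]), 0.95)
  }
})

test_that("a branch leaving a primary path is labeled secondary", {
  # T-shape: vertical tube with a side branch off its middle
  nodes <- data.frame(
    id = 1:4,
    compartment = c("stem-seed", "lower", "lower", "lower"),
    order = c("primary", "primary", "primary", "secondary"),
    x = c(22.4, 22.4, 22.4, 30.4), y = 22.4,
    z = c(10, 25, 40, 26), radius = c(1, 0.7, 0.7, 0.5),
    parent = c(NA, 1L, 2L, 2L), birth_week = 1L)
  tr <- new("ArchitectureTree", nodes = nodes)
  spec <- phantomSpec(noise_sd = 0)
  ph <- voxelizePhantom(tr, 1, spec, rng_seed = 1)
  sk <- skeletonizeMask(segmentRootMaterial(ph$grid), spec$spacing)
  lab <- classifyCompartments(sk, c(22.4, 22.4), 10)
  # voxels far out on the side branch must be secondary
  far_branch <- lab@coords[, 1] > 75
  expect_true(any(far_branch))
  expect_true(all(lab@order[far_branch] == "secondary"))
  # deep trunk voxels are primary
  deep <- lab@coords[, 3] > 85 & lab@coords[, 1] < 70
  expect_true(any(deep))
  expect_true(all(lab@order[deep] == "primary"))
})

test_that("layer growing respects order thresholds, caps and exclusions", {
  dims <- c(11L, 11L, 11L)
  v <- array(900, dims)
  grid <- VoxelGrid(v, spacing = c(1, 1, 1))
  mk_skel <- function(ord) {
    new("SkeletonGraph", coords = matrix(c(6L, 6L, 6L), 1, 3), dims = dims,
        spacing = c(1, 1, 1), compartment = "lower", order = ord,
        attachments = 1L)
  }
  # primary at 850 HU: neighbors at 900 are never added
  rm_p <- expandSkeleton(mk_skel("primary"), grid)
  expect_equal(sum(maskLayers(rm_p) >= 0L), 1L)
  # secondary at 950 HU: growth proceeds, but only two layers
  rm_s <- expandSkeleton(mk_skel("secondary"), grid)
  ly <- maskLayers(rm_s)
  expect_gt(sum(ly >= 1L), 0L)
  expect_equal(max(ly), 2L)
  # layer L is exactly the 26-dilation shell of layer < L
  expect_equal(sum(ly == 1L), 26L)
  expect_equal(sum(ly == 2L), 98L)

  # monotone in hu_max and max_layers
  set.seed(6)
  v2 <- array(runif(prod(dims), 700, 1100), dims)
  g2 <- VoxelGrid(v2, spacing = c(1, 1, 1))
  grown <- function(hu, layers)
    sum(maskLayers(expandSkeleton(mk_skel("primary"), g2,
      rules = list(primary = list(max_layers = layers, hu_max = hu),
                   secondary = list(max_layers = 2, hu_max = 950)))) >= 0L)
  expect_lte(grown(800, 3), grown(900, 3))
  expect_lte(grown(900, 2), grown(900, 4))

  expect_error(expandSkeleton(
    new("SkeletonGraph", coords = matrix(c(6L, 6L, 6L), 1, 3), dims = dims,
        spacing = c(1, 1, 1), compartment = NA_character_,
        order = NA_character_, attachments = integer()), grid), "labeled")
})

test_that("expansion recovers a noiseless cylinder and excludes the stem", {
  tube <- tubePhantom(c(0, 0, 1), length_mm = 25, radius = 1)
  spec <- tube$spec
  sk <- skeletonizeMask(segmentRootMaterial(tube$phantom$grid), spec$spacing)
  lab <- classifyCompartments(sk, c(22.4, 22.4), 10)
  region <- stemSeedRegion(spec$dims, spec$spacing, c(22.4, 22.4), 10)
  rmask <- expandSkeleton(lab, tube$phantom$grid, exclude = region)
  truth <- tube$phantom$compartment == 1L & !region
  covered <- sum(maskLayers(rmask) >= 0L & truth) / sum(truth)
  expect_gte(covered, 0.90)
  # the stem-seed region contributes nothing to the mask
  expect_equal(sum(maskLayers(rmask) >= 0L & region), 0L)
  validObject(rmask)
})
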