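test_that("hounsfield reproduces the CT calibration points and is linear", {
  expect_identical(hounsfield(1, mu_water = 1, mu_air = 0), 0)
  expect_identical(hounsfield(0, mu_water = 1, mu_air = 0), -1000)
  expect_equal(hounsfield(1.5, 1, 0), 500)
  # linearity / strict monotonicity in mu_object
  mu <- seq(-0.5, 2, by = 0.1)
  hu <- hounsfield(mu, 1, 0)
  expect_true(all(diff(hu) > 0))
  expect_equal(diff(hu), rep(100, length(mu) - 1))
  # arbitrary calibration pair still maps water -> 0, air -> -1000
  expect_equal(hounsfield(0.21, mu_water = 0.21, mu_air = 0.0002), 0)
  expect_equal(hounsfield(0.0002, mu_water = 0.21, mu_air = 0.0002), -1000)
  expect_error(hounsfield(1, mu_water = 0.5, mu_air = 0.5), "undefined")
})

test_that("stack extent is slices times reconstruction interval", {
  expect_equal(stackExtent(300, 0.4), 120)  # the scanner's 12 cm of depth
  expect_equal(stackExtent(1, 0.4), 0.4)
  expect_equal(stackExtent(250, 0.5), 125)
  expect_error(stackExtent(0, 0.4))
  expect_error(stackExtent(10, 0))
})

test_that("8-bit windowing matches the hand-computed mapping", {
  hu <- c(-1000, 1500, 0, 850, 2000, -2000)
  expect_identical(huToGray8(hu, c(-1000, 1500)),
                   c(0L, 255L, 102L, 189L, 255L, 0L))
  expect_error(huToGray8(0, c(10, 10)))
})

test_that("MetaImage round-trip preserves values, dims and spacing", {
  set.seed(11)
  vals <- array(sample(-1000:2000, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  vg <- VoxelGrid(vals, spacing = c(0.35, 0.35, 0.4))
  path <- file.path(withr::local_tempdir(), "vol.mhd")
  writeMetaImage(vg, path)
  back <- readMetaImage(path)
  expect_identical(gridValues(back), vals + 0)  # bit-exact for int16 payload
  expect_identical(gridDims(back), dim(vals))
  expect_equal(gridSpacing(back), c(0.35, 0.35, 0.4))
})

test_that("MetaImage reader rejects corrupt inputs naming the field", {
  dir <- withr::local_tempdir()
  vg <- VoxelGrid(array(0, c(4, 4, 4)))
  path <- file.path(dir, "vol.mhd")
  writeMetaImage(vg, path)
  # truncated payload
  raw_path <- file.path(dir, "vol.raw")
  writeBin(raw(10), raw_path)
  expect_error(readMetaImage(path), "truncated")
  # unsupported scalar type
  hdr <- readLines(path)
  hdr <- sub("MET_SHORT", "MET_FLOAT", hdr)
  writeLines(hdr, path)
  expect_error(readMetaImage(path), "ElementType|unsupported")
  # missing DimSize
  writeLines(c("ObjectType = Image", "ElementType = MET_SHORT",
               "ElementDataFile = vol.raw"), path)
  expect_error(readMetaImage(path), "DimSize")
})

test_that("TIFF slice stacks round-trip HU losslessly at 16 bit", {
  set.seed(12)
  vals <- array(sample(-1000:2000, 8 * 7 * 3, replace = TRUE), c(8, 7, 3))
  vg <- VoxelGrid(vals)
  dir <- withr::local_tempdir()
  paths <- writeTiffStack(vg, dir, prefix = "ct")
  expect_length(list.files(dir, pattern = "^ct_\\d{4}\\.tif$"), 3L)
  back <- readTiffStack(dir, prefix = "ct")
  expect_equal(gridValues(back), vals + 0)
})

test_that("VoxelGrid validity enforces finite HU and positive spacing", {
  expect_error(VoxelGrid(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(VoxelGrid(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(VoxelGrid(matrix(0, 2, 2)), "3-D")
})
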