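test_that("cube counts are exact on simple constructions", {
  one <- matrix(c(5L, 9L, 3L), 1, 3)
  cc <- cubeCounts(one, c(1, 2, 4, 8, 16))
  expect_true(all(cc$N == 1L))

  line <- cbind(1:256, 1L, 1L)
  cc2 <- cubeCounts(line, c(1, 2, 4))
  expect_equal(cc2$N, c(256L, 128L, 64L))

  expect_error(cubeCounts(matrix(integer(), 0, 3), 2), "empty")
  expect_error(cubeCounts(one, 0), "positive")
})

test_that("cube counts equal the brute-force oracle on random skeletons", {
  grids <- rep(c(16L, 32L, 64L), length.out = 50)
  set.seed(99)
  sizes <- sample(20:200, 50, replace = TRUE)
  for (i in 1:50) {
    coords <- randomSkeleton(grids[i], sizes[i], seed = 1000 + i)
    ss <- c(2L, 4L, 8L)
    cc <- cubeCounts(coords, ss)
    oracle <- vapply(ss, function(s) bruteForceCubeCount(coords, grids[i], s),
                     integer(1))
    expect_identical(cc$N, oracle)
    # N(1) equals the voxel count; N non-increasing
    expect_equal(cubeCounts(coords, 1)$N, nrow(coords))
    expect_true(all(diff(cubeCounts(coords, c(1, 2, 4, 8, 16))$N) <= 0))
  }
})

test_that("the dyadic ladder has nine rungs on clinical-footprint grids", {
  expect_identical(dyadicLadder(512), as.integer(2^(0:8)))
  expect_length(dyadicLadder(512), 9L)
  expect_identical(dyadicLadder(150), as.integer(2^(0:7)))
  expect_identical(dyadicLadder(64), as.integer(2^(0:6)))
  expect_error(dyadicLadder(1))
})

test_that("fixed-middle subset discards three sidelengths per end", {
  tab <- data.frame(s = 2^(0:8), N = 9:1)
  expect_identical(selectSidelengths(tab), c(8L, 16L, 32L))
  # scaled discards for shorter ladders
  tab8 <- data.frame(s = 2^(0:7), N = 8:1)
  expect_identical(selectSidelengths(tab8), c(4L, 8L, 16L, 32L))
  # explicit 3+3 discards on five rungs is a contract error
  tab5 <- data.frame(s = 2^(0:4), N = 5:1)
  expect_error(selectSidelengths(tab5, discard_small = 3, discard_large = 3),
               "at least")
})

test_that("best-subset returns the run with a perfect power law", {
  s <- 2^(0:8)
  N <- round(2000 / s^1.3) + c(37, 11, 0, 0, 0, 0, 0, 2, 5)  # middle run exact
  tab <- data.frame(s = s, N = pmax(N, 1L))
  run <- selectSidelengths(tab, mode = "best-subset")
  fit <- fitFractalDimension(tab, run)
  # the returned run must beat every other admissible contiguous run
  for (len in 3:5) for (start in 2:(9 - len)) {
    cand <- s[start:(start + len - 1)]
    expect_lte(fitFractalDimension(tab, cand)@r_squared,
               fit@r_squared + 1e-12)
  }
})

test_that("OLS fit recovers exact power laws and matches the oracle", {
  tab1 <- data.frame(s = c(2, 4, 8), N = 256 / c(2, 4, 8))
  f1 <- fitFractalDimension(tab1)
  expect_equal(fractalDim(f1), 1, tolerance = 1e-12)
  expect_equal(f1@r_squared, 1, tolerance = 1e-9)

  tab2 <- data.frame(s = c(4, 8, 16), N = (512 / c(4, 8, 16))^2)
  expect_equal(fractalDim(fitFractalDimension(tab2)), 2, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    s <- sort(sample(2^(1:8), 4))
    N <- sample(1:500, 4)
    fit <- fitFractalDimension(data.frame(s = s, N = N))
    o <- olsOracle(log(1 / s), log(N))
    expect_equal(fractalDim(fit), unname(o["slope"]), tolerance = 1e-10)
    expect_equal(fit@intercept, unname(o["intercept"]), tolerance = 1e-10)
  }

  expect_error(fitFractalDimension(data.frame(s = c(2, 4), N = c(3, 2))),
               "at least 3")
  expect_error(fitFractalDimension(data.frame(s = c(2, 4, 8), N = c(3, 2, 0))))
})

test_that("line and plane fixtures bracket the FD scale", {
  suppressWarnings({
    fd_line <- fractalDim(estimateFD(makeFixture("line", 256)$skeleton,
                                     footprint = 512))
    fd_plane <- fractalDim(estimateFD(makeFixture("plane", 256)$skeleton,
                                      footprint = 512))
  })
  expect_gte(fd_line, 0.95); expect_lte(fd_line, 1.05)
  expect_gte(fd_plane, 1.90); expect_lte(fd_plane, 2.10)
})

test_that("FD estimates stay in [0, 3] on arbitrary skeletons", {
  for (i in 1:10) {
    coords <- randomSkeleton(64L, 150, seed = 500 + i)
    fd <- fractalDim(estimateFD(coords))
    expect_gte(fd, 0); expect_lte(fd, 3)
  }
})

test_that("FD ratios divide later weeks by week 1", {
  expect_equal(fdRatios(c(1.2, 1.2, 1.2)), c(1, 1))
  expect_equal(fdRatios(c(1.0, 1.25, 1.5)), c(1.25, 1.5))
  expect_error(fdRatios(c(0, 1.2)), "positive")
  expect_error(fdRatios(1.5), "2 weeks")
})
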