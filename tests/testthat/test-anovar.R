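test_that("epsilon is 1 for two time points and under compound symmetry", {
  expect_identical(ggEpsilon(matrix(c(2, 0.5, 0.5, 3), 2, 2)), 1)
  cs <- matrix(0.4, 3, 3); diag(cs) <- 1.4
  expect_equal(ggEpsilon(cs), 1, tolerance = 1e-12)
  expect_error(ggEpsilon(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("epsilon matches the summation-form oracle and stays in bounds", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 0.1
    eps <- ggEpsilon(S)
    expect_equal(eps, epsilonSummationOracle(S), tolerance = 1e-10)
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
  }
})

test_that("split-plot F statistics match the cell-means oracle", {
  for (i in 1:100) {
    d <- randomRMDesign(n_per_group = 3, k = 3, seed = 2000 + i,
                        group_shift = (i %% 3) * 0.5)
    res <- anovarUnivariate(d)
    o <- splitPlotOracle(d$value, d$subject, d$group, d$time)
    tab <- res$table
    expect_equal(tab$F[tab$effect == "Group"], unname(o["F_group"]),
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "Time"], unname(o["F_time"]),
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "Time x Group"], unname(o["F_int"]),
                 tolerance = 1e-8)
    # adjusted P never below unadjusted for within-subject tests
    w <- tab$effect != "Group"
    expect_true(all(tab$P_adjusted[w] >= tab$P[w] - 1e-12))
  }
})

test_that("two repeated measures need no epsilon adjustment", {
  d <- randomRMDesign(n_per_group = 3, k = 2, seed = 77)
  res <- anovarUnivariate(d)
  expect_identical(res$epsilon, 1)
  w <- res$table$effect != "Group"
  expect_equal(res$table$P_adjusted[w], res$table$P[w])
})

test_that("identical responses give zero effects and an undefined F", {
  d <- repeatedMeasuresData(rep(5, 12), rep(1:4, each = 3),
                            rep(c("A", "B"), each = 6), rep(1:3, 4))
  res <- anovarUnivariate(d)
  expect_true(all(is.na(res$table$F)))  # reported as undefined, not NaN
})

test_that("the per-week contrast is the squared pooled t test", {
  expect_equal(unname(perWeekContrast(c(1, 2, 3), c(1, 2, 3))[c("F", "P")]),
               c(0, 1))
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1), mean = 0.8)
    ct <- perWeekContrast(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(ct["F"]), unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(unname(ct["P"]), tt$p.value, tolerance = 1e-10)
  }
  deg <- perWeekContrast(c(5, 5, 5), c(7, 7, 7))
  expect_true(is.na(deg["F"]))
  expect_error(perWeekContrast(1, c(1, 2)))
})

test_that("variance homogeneity is the two-sided variance-ratio F test", {
  a <- c(1.2, 3.4, 2.2, 4.1)
  expect_equal(unname(varianceHomogeneity(a, a + 10)[c("F", "P")]), c(1, 1))
  set.seed(9)
  x <- rnorm(5, sd = 1); y <- rnorm(7, sd = 3)
  vh <- varianceHomogeneity(x, y)
  Fv <- var(x) / var(y)
  p <- 2 * min(pf(Fv, 4, 6), 1 - pf(Fv, 4, 6))
  expect_equal(unname(vh["F"]), Fv, tolerance = 1e-12)
  expect_equal(unname(vh["P"]), p, tolerance = 1e-10)
  expect_true(is.na(varianceHomogeneity(c(1, 1), c(2, 2))["F"]))
  expect_error(varianceHomogeneity(1, c(1, 2)))
})

test_that("unbalanced or inconsistent designs are rejected", {
  expect_error(repeatedMeasuresData(1:5, c(1, 1, 2, 2, 2),
                                    rep("A", 5), c(1, 2, 1, 2, 2)),
               "balanced")
  expect_error(repeatedMeasuresData(1:4, c(1, 1, 2, 2),
                                    c("A", "B", "A", "A"), c(1, 2, 1, 2)),
               "one group")
  expect_error(repeatedMeasuresData(1:2, 1:2, c("A", "B"), c(1, 1)),
               "time")
})
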