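# Radial and non-radial efficiency programs against hand-solved and
# grid-search oracles.

one_period_panel <- function(X, Y) {
  # X: dmu x input, Y: dmu x output; duplicated into two periods so the
  # panel constructor's completeness checks stay satisfied
  panel_from_lists(list(X, X), list(Y, Y))
}

test_that("a lone DMU spans its own frontier", {
  p <- one_period_panel(matrix(c(2, 3), 1), matrix(5, 1))
  expect_equal(dea_efficiency(p, 1, 1, mode = "radial")$score, 1,
               tolerance = 1e-9)
  expect_equal(dea_efficiency(p, 1, 1, mode = "nonradial")$score, 1,
               tolerance = 1e-9)
})

test_that("radial efficiency solves the two-DMU textbook case", {
  # A = (x=1, y=1), B = (x=2, y=1): B can halve its input against A
  p <- one_period_panel(matrix(c(1, 2), 2, 1), matrix(c(1, 1), 2, 1))
  rB <- dea_efficiency(p, 2, 1, mode = "radial")
  expect_equal(rB$score, 0.5, tolerance = 1e-7)
  expect_equal(unname(rB$lambda), c(1, 0), tolerance = 1e-7)
  expect_equal(dea_efficiency(p, 1, 1, mode = "radial")$score, 1,
               tolerance = 1e-7)
})

test_that("duplicated DMUs share the same score", {
  set.seed(2)
  X <- matrix(rlnorm(8), 4, 2); Y <- matrix(rlnorm(4), 4, 1)
  X <- rbind(X, X[2, ]); Y <- rbind(Y, Y[2, , drop = FALSE])
  p <- one_period_panel(X, Y)
  for (mode in c("radial", "nonradial")) {
    s2 <- dea_efficiency(p, 2, 1, mode = mode)$score
    s5 <- dea_efficiency(p, 5, 1, mode = mode)$score
    expect_equal(s2, s5, tolerance = 1e-9)
  }
})

test_that("non-radial program solves the hand cases with weight exclusion", {
  # frontier point (x1, x2, y) = (1, 1, 1); evaluated point (2, 4, 1)
  p <- panel_from_lists(list(matrix(c(1, 1), 1, 2), matrix(c(2, 4), 1, 2)),
                        list(matrix(1, 1, 1), matrix(1, 1, 1)))
  r <- dea_efficiency(p, 1, "t1", "t2", mode = "nonradial")
  expect_equal(r$score, 0.375, tolerance = 1e-7)
  expect_equal(unname(r$per_input_theta), c(0.5, 0.25), tolerance = 1e-7)

  r0 <- dea_efficiency(p, 1, "t1", "t2", mode = "nonradial",
                       weights = c(1, 0))
  expect_equal(r0$score, 0.5, tolerance = 1e-7)
  expect_equal(unname(r0$per_input_theta)[2], 1)  # excluded input fixed at 1
})

test_that("non-radial never exceeds radial under equal weights", {
  for (seed in 1:5) {
    p <- random_panel(n = 8, Tn = 2, m = 3, s = 2, seed = seed)
    for (j in 1:8) {
      sr <- dea_efficiency(p, j, 1, mode = "radial")$score
      sn <- dea_efficiency(p, j, 1, mode = "nonradial")$score
      expect_lte(sn, sr + 1e-7)
      expect_gt(sn, 0)
      expect_lte(sr, 1 + 1e-7)
    }
  }
})

test_that("LP scores match a grid-search oracle on tiny problems", {
  set.seed(13)
  for (k in 1:6) {
    n <- sample(2:3, 1)
    X <- matrix(rlnorm(2 * n, 0, 0.4), 2, n)   # input x dmu
    Y <- matrix(rlnorm(n, 0, 0.4), 1, n)
    p <- one_period_panel(t(X), t(Y))
    for (j in seq_len(n)) {
      lp_r <- dea_efficiency(p, j, 1, mode = "radial")$score
      lp_n <- dea_efficiency(p, j, 1, mode = "nonradial")$score
      or_r <- grid_dea(X, Y, X[, j], Y[, j], mode = "radial", steps = 2000L)
      or_n <- grid_dea(X, Y, X[, j], Y[, j], mode = "nonradial", steps = 2000L)
      expect_equal(lp_r, or_r, tolerance = 1e-3)
      expect_equal(lp_n, or_n, tolerance = 1e-3)
    }
  }
})

test_that("cross-period programs stay feasible on positive panels", {
  for (seed in 1:4) {
    p <- random_panel(n = 6, Tn = 3, m = 3, s = 2, seed = 100 + seed)
    for (j in 1:6) for (tf in 1:3) for (te in 1:3) {
      r <- dea_efficiency(p, j, tf, te, mode = "nonradial")
      expect_identical(r$status, "optimal")
      expect_gt(r$score, 0)
    }
  }
})

test_that("scores are invariant to rescaling any input or output column", {
  p <- random_panel(n = 10, Tn = 2, m = 3, s = 2, seed = 21)
  base_r <- sapply(1:10, function(j) dea_efficiency(p, j, 1, mode = "radial")$score)
  base_n <- sapply(1:10, function(j) dea_efficiency(p, j, 1, mode = "nonradial")$score)
  rescale <- function(p, input = NULL, output = NULL, by) {
    x <- p$x; y <- p$y
    if (!is.null(input)) x[, , input] <- x[, , input] * by
    if (!is.null(output)) y[, , output] <- y[, , output] * by
    panel_dataset(x, y)
  }
  for (case in list(list(input = 2, by = 1000), list(input = 3, by = 1e-3),
                    list(output = 1, by = 250))) {
    p2 <- do.call(rescale, c(list(p), case))
    r2 <- sapply(1:10, function(j) dea_efficiency(p2, j, 1, mode = "radial")$score)
    n2 <- sapply(1:10, function(j) dea_efficiency(p2, j, 1, mode = "nonradial")$score)
    expect_equal(r2, base_r, tolerance = 1e-7)
    expect_equal(n2, base_n, tolerance = 1e-7)
  }
})

test_that("dominated DMUs do not disturb the frontier", {
  set.seed(31)
  X <- matrix(rlnorm(12, 1, 0.3), 6, 2); Y <- matrix(rlnorm(6, 1, 0.3), 6, 1)
  p <- one_period_panel(X, Y)
  base <- sapply(1:6, function(j) dea_efficiency(p, j, 1, mode = "nonradial")$score)
  # add a DMU weakly dominated by DMU 1 (more input, less output)
  p2 <- one_period_panel(rbind(X, X[1, ] * 1.5), rbind(Y, Y[1, ] * 0.7))
  after <- sapply(1:6, function(j) dea_efficiency(p2, j, 1, mode = "nonradial")$score)
  expect_equal(after, base, tolerance = 1e-9)
  # dropping a non-frontier DMU leaves efficient DMUs at score 1
  rad <- sapply(1:6, function(j) dea_efficiency(p, j, 1, mode = "radial")$score)
  drop_j <- which(rad < 1 - 1e-7)[1]
  expect_false(is.na(drop_j))          # seed chosen panel has an interior DMU
  keep <- setdiff(1:6, drop_j)
  p3 <- one_period_panel(X[keep, ], Y[keep, , drop = FALSE])
  for (j in which(rad[keep] > 1 - 1e-9))
    expect_equal(dea_efficiency(p3, j, 1, mode = "radial")$score, 1,
                 tolerance = 1e-9)
})

test_that("weight and id validation raise clear errors", {
  p <- random_panel(4, 2, 2, 1, seed = 1)
  expect_error(dea_efficiency(p, "nope", 1), "no such DMU")
  expect_error(dea_efficiency(p, 1, "nope"), "no such period")
  expect_error(dea_efficiency(p, 1, 1, weights = c(0, 0)), "at least one")
  expect_error(dea_efficiency(p, 1, 1, weights = c(a = 1, b = 2)),
               "weight names")
})
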