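test_that("influence closure handles trivial and nilpotent matrices", {
  z <- matrix(0, 3, 3)
  expect_equal(unclass(influence_closure(z, max_len = 5))[,],
               z, ignore_attr = TRUE)

  a <- matrix(c(0, 0, 0.5, 0), 2, 2)   # single edge 1 -> 2; A^2 = 0
  cl <- influence_closure(a, max_len = 3, normalize = "none")
  expect_equal(cl[,], a, ignore_attr = TRUE)
  expect_true(attr(cl, "converged"))
})

test_that("influence closure matches walk-enumeration oracle on cycles", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- 0.5; a[2, 1] <- 0.5       # 2-cycle of weight 0.5
  cl <- influence_closure(a, max_len = 10, tol = 1e-6, normalize = "none")
  expect_equal(cl[1, 2], sum(0.5^seq(1, 10, by = 2)), tolerance = 1e-12)
  expect_equal(unclass(cl)[,], walk_sum_closure(a, 10), tolerance = 1e-12)

  set.seed(3)
  for (k in 1:10) {
    n <- sample(2:4, 1)
    a <- matrix(runif(n * n, 0, 0.6), n, n); diag(a) <- 0
    L <- sample(1:6, 1)
    cl <- influence_closure(a, max_len = L, tol = 1e-12, normalize = "none")
    expect_equal(unclass(cl)[,], walk_sum_closure(a, L), tolerance = 1e-10)
  }
})

test_that("closure validates its inputs and records truncation", {
  expect_error(influence_closure(matrix(1, 2, 3)), "square")
  expect_error(influence_closure(matrix(c(0, -1, 0, 0), 2, 2)), "negative")
  # column-stochastic rescaling never meets tol: series flagged truncated
  a <- matrix(c(0, 1, 2, 0), 2, 2)
  cl <- influence_closure(a, max_len = 4, tol = 1e-6, normalize = "column")
  expect_true(attr(cl, "truncated"))
  expect_identical(attr(cl, "length"), 4L)
})

test_that("propagation reproduces hand arithmetic on the two-factor toy", {
  # af_af = [[0,1],[0,0]], one TF, one MF with score 2, unit outcome weight
  fit <- mdm(toy_spec(), max_len = 1, normalize = "none")
  expect_equal(unname(fit$af_tf_star[, 1]), c(2, 1))
  expect_equal(unname(fit$af_mf[, 1]), c(4, 2))
  expect_equal(unname(fit$weights_raw), c(4, 2))
  expect_equal(unname(fit$weights), c(2 / 3, 1 / 3))
})

test_that("identity chain leaves outcome weights untouched", {
  ids <- c("F1", "F2")
  spec <- mdm_spec(mf_weights = c(m1 = 0.5, m2 = 0.5),
                   tf_mf = diag(2) |>
                     (\(m) { dimnames(m) <- list(c("T1","T2"), c("m1","m2")); m })(),
                   af_tf = diag(2) |>
                     (\(m) { dimnames(m) <- list(ids, c("T1","T2")); m })(),
                   af_af = matrix(0, 2, 2, dimnames = list(ids, ids)))
  fit <- mdm(spec, normalize = "none")
  expect_equal(unname(fit$weights), c(0.5, 0.5))
  # zero influence: af_tf_star must equal af_tf exactly
  expect_identical(fit$af_tf_star, spec$af_tf)
})

test_that("propagation equals nested-loop recomputation on small specs", {
  set.seed(5)
  for (k in 1:8) {
    nf <- sample(2:4, 1); nt <- sample(1:3, 1); nm <- sample(1:3, 1)
    ids <- paste0("F", seq_len(nf)); tfs <- paste0("T", seq_len(nt))
    mfs <- paste0("m", seq_len(nm))
    w <- runif(nm); w <- w / sum(w); names(w) <- mfs
    spec <- mdm_spec(
      mf_weights = w,
      tf_mf = matrix(runif(nt * nm, 0, 9), nt, nm, dimnames = list(tfs, mfs)),
      af_tf = matrix(runif(nf * nt), nf, nt, dimnames = list(ids, tfs)),
      af_af = { a <- matrix(runif(nf * nf, 0, .7), nf, nf); diag(a) <- 0
                dimnames(a) <- list(ids, ids); a })
    for (nm_opt in c("none", "column")) {
      L <- sample(1:4, 1)
      fit <- mdm(spec, max_len = L, tol = 1e-15, normalize = nm_opt)
      oracle <- loop_propagate(spec, L, normalize = nm_opt)
      expect_equal(unclass(fit$closure)[,], oracle$closure, tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(unname(fit$weights), oracle$weights, tolerance = 1e-10)
      expect_equal(fit$af_mf, oracle$af_mf, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("global weights are a probability vector and stage sums match", {
  spec <- load_fixture("table3_mdm")
  fit <- mdm(spec)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$stage_shares$share), 1, tolerance = 1e-9)
  expect_equal(sum(fit$level1_shares$share), 1, tolerance = 1e-9)
  # stage share equals the sum of member weights by construction
  pre <- sum(fit$weights[grep("^A", names(fit$weights))])
  expect_equal(fit$stage_shares$share[fit$stage_shares$stage == "pre"], pre)
})

test_that("raising an af_tf score never lowers that factor's raw weight", {
  spec <- load_fixture("table3_mdm")
  base <- mdm(spec, normalize = "none")$weights_raw
  set.seed(9)
  for (k in 1:10) {
    i <- sample(17, 1); j <- sample(3, 1)
    af2 <- spec$af_tf; af2[i, j] <- af2[i, j] + runif(1, 0.1, 2)
    spec2 <- mdm_spec(spec$mf_weights, spec$tf_mf, af2, spec$af_af,
                      spec$factors)
    bumped <- mdm(spec2, normalize = "none")$weights_raw
    expect_gte(bumped[i], base[i] - 1e-12)
  }
})

test_that("spec validation rejects malformed inputs", {
  spec <- load_fixture("table3_mdm")
  expect_error(mdm_spec(c(a = 0.5, b = 0.6), spec$tf_mf, spec$af_tf,
                        spec$af_af), "sum to 1")
  bad_tf <- spec$tf_mf; bad_tf[1, 1] <- 10
  expect_error(mdm_spec(spec$mf_weights, bad_tf, spec$af_tf, spec$af_af),
               "\\[0, 9\\]")
  bad_aa <- spec$af_af; diag(bad_aa)[1] <- 0.2
  expect_error(mdm_spec(spec$mf_weights, spec$tf_mf, spec$af_tf, bad_aa),
               "diagonal")
  bad_labels <- spec$af_tf; rownames(bad_labels)[1] <- "X-9.9"
  expect_error(mdm_spec(spec$mf_weights, spec$tf_mf, bad_labels, spec$af_af),
               "label mismatch")
})
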