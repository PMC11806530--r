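# Independent oracles used across the suite.  These deliberately avoid the
# package's own linear-algebra / LP code paths: walks are enumerated
# recursively, matrix products are written as nested loops, and small DEA
# programs are minimised over a dense grid of intensity vectors.

# sum of products of edge weights over all walks i -> j of length 1..max_len
walk_sum_closure <- function(A, max_len) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  recurse <- function(start, node, prod, len) {
    if (len > 0) S[start, node] <<- S[start, node] + prod
    if (len == max_len) return()
    for (nxt in seq_len(n)) {
      w <- A[node, nxt]
      if (w != 0) recurse(start, nxt, prod * w, len + 1L)
    }
  }
  for (i in seq_len(n)) recurse(i, i, 1, 0L)
  S
}

# nested-loop matrix product (no %*%)
loop_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# brute-force recomputation of the full propagation chain for tiny specs
loop_propagate <- function(spec, max_len, normalize = "none") {
  A <- unclass(spec$af_af)
  if (normalize == "column") {
    for (j in seq_len(ncol(A))) {
      cs <- sum(A[, j]); if (cs > 0) A[, j] <- A[, j] / cs
    }
  }
  closure <- walk_sum_closure(A, max_len)
  af_tf_star <- spec$af_tf + loop_matmul(closure, spec$af_tf)
  af_mf <- loop_matmul(af_tf_star, spec$tf_mf)
  raw <- as.numeric(loop_matmul(af_mf, matrix(spec$mf_weights, ncol = 1)))
  list(closure = closure, af_tf_star = af_tf_star, af_mf = af_mf,
       raw = raw, weights = raw / sum(raw))
}

# grid-search DEA oracle: <= 3 DMUs, any inputs, one output, CRS.
# The output constraint binds at the optimum, so intensities are a scaled
# point of the simplex; the objective is evaluated on a dense grid.
grid_dea <- function(X, y, x0, y0, mode = "radial", alpha = NULL,
                     steps = 800L) {
  n <- ncol(X); m <- nrow(X)
  if (is.null(alpha)) alpha <- rep(1, m)
  wgrid <- if (n == 1) matrix(1, 1, 1) else {
    g <- seq(0, 1, length.out = steps + 1L)
    if (n == 2) rbind(g, 1 - g) else {
      gg <- expand.grid(a = g, b = g)
      gg <- gg[gg$a + gg$b <= 1, ]
      rbind(gg$a, gg$b, 1 - gg$a - gg$b)
    }
  }
  mu <- y0 / as.numeric(y %*% wgrid)          # scale to bind the output
  lam <- sweep(wgrid, 2, mu, "*")
  ratios <- (X %*% lam) / x0                  # m x grid
  obj <- if (mode == "radial") apply(ratios, 2, max)
         else as.numeric(alpha %*% ratios) / sum(alpha)
  min(obj)
}

# tiny panel builders ------------------------------------------------------

panel_from_lists <- function(x_by_period, y_by_period,
                             dmus = NULL, periods = NULL) {
  # x_by_period: list over periods of (dmu x input) matrices
  Tn <- length(x_by_period)
  n <- nrow(x_by_period[[1]]); m <- ncol(x_by_period[[1]])
  s <- ncol(y_by_period[[1]])
  x <- array(NA_real_, c(n, Tn, m)); y <- array(NA_real_, c(n, Tn, s))
  for (t in seq_len(Tn)) { x[, t, ] <- x_by_period[[t]]; y[, t, ] <- y_by_period[[t]] }
  panel_dataset(x, y,
                dmu_ids = dmus %||% paste0("d", seq_len(n)),
                period_ids = periods %||% paste0("t", seq_len(Tn)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_panel <- function(n, Tn, m, s, seed) {
  set.seed(seed)
  x <- array(stats::rlnorm(n * Tn * m, 3, 0.4), c(n, Tn, m))
  y <- array(stats::rlnorm(n * Tn * s, 2, 0.4), c(n, Tn, s))
  panel_dataset(x, y)
}

# toy two-factor MDM spec used in propagation examples
toy_spec <- function(af_af = matrix(c(0, 0, 1, 0), 2, 2)) {
  ids <- c("F1", "F2")
  dimnames(af_af) <- list(ids, ids)
  mdm_spec(mf_weights = c(goal = 1),
           tf_mf = matrix(2, 1, 1, dimnames = list("T1", "goal")),
           af_tf = matrix(1, 2, 1, dimnames = list(ids, "T1")),
           af_af = af_af)
}
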