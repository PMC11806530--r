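# Dense two-phase primal simplex for the small linear programs that arise in
# DEA efficiency scoring.  Problems here have at most a few hundred variables
# and ~20 constraints, so a tableau implementation with vectorised row
# operations is adequate and keeps the package free of external solver
# dependencies.
#
# Solves:  min  c'x
#          s.t. A x (<=, >=, =) b,  x >= 0
#
# `dir` is a character vector of "<=", ">=", "=" per row.

solve_lp <- function(objective, A, dir, rhs,
                     tol = 1e-9, max_iter = NULL) {
  n <- length(objective)
  A <- matrix(as.numeric(A), nrow = length(rhs), ncol = n)
  m <- nrow(A)
  stopifnot(length(dir) == m, length(rhs) == m)
  if (is.null(max_iter)) max_iter <- 50L * (n + m + 10L)

  # normalise rows so every rhs is nonnegative
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  n_art <- sum(dir != "<=")          # artificials for >= and = rows

  # column layout: [x (n)] [slack (n_le)] [surplus (n_ge)] [artificial (n_art)]
  N <- n + n_le + n_ge + n_art
  Ax <- matrix(0, m, N)
  Ax[, seq_len(n)] <- A
  basis <- integer(m)
  i_sl <- n; i_su <- n + n_le; i_ar <- n + n_le + n_ge
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      i_sl <- i_sl + 1L; Ax[i, i_sl] <- 1; basis[i] <- i_sl
    } else {
      if (dir[i] == ">=") { i_su <- i_su + 1L; Ax[i, i_su] <- -1 }
      i_ar <- i_ar + 1L; Ax[i, i_ar] <- 1; basis[i] <- i_ar
    }
  }
  art_cols <- seq.int(n + n_le + n_ge + 1L, length.out = n_art)

  Tmat <- cbind(Ax, rhs)

  run_phase <- function(Tmat, basis, cost, ncols) {
    # build reduced-cost row from scratch for current basis
    crow <- c(cost, 0)
    for (i in seq_len(m)) {
      cb <- cost[basis[i]]
      if (cb != 0) crow <- crow - cb * Tmat[i, ]
    }
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      red <- crow[seq_len(ncols)]
      if (it <= max_iter %/% 2L) {
        pc <- which.min(red)
        if (red[pc] >= -tol) break
      } else {                      # Bland's rule guard against cycling
        cand <- which(red < -tol)
        if (!length(cand)) break
        pc <- cand[1L]
      }
      col <- Tmat[, pc]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- Tmat[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      tied <- pos[ratio <= rmin + 1e-9 * (1 + abs(rmin))]
      # smallest basis index among ties (anti-cycling, Bland-compatible)
      pr <- tied[which.min(basis[tied])]
      piv <- Tmat[pr, pc]
      prow <- Tmat[pr, ] / piv
      Tmat <- Tmat - outer(Tmat[, pc], prow)
      Tmat[pr, ] <- prow
      crow <- crow - crow[pc] * prow
      basis[pr] <- pc
    }
    list(status = "optimal", Tmat = Tmat, basis = basis,
         value = -crow[ncols + 1L])
  }

  # Phase 1: drive artificials out
  if (n_art > 0L) {
    cost1 <- numeric(N); cost1[art_cols] <- 1
    p1 <- run_phase(Tmat, basis, cost1, N)
    if (p1$status != "optimal") return(list(status = p1$status))
    if (p1$value > 1e-7) return(list(status = "infeasible"))
    Tmat <- p1$Tmat; basis <- p1$basis
    # pivot any artificial still basic out of the basis if possible
    for (i in which(basis %in% art_cols)) {
      row <- Tmat[i, seq_len(n + n_le + n_ge)]
      pc <- which(abs(row) > tol)[1L]
      if (is.na(pc)) next                       # redundant constraint row
      piv <- Tmat[i, pc]
      prow <- Tmat[i, ] / piv
      Tmat <- Tmat - outer(Tmat[, pc], prow)
      Tmat[i, ] <- prow
      basis[i] <- pc
    }
    # drop redundant rows whose artificial could not leave the basis
    red_rows <- which(basis %in% art_cols)
    if (length(red_rows)) {
      Tmat <- Tmat[-red_rows, , drop = FALSE]
      basis <- basis[-red_rows]
      m <- m - length(red_rows)
    }
    keep <- seq_len(n + n_le + n_ge)
    Tmat <- Tmat[, c(keep, N + 1L), drop = FALSE]
  }

  ncols2 <- n + n_le + n_ge
  cost_full <- c(as.numeric(objective), numeric(n_le + n_ge))
  p2 <- run_phase(Tmat, basis, cost_full, ncols2)
  if (p2$status != "optimal") return(list(status = p2$status))

  x <- numeric(ncols2 + (ncol(p2$Tmat) - 1L - ncols2))
  x[p2$basis] <- p2$Tmat[, ncol(p2$Tmat)]
  list(status = "optimal",
       x = x[seq_len(n)],
       value = sum(as.numeric(objective) * x[seq_len(n)]))
}
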