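#' Non-radial Malmquist productivity index for one DMU and period pair
#'
#' Combines the four within- and cross-period efficiencies
#' \eqn{\tilde\theta^t(x^t,y^t)}, \eqn{\tilde\theta^{t+1}(x^{t+1},y^{t+1})},
#' \eqn{\tilde\theta^{t+1}(x^t,y^t)}, \eqn{\tilde\theta^t(x^{t+1},y^{t+1})}
#' into the input-oriented productivity index
#' \deqn{PI = \frac{\theta^t_{t}}{\theta^{t+1}_{t+1}}
#'   \sqrt{\frac{\theta^{t+1}_{t+1}\,\theta^{t+1}_{t}}
#'              {\theta^{t}_{t+1}\,\theta^{t}_{t}}}
#'   \;=\; \sqrt{\frac{\theta^t_t\,\theta^{t+1}_t}
#'                    {\theta^{t+1}_{t+1}\,\theta^t_{t+1}}},}
#' where subscripts denote the evaluated period and superscripts the frontier
#' period.  The index is computed literally in the first (redundant) form;
#' the algebraic simplification is noted for reference only.  Under this
#' input-oriented convention a uniform outward shift of the frontier yields
#' an index below 1; see \code{summary} output and the package vignette for
#' the interpretation, and \code{inverse = TRUE} to report reciprocals.
#'
#' @param panel a \code{\link{panel_dataset}}.
#' @param dmu DMU id or index.
#' @param t the first period of the adjacent pair (id or index).
#' @param weights input preference weights, as in
#'   \code{\link{dea_efficiency}}.
#' @param mode \code{"nonradial"} (default) or \code{"radial"}.
#' @return a list of class \code{"malmquist_record"}: the four efficiencies
#'   (\code{eff_tt}, \code{eff_t1t1}, \code{eff_t1t}, \code{eff_tt1}),
#'   \code{pi}, \code{dmu}, \code{period_pair}.
#' @export
malmquist_index <- function(panel, dmu, t, weights = NULL,
                            mode = c("nonradial", "radial")) {
  mode <- match.arg(mode)
  it <- resolve_id(t, panel$period_ids, "period")
  if (it >= length(panel$period_ids))
    stop("period ", panel$period_ids[it],
         " has no successor in the panel", call. = FALSE)
  p1 <- panel$period_ids[it]; p2 <- panel$period_ids[it + 1L]
  eff <- function(frontier, evaluated)
    dea_efficiency(panel, dmu, frontier, evaluated,
                   mode = mode, weights = weights)$score
  eff_tt   <- eff(p1, p1)
  eff_t1t1 <- eff(p2, p2)
  eff_t1t  <- eff(p2, p1)
  eff_tt1  <- eff(p1, p2)
  pi <- (eff_tt / eff_t1t1) *
    sqrt((eff_t1t1 * eff_t1t) / (eff_tt1 * eff_tt))
  structure(list(dmu = panel$dmu_ids[resolve_id(dmu, panel$dmu_ids, "DMU")],
                 period_pair = paste0(p1, "=>", p2),
                 eff_tt = eff_tt, eff_t1t1 = eff_t1t1,
                 eff_t1t = eff_t1t, eff_tt1 = eff_tt1, pi = pi),
            class = "malmquist_record")
}

#' @export
print.malmquist_record <- function(x, digits = 4, ...) {
  cat(sprintf("Malmquist index of %s, %s: %.*f\n",
              x$dmu, x$period_pair, digits, x$pi))
  invisible(x)
}

#' Fit Malmquist productivity indices over a panel
#'
#' Computes the non-radial (or radial) input-oriented Malmquist index for
#' every DMU and every adjacent period pair, together with the panel
#' summaries (per-DMU means; per-pair mean, max, min, sample SD; grand
#' mean).
#'
#' @param panel a \code{\link{panel_dataset}} with at least two periods.
#' @param weights input preference weights \eqn{\alpha_i}, as in
#'   \code{\link{dea_efficiency}}; either one vector applied to all DMUs or
#'   a list keyed by DMU id.
#' @param mode \code{"nonradial"} (default) or \code{"radial"}.
#' @param inverse also report \code{1/pi} in the records (the conventional
#'   reading in which values above 1 denote productivity growth under an
#'   advancing frontier).
#' @return an object of class \code{"malmquist"}: \code{records} (one row
#'   per DMU x pair, with the four component efficiencies), \code{index}
#'   (DMU x pair matrix of indices) and \code{weights}, \code{mode}.
#' @examples
#' sim <- simulate_panel(synthetic_config(n_dmus = 6, n_periods = 3, seed = 1))
#' fit <- malmquist(sim$panel)
#' summary(fit)
#' @export
malmquist <- function(panel, weights = NULL,
                      mode = c("nonradial", "radial"), inverse = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "panel_dataset"))
  Tn <- length(panel$period_ids)
  if (Tn < 2) stop("at least two periods are required", call. = FALSE)
  dmus <- panel$dmu_ids
  per_dmu_weights <- is.list(weights)
  pairs <- paste0(panel$period_ids[-Tn], "=>", panel$period_ids[-1])
  rows <- vector("list", length(dmus) * (Tn - 1L))
  k <- 0L
  for (j in dmus) {
    wj <- if (per_dmu_weights) weights[[j]] else weights
    for (t in seq_len(Tn - 1L)) {
      rec <- malmquist_index(panel, j, t, weights = wj, mode = mode)
      k <- k + 1L
      rows[[k]] <- data.frame(dmu = rec$dmu, period_pair = rec$period_pair,
                              eff_tt = rec$eff_tt, eff_t1t1 = rec$eff_t1t1,
                              eff_t1t = rec$eff_t1t, eff_tt1 = rec$eff_tt1,
                              pi = rec$pi, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  if (inverse) records$pi_inverse <- 1 / records$pi
  index <- matrix(records$pi, nrow = length(dmus), ncol = Tn - 1L,
                  byrow = TRUE, dimnames = list(dmus, pairs))
  structure(list(records = records, index = index,
                 weights = weights, mode = mode),
            class = "malmquist")
}

#' @export
print.malmquist <- function(x, digits = 4, ...) {
  cat(sprintf("%s Malmquist productivity indices: %d DMUs x %d period pairs\n",
              x$mode, nrow(x$index), ncol(x$index)))
  s <- malmquist_summary(x$index)
  cat(sprintf("  grand mean index: %.*f\n", digits, s$grand_mean))
  invisible(x)
}

#' @export
summary.malmquist <- function(object, ...) malmquist_summary(object$index)

#' @export
plot.malmquist <- function(x, ...) {
  s <- malmquist_summary(x$index)
  graphics::matplot(t(x$index), type = "l", lty = 1,
                    col = grDevices::grey(0.7),
                    xaxt = "n", xlab = "period pair",
                    ylab = "Malmquist index", ...)
  graphics::axis(1, at = seq_len(ncol(x$index)), labels = colnames(x$index),
                 las = 2, cex.axis = 0.8)
  graphics::lines(seq_len(ncol(x$index)), s$pair_stats["mean", ], lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Summarise a matrix of Malmquist indices
#'
#' @param index a DMU x period-pair numeric matrix (e.g. the \code{index}
#'   component of a \code{\link{malmquist}} fit, or a published table).
#' @return an object of class \code{"malmquist_summary"}: \code{dmu_means}
#'   (per-DMU arithmetic means over pairs), \code{pair_stats} (matrix with
#'   rows mean/max/min/sd over DMUs; SD uses the sample divisor n-1) and
#'   \code{grand_mean} (mean of the per-pair means).
#' @export
malmquist_summary <- function(index) {
  if (inherits(index, "malmquist")) index <- index$index
  index <- as.matrix(index)
  if (length(index) == 0 || !is.numeric(index))
    stop("'index' must be a non-empty numeric matrix", call. = FALSE)
  pair_stats <- rbind(mean = colMeans(index),
                      max = apply(index, 2, max),
                      min = apply(index, 2, min),
                      sd = apply(index, 2, stats::sd))
  structure(list(dmu_means = rowMeans(index),
                 pair_stats = pair_stats,
                 grand_mean = mean(colMeans(index))),
            class = "malmquist_summary")
}

#' @export
print.malmquist_summary <- function(x, digits = 4, ...) {
  cat("Per-pair summary of Malmquist indices:\n")
  print(round(x$pair_stats, digits))
  cat(sprintf("grand mean: %.*f\n", digits, x$grand_mean))
  invisible(x)
}
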