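#' Construct a DMU x period input-output panel
#'
#' The container used by the DEA stage: a complete panel of strictly
#' positive inputs and outputs for every decision-making unit (DMU) and
#' period.
#'
#' @param x numeric array \code{[dmu, period, input]} of inputs.
#' @param y numeric array \code{[dmu, period, output]} of outputs.
#' @param dmu_ids,period_ids,input_names,output_names identifiers; taken from
#'   the array dimnames when omitted.
#' @return an object of class \code{"panel_dataset"}.
#' @export
panel_dataset <- function(x, y, dmu_ids = dimnames(x)[[1]],
                          period_ids = dimnames(x)[[2]],
                          input_names = dimnames(x)[[3]],
                          output_names = dimnames(y)[[3]]) {
  stopifnot(length(dim(x)) == 3, length(dim(y)) == 3)
  if (is.null(dmu_ids)) dmu_ids <- paste0("dmu", seq_len(dim(x)[1]))
  if (is.null(period_ids)) period_ids <- as.character(seq_len(dim(x)[2]))
  if (is.null(input_names)) input_names <- paste0("x", seq_len(dim(x)[3]))
  if (is.null(output_names)) output_names <- paste0("y", seq_len(dim(y)[3]))
  if (!identical(dim(x)[1:2], dim(y)[1:2]))
    stop("'x' and 'y' must cover the same DMUs and periods", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("panel is incomplete: missing values present", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("panel values must be strictly positive", call. = FALSE)
  dimnames(x) <- list(dmu_ids, period_ids, input_names)
  dimnames(y) <- list(dmu_ids, period_ids, output_names)
  structure(list(x = x, y = y, dmu_ids = dmu_ids, period_ids = period_ids,
                 input_names = input_names, output_names = output_names),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("Input-output panel: %d DMUs x %d periods, %d inputs, %d outputs\n",
              length(x$dmu_ids), length(x$period_ids),
              length(x$input_names), length(x$output_names)))
  cat("  periods:", paste(x$period_ids, collapse = ", "), "\n")
  invisible(x)
}

resolve_id <- function(id, ids, what) {
  if (is.numeric(id)) {
    if (id < 1 || id > length(ids)) stop("no such ", what, ": ", id, call. = FALSE)
    return(as.integer(id))
  }
  i <- match(as.character(id), ids)
  if (is.na(i)) stop("no such ", what, ": ", id, call. = FALSE)
  i
}

check_weights <- function(weights, input_names) {
  m <- length(input_names)
  if (is.null(weights)) weights <- rep(1, m)
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), input_names))
      stop("weight names must match the panel's input names", call. = FALSE)
    weights <- weights[input_names]
  } else if (length(weights) != m) {
    stop("'weights' must have one entry per input", call. = FALSE)
  }
  if (any(weights < 0) || all(weights == 0))
    stop("input weights must be nonnegative with at least one positive entry",
         call. = FALSE)
  unname(weights)
}

#' DEA efficiency of one DMU against a period frontier
#'
#' Solves the input-oriented constant-returns DEA program for one DMU.  In
#' radial mode a single contraction factor is applied to all inputs:
#' \deqn{\min \theta \quad s.t. \quad \sum_j \lambda_j x_j \le \theta x_0,\;
#'       \sum_j \lambda_j y_j \ge y_0,\; \lambda \ge 0.}
#' In non-radial mode each input carries its own factor \eqn{\theta_i},
#' aggregated by preference weights:
#' \deqn{\min \frac{\sum_i \alpha_i \theta_i}{\sum_i \alpha_i} \quad s.t.
#'       \quad \sum_j \lambda_j x_{ij} \le \theta_i x_{i0} \;\forall i,\;
#'       \sum_j \lambda_j y_{rj} \ge y_{r0} \;\forall r.}
#' Inputs with \eqn{\alpha_i = 0} have \eqn{\theta_i} fixed to 1 and are
#' excluded from the objective.  The reference technology is spanned by all
#' DMUs of \code{frontier_period}; the evaluated point is taken from
#' \code{evaluated_period}, so cross-period scores may exceed 1.
#'
#' @param panel a \code{\link{panel_dataset}}.
#' @param dmu DMU id or index.
#' @param frontier_period period supplying the reference technology.
#' @param evaluated_period period supplying the evaluated point (defaults to
#'   the frontier period).
#' @param mode \code{"nonradial"} (default) or \code{"radial"}.
#' @param weights nonnegative input preference weights \eqn{\alpha_i}
#'   (default: equal).  Ignored in radial mode.
#' @return an object of class \code{"dea_efficiency"}: a list with
#'   \code{score}, \code{per_input_theta}, \code{lambda}, \code{mode},
#'   \code{dmu}, \code{frontier_period}, \code{evaluated_period},
#'   \code{status}.
#' @export
dea_efficiency <- function(panel, dmu, frontier_period,
                           evaluated_period = frontier_period,
                           mode = c("nonradial", "radial"),
                           weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "panel_dataset"))
  j0 <- resolve_id(dmu, panel$dmu_ids, "DMU")
  tf <- resolve_id(frontier_period, panel$period_ids, "period")
  te <- resolve_id(evaluated_period, panel$period_ids, "period")

  m <- length(panel$input_names); s <- length(panel$output_names)
  n <- length(panel$dmu_ids)
  X <- matrix(panel$x[, tf, ], n, m)   # frontier inputs, DMU x input
  Y <- matrix(panel$y[, tf, ], n, s)
  x0 <- panel$x[j0, te, ]; y0 <- panel$y[j0, te, ]

  if (mode == "radial") {
    # vars: (theta, lambda_1..n)
    A <- rbind(cbind(-x0, t(X)), cbind(0, t(Y)))
    r <- solve_lp(c(1, numeric(n)), A,
                  c(rep("<=", m), rep(">=", s)), c(numeric(m), y0))
    if (r$status != "optimal")
      stop("LP solver failed with status '", r$status, "'", call. = FALSE)
    theta <- r$x[1]; lambda <- r$x[-1]
    per_input <- rep(theta, m)
  } else {
    alpha <- check_weights(weights, panel$input_names)
    act <- alpha > 0
    # theta_i is binding at the optimum for active inputs, so it can be
    # substituted out: minimise sum_j lambda_j c_j with
    # c_j = sum_{i active} alpha_i x_ij / x_i0 / sum(alpha); inactive inputs
    # keep their constraint with theta_i fixed at 1.
    cc <- as.numeric(X[, act, drop = FALSE] %*% (alpha[act] / x0[act])) /
      sum(alpha)
    A <- t(Y); dir <- rep(">=", s); b <- y0
    if (any(!act)) {
      A <- rbind(A, t(X[, !act, drop = FALSE]))
      dir <- c(dir, rep("<=", sum(!act)))
      b <- c(b, x0[!act])
    }
    r <- solve_lp(cc, A, dir, b)
    if (r$status != "optimal")
      stop("LP solver failed with status '", r$status, "'", call. = FALSE)
    lambda <- r$x
    per_input <- rep(1, m)
    per_input[act] <- as.numeric(crossprod(X[, act, drop = FALSE], lambda)) /
      x0[act]
    theta <- sum(alpha[act] * per_input[act]) / sum(alpha)
  }
  names(per_input) <- panel$input_names
  names(lambda) <- panel$dmu_ids
  structure(list(dmu = panel$dmu_ids[j0],
                 frontier_period = panel$period_ids[tf],
                 evaluated_period = panel$period_ids[te],
                 mode = mode, score = theta,
                 per_input_theta = per_input, lambda = lambda,
                 status = "optimal"),
            class = "dea_efficiency")
}

#' @export
print.dea_efficiency <- function(x, digits = 4, ...) {
  cat(sprintf("%s DEA efficiency of %s (frontier %s, evaluated %s): %.*f\n",
              x$mode, x$dmu, x$frontier_period, x$evaluated_period,
              digits, x$score))
  invisible(x)
}
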