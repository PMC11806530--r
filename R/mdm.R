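#' Transitive influence closure of a factor influence matrix
#'
#' Computes the matrix power series \eqn{\sum_{k=1}^{L} A^k} that accumulates
#' direct and indirect (multi-step) influence among factors, the standard
#' design-structure-matrix treatment of dependency propagation.  Because
#' elicited influence scores can exceed 1 the raw series need not converge;
#' the matrix is therefore rescaled first (see \code{normalize}) and the
#' series is truncated at \code{max_len} steps or once the largest entry of
#' the k-th power term drops below \code{tol}, whichever comes first.
#'
#' @param af_af square nonnegative influence matrix with zero diagonal.
#' @param max_len maximum path length accumulated (default 3).
#' @param tol convergence tolerance on the max-norm of the k-th term.
#' @param normalize rescaling applied before the series: \code{"column"}
#'   divides each nonzero column by its column sum, \code{"max"} divides the
#'   whole matrix by its largest column sum, \code{"none"} uses the raw
#'   matrix.
#' @return the closure matrix, with attributes \code{length} (number of terms
#'   accumulated), \code{converged} and \code{truncated}.
#' @examples
#' a <- matrix(c(0, 0, 0.5, 0), 2, 2)
#' influence_closure(a, max_len = 3, normalize = "none")  # nilpotent: A^2 = 0
#' @export
influence_closure <- function(af_af, max_len = 3L, tol = 1e-6,
                              normalize = c("column", "max", "none")) {
  normalize <- match.arg(normalize)
  if (!is.matrix(af_af) || nrow(af_af) != ncol(af_af))
    stop("'af_af' must be a square matrix", call. = FALSE)
  check_nonneg_matrix(af_af, "af_af")
  if (max_len < 1) stop("'max_len' must be at least 1", call. = FALSE)

  A <- switch(normalize,
    column = {
      cs <- colSums(af_af)
      sweep(af_af, 2, ifelse(cs > 0, cs, 1), "/")
    },
    max = {
      cs <- max(colSums(af_af))
      if (cs > 0) af_af / cs else af_af
    },
    none = af_af)

  S <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(af_af))
  P <- diag(nrow(A))
  converged <- FALSE
  len <- 0L
  for (k in seq_len(max_len)) {
    P <- P %*% A
    if (max(abs(P)) < tol) { converged <- TRUE; break }
    S <- S + P
    len <- k
  }
  structure(S, length = len, converged = converged,
            truncated = !converged && len == max_len,
            normalize = normalize)
}

#' Fit the multiple-domain importance propagation
#'
#' Propagates elicited relationship matrices into per-factor global
#' importance weights by the chained products
#' \deqn{M^*_{AF \times AF} = \sum_k A^k, \quad
#'       M^*_{AF \times TF} = M_{AF \times TF} + M^*_{AF \times AF} M_{AF \times TF},}
#' \deqn{M_{AF \times MF} = M^*_{AF \times TF} M_{TF \times MF}, \quad
#'       M_{AF \times PD} = M_{AF \times MF} M_{MF \times PD},}
#' and normalises the final outcome column to a unit-sum weight vector.
#'
#' @param spec an \code{\link{mdm_spec}} object.
#' @param max_len,tol,normalize closure options passed to
#'   \code{\link{influence_closure}}.
#' @return an object of class \code{"mdm"} with components
#'   \code{closure}, \code{af_tf_star}, \code{af_mf}, \code{weights_raw},
#'   \code{weights} (unit-sum global importance), \code{stage_shares},
#'   \code{level1_shares}, \code{settings} and the input \code{spec}.
#' @seealso \code{\link{stage_shares}}, \code{\link{level1_shares}},
#'   \code{\link{goal_ranking}}
#' @export
mdm <- function(spec, max_len = 3L, tol = 1e-6,
                normalize = c("column", "max", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(spec, "mdm_spec"))
  closure <- influence_closure(spec$af_af, max_len = max_len, tol = tol,
                               normalize = normalize)
  af_tf_star <- spec$af_tf + closure %*% spec$af_tf
  af_mf <- af_tf_star %*% spec$tf_mf
  raw <- drop(af_mf %*% spec$mf_weights)
  names(raw) <- rownames(spec$af_tf)
  total <- sum(raw)
  weights <- if (total > 0) raw / total else raw

  has_stage <- !anyNA(spec$factors$stage[match(names(weights), spec$factors$id)])
  res <- structure(list(
    spec = spec,
    closure = closure,
    af_tf_star = af_tf_star,
    af_mf = af_mf,
    weights_raw = raw,
    weights = weights,
    stage_shares = if (has_stage) stage_shares(weights, spec$factors) else NULL,
    level1_shares = if (has_stage) level1_shares(weights, spec$factors) else NULL,
    settings = list(max_len = max_len, tol = tol, normalize = normalize,
                    closure_length = attr(closure, "length"),
                    truncated = attr(closure, "truncated"))),
    class = "mdm")
  res
}

#' @export
print.mdm <- function(x, digits = 3, ...) {
  cat("Multiple-domain importance propagation\n")
  s <- x$settings
  cat(sprintf("  closure: %d term(s), normalization '%s'%s\n",
              s$closure_length, s$normalize,
              if (isTRUE(s$truncated)) " (series truncated)" else ""))
  cat("  global importance weights:\n")
  print(round(sort(x$weights, decreasing = TRUE), digits))
  invisible(x)
}

#' @export
coef.mdm <- function(object, ...) object$weights

#' @export
summary.mdm <- function(object, ...) {
  structure(list(weights = object$weights,
                 stage_shares = object$stage_shares,
                 level1_shares = object$level1_shares,
                 settings = object$settings),
            class = "summary.mdm")
}

#' @export
print.summary.mdm <- function(x, digits = 3, ...) {
  cat("Global importance weights (unit sum):\n")
  print(round(sort(x$weights, decreasing = TRUE), digits))
  if (!is.null(x$stage_shares)) {
    cat("\nShares by medication stage:\n")
    print(x$stage_shares, digits = digits)
  }
  if (!is.null(x$level1_shares)) {
    cat("\nShares by first-level factor:\n")
    print(x$level1_shares, digits = digits)
  }
  invisible(x)
}

#' @export
plot.mdm <- function(x, ...) {
  w <- sort(x$weights, decreasing = TRUE)
  graphics::barplot(w, las = 2, ylab = "global importance weight", ...)
  invisible(x)
}

#' Aggregate factor weights by medication stage
#'
#' Sums a per-factor weight vector over the pre-, during- and post-medication
#' stages.  The vector is used as given (no renormalisation), so applying the
#' function to a printed importance column reproduces its printed stage sums
#' exactly.
#'
#' @param weights named numeric vector of per-factor weights.
#' @param factors factor table mapping ids to stages
#'   (see \code{\link{factor_codes}}).
#' @return data.frame with one row per stage: \code{stage}, \code{share}
#'   (sum of member weights), \code{count}, \code{mean}.
#' @export
stage_shares <- function(weights, factors = factor_codes(names(weights))) {
  if (is.null(names(weights)))
    stop("'weights' must be a named vector", call. = FALSE)
  idx <- match(names(weights), factors$id)
  if (anyNA(idx))
    stop("unknown factor id(s): ",
         paste(names(weights)[is.na(idx)], collapse = ", "), call. = FALSE)
  stage <- factors$stage[idx]
  if (anyNA(stage))
    stop("factor(s) without a stage: ",
         paste(names(weights)[is.na(stage)], collapse = ", "), call. = FALSE)
  lev <- c("pre", "during", "post")
  share <- vapply(lev, function(s) sum(weights[stage == s]), numeric(1))
  count <- vapply(lev, function(s) sum(stage == s), numeric(1))
  data.frame(stage = lev, share = share, count = as.integer(count),
             mean = ifelse(count > 0, share / count, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate level-2 factor weights by their level-1 parent
#'
#' @inheritParams stage_shares
#' @return data.frame with one row per parent: \code{parent}, \code{share},
#'   \code{count}, \code{mean}.
#' @export
level1_shares <- function(weights, factors = factor_codes(names(weights))) {
  if (is.null(names(weights)))
    stop("'weights' must be a named vector", call. = FALSE)
  idx <- match(names(weights), factors$id)
  if (anyNA(idx))
    stop("unknown factor id(s): ",
         paste(names(weights)[is.na(idx)], collapse = ", "), call. = FALSE)
  parent <- factors$parent[idx]
  if (anyNA(parent))
    stop("factor(s) without a level-1 parent: ",
         paste(names(weights)[is.na(parent)], collapse = ", "), call. = FALSE)
  lev <- unique(parent)
  share <- vapply(lev, function(p) sum(weights[parent == p]), numeric(1))
  count <- vapply(lev, function(p) sum(parent == p), numeric(1))
  data.frame(parent = lev, share = share, count = as.integer(count),
             mean = share / count, row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank actual factors under one guiding objective
#'
#' Sorts the factors by their score in one main-factor column of the
#' AF x MF matrix, reports each score as a ratio to the column's reference
#' factor (the maximum), and breaks ties lexicographically on the factor id.
#'
#' @param af_mf AF x MF matrix (e.g. component \code{af_mf} of a fitted
#'   \code{\link{mdm}} object, or a published table).
#' @param goal a main-factor column name.
#' @return data.frame of class \code{"goal_ranking"} with columns
#'   \code{factor}, \code{score}, \code{ratio}; attributes \code{goal} and
#'   \code{reference}.
#' @export
goal_ranking <- function(af_mf, goal) {
  if (inherits(af_mf, "mdm")) af_mf <- af_mf$af_mf
  if (!goal %in% colnames(af_mf))
    stop("unknown goal '", goal, "'; available: ",
         paste(colnames(af_mf), collapse = ", "), call. = FALSE)
  score <- af_mf[, goal]
  ids <- rownames(af_mf)
  ord <- order(-score, ids)
  score <- score[ord]; ids <- ids[ord]
  ref_val <- score[1]
  ratio <- if (ref_val > 0) score / ref_val else rep(0, length(score))
  out <- data.frame(factor = ids, score = unname(score),
                    ratio = unname(ratio),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, goal = goal, reference = ids[1],
            class = c("goal_ranking", "data.frame"))
}

#' @export
print.goal_ranking <- function(x, digits = 3, ...) {
  cat(sprintf("Factor ranking for goal '%s' (reference: %s)\n",
              attr(x, "goal"), attr(x, "reference")))
  print.data.frame(cbind(x[1], round(x[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Rank agreement between two weight vectors
#'
#' Spearman rank correlation between a computed importance vector and a
#' reference (e.g. published) one, used as a diagnostic where end-to-end
#' numerical reproduction is not defined.
#'
#' @param x,y named numeric vectors over the same factors.
#' @return Spearman correlation in \code{[-1, 1]}.
#' @export
rank_agreement <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    if (length(common) < 2) stop("fewer than 2 shared factors", call. = FALSE)
    x <- x[common]; y <- y[common]
  }
  stats::cor(x, y, method = "spearman")
}
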