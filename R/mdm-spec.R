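#' Build the factor table for an MDM specification
#'
#' Factors are coded \code{"X-j"} (level 1) or \code{"X-j.k"} (level 2) with
#' the leading letter giving the medication stage: \code{A} = pre-medication,
#' \code{B} = during medication, \code{C} = post-medication.  Level-2 codes
#' inherit their level-1 parent from the code itself.
#'
#' @param ids character vector of factor codes.
#' @param labels optional character vector of human-readable labels.
#' @return a data.frame with columns \code{id}, \code{label}, \code{stage},
#'   \code{level}, \code{parent}.  \code{stage}/\code{parent} are \code{NA}
#'   for ids that do not follow the coding scheme (allowed in toy examples).
#' @export
factor_codes <- function(ids, labels = ids) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  stage_map <- c(A = "pre", B = "during", C = "post")
  lead <- substr(ids, 1, 1)
  stage <- unname(stage_map[lead])
  coded <- grepl("^[ABC]-[0-9]+(\\.[0-9]+)?$", ids)
  stage[!coded] <- NA_character_
  level <- ifelse(grepl("\\.", ids), 2L, 1L)
  level[!coded] <- NA_integer_
  parent <- ifelse(coded & level == 2L, sub("\\.[0-9]+$", "", ids), NA_character_)
  bad <- !is.na(parent) & !(parent %in% ids) & coded
  # a parent need not be listed explicitly; it is implied by the code
  data.frame(id = ids, label = labels, stage = stage, level = level,
             parent = parent, stringsAsFactors = FALSE)
}

check_nonneg_matrix <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (anyNA(m)) stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  if (any(m < 0)) stop(sprintf("'%s' has negative entries", name), call. = FALSE)
  invisible(m)
}

#' Assemble and validate an MDM specification
#'
#' Bundles the four elicited relationship matrices that drive the
#' multiple-domain-matrix importance propagation:
#' the outcome weights over the main factors (MF), the time-factor-by-main-factor
#' Likert scores (TF x MF), the actual-factor-by-time-factor matrix (AF x TF)
#' and the actual-factor influence matrix (AF x AF).
#'
#' @param mf_weights named nonnegative vector over the main factors, summing
#'   to 1 (tolerance 1e-9).
#' @param tf_mf TF x MF matrix of elicited scores in \code{[0, 9]}.
#' @param af_tf AF x TF nonnegative matrix.
#' @param af_af square AF x AF nonnegative influence matrix with zero diagonal.
#' @param factors optional factor table (see \code{\link{factor_codes}});
#'   defaults to codes derived from the rownames of \code{af_tf}.
#' @return an object of class \code{"mdm_spec"}.
#' @examples
#' spec <- mdm_spec(
#'   mf_weights = c(goal = 1),
#'   tf_mf = matrix(2, 1, 1, dimnames = list("T1", "goal")),
#'   af_tf = matrix(1, 2, 1, dimnames = list(c("F1", "F2"), "T1")),
#'   af_af = matrix(c(0, 0, 1, 0), 2, 2,
#'                  dimnames = list(c("F1", "F2"), c("F1", "F2"))))
#' @export
mdm_spec <- function(mf_weights, tf_mf, af_tf, af_af, factors = NULL) {
  if (is.null(names(mf_weights)))
    stop("'mf_weights' must be named by main factor", call. = FALSE)
  if (any(mf_weights < 0)) stop("'mf_weights' must be nonnegative", call. = FALSE)
  if (abs(sum(mf_weights) - 1) > 1e-9)
    stop("'mf_weights' must sum to 1", call. = FALSE)

  check_nonneg_matrix(tf_mf, "tf_mf")
  if (any(tf_mf > 9)) stop("'tf_mf' scores must lie in [0, 9]", call. = FALSE)
  check_nonneg_matrix(af_tf, "af_tf")
  check_nonneg_matrix(af_af, "af_af")
  if (nrow(af_af) != ncol(af_af))
    stop("'af_af' must be square", call. = FALSE)
  if (any(diag(af_af) != 0))
    stop("'af_af' must have a zero diagonal (no self-influence)", call. = FALSE)

  # label agreement along the chain AF -> TF -> MF -> PD
  pair_check <- function(a, b, what) {
    if (!identical(a, b))
      stop(sprintf("label mismatch between %s", what), call. = FALSE)
  }
  pair_check(rownames(af_tf), rownames(af_af), "af_tf rows and af_af rows")
  pair_check(rownames(af_af), colnames(af_af), "af_af rows and af_af columns")
  pair_check(colnames(af_tf), rownames(tf_mf), "af_tf columns and tf_mf rows")
  pair_check(colnames(tf_mf), names(mf_weights), "tf_mf columns and mf_weights")

  if (is.null(factors)) factors <- factor_codes(rownames(af_tf))
  if (!all(rownames(af_tf) %in% factors$id))
    stop("every af_tf row must appear in the factor table", call. = FALSE)

  structure(list(mf_weights = mf_weights, tf_mf = tf_mf,
                 af_tf = af_tf, af_af = af_af, factors = factors),
            class = "mdm_spec")
}

#' @export
print.mdm_spec <- function(x, ...) {
  cat("MDM specification\n")
  cat(sprintf("  %d actual factors, %d time factors, %d main factors\n",
              nrow(x$af_tf), ncol(x$af_tf), length(x$mf_weights)))
  cat("  main-factor weights:\n")
  print(round(x$mf_weights, 4))
  invisible(x)
}

#' Read an MDM specification from JSON
#'
#' The file holds \code{factors} (objects with \code{id}, \code{label}),
#' \code{mf_weights} (object keyed by main-factor name) and the three
#' matrices \code{tf_mf}, \code{af_tf}, \code{af_af}, each encoded as
#' \code{rows}, \code{cols} and dense row-major \code{values}.
#'
#' @param path path to a JSON file.
#' @return an \code{"mdm_spec"} object.
#' @export
read_mdm_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  mf <- unlist(j$mf_weights)
  factors <- factor_codes(j$factors$id, j$factors$label)
  mdm_spec(mf_weights = mf,
           tf_mf = decode_matrix_block(j$tf_mf),
           af_tf = decode_matrix_block(j$af_tf),
           af_af = decode_matrix_block(j$af_af),
           factors = factors)
}

# dense row-major JSON block {rows, cols, values} -> labelled matrix
decode_matrix_block <- function(block) {
  v <- block$values
  if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
  if (!is.matrix(v)) v <- matrix(as.numeric(v), nrow = length(block$rows),
                                 ncol = length(block$cols), byrow = TRUE)
  dimnames(v) <- list(block$rows, block$cols)
  v
}
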