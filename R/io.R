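#' Read a wide-format panel CSV
#'
#' Expects columns \code{dmu}, \code{period}, then one \code{in:<name>}
#' column per input and one \code{out:<name>} column per output.  The panel
#' must be complete (every DMU observed in every period), without duplicate
#' \code{(dmu, period)} rows, and strictly positive: the indicators are
#' counts and ratios, and efficiency against a zero input is undefined.
#' Zeros can optionally be replaced by a small fraction of the column mean.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param epsilon \code{FALSE} (default) to reject zeros; \code{TRUE} to
#'   replace them by \code{1e-6} times the column mean, or a numeric factor
#'   to use instead of \code{1e-6}.  Negative values are always rejected.
#' @return a \code{\link{panel_dataset}}.
#' @export
read_panel_csv <- function(path, epsilon = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("dmu", "period")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  in_cols <- grep("^in:", names(df), value = TRUE)
  out_cols <- grep("^out:", names(df), value = TRUE)
  if (!length(in_cols) || !length(out_cols))
    stop("need at least one 'in:' and one 'out:' column", call. = FALSE)
  panel_from_frame(df, in_cols, out_cols, epsilon, path)
}

panel_from_frame <- function(df, in_cols, out_cols, epsilon, path) {
  df$dmu <- as.character(df$dmu); df$period <- as.character(df$period)
  if (anyDuplicated(df[c("dmu", "period")]))
    stop("duplicate (dmu, period) rows in ", path, call. = FALSE)
  for (cn in c(in_cols, out_cols)) {
    v <- df[[cn]]
    if (!is.numeric(v))
      stop("non-numeric cell(s) in column '", cn, "'", call. = FALSE)
    if (anyNA(v))
      stop("missing value in column '", cn, "', row ",
           which(is.na(v))[1], call. = FALSE)
    if (any(v < 0))
      stop("negative value in column '", cn, "', row ",
           which(v < 0)[1], call. = FALSE)
    if (any(v == 0)) {
      if (identical(epsilon, FALSE))
        stop("non-positive value in column '", cn, "', row ",
             which(v == 0)[1],
             " (dmu ", df$dmu[which(v == 0)[1]],
             ", period ", df$period[which(v == 0)[1]],
             "); rerun with an epsilon replacement to impute zeros",
             call. = FALSE)
      fac <- if (isTRUE(epsilon)) 1e-6 else as.numeric(epsilon)
      df[[cn]][v == 0] <- fac * mean(v)
    }
  }
  dmus <- unique(df$dmu); periods <- unique(df$period)
  full <- expand.grid(dmu = dmus, period = periods, stringsAsFactors = FALSE)
  have <- paste(df$dmu, df$period, sep = "\r")
  missing <- !(paste(full$dmu, full$period, sep = "\r") %in% have)
  if (any(missing))
    stop("incomplete panel; missing cells: ",
         paste(paste0("(", full$dmu[missing], ", ", full$period[missing], ")"),
               collapse = ", "), call. = FALSE)
  n <- length(dmus); Tn <- length(periods)
  x <- array(NA_real_, c(n, Tn, length(in_cols)))
  y <- array(NA_real_, c(n, Tn, length(out_cols)))
  ij <- cbind(match(df$dmu, dmus), match(df$period, periods))
  for (k in seq_along(in_cols)) x[cbind(ij, k)] <- df[[in_cols[k]]]
  for (k in seq_along(out_cols)) y[cbind(ij, k)] <- df[[out_cols[k]]]
  panel_dataset(x, y, dmu_ids = dmus, period_ids = periods,
                input_names = sub("^in:", "", in_cols),
                output_names = sub("^out:", "", out_cols))
}

#' Read a long-format panel CSV
#'
#' Expects columns \code{dmu}, \code{period}, \code{variable}, \code{role}
#' (\code{"input"} or \code{"output"}) and \code{value}.
#'
#' @inheritParams read_panel_csv
#' @return a \code{\link{panel_dataset}}.
#' @export
read_panel_long <- function(path, epsilon = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("dmu", "period", "variable", "role", "value")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!all(df$role %in% c("input", "output")))
    stop("'role' must be 'input' or 'output'", call. = FALSE)
  df$col <- paste0(ifelse(df$role == "input", "in:", "out:"), df$variable)
  wide <- stats::reshape(df[c("dmu", "period", "col", "value")],
                         idvar = c("dmu", "period"), timevar = "col",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  in_cols <- grep("^in:", names(wide), value = TRUE)
  out_cols <- grep("^out:", names(wide), value = TRUE)
  panel_from_frame(wide, in_cols, out_cols, epsilon, path)
}

#' Write a panel to a wide-format CSV
#'
#' Inverse of \code{\link{read_panel_csv}}; numeric values are written with
#' full double precision so a write/read round trip is lossless to well
#' below 1e-12 relative error.
#'
#' @param panel a \code{\link{panel_dataset}}.
#' @param path output path.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "panel_dataset"))
  n <- length(panel$dmu_ids); Tn <- length(panel$period_ids)
  grid <- expand.grid(period = seq_len(Tn), dmu = seq_len(n))
  df <- data.frame(dmu = panel$dmu_ids[grid$dmu],
                   period = panel$period_ids[grid$period],
                   stringsAsFactors = FALSE)
  for (k in seq_along(panel$input_names))
    df[[paste0("in:", panel$input_names[k])]] <-
      panel$x[cbind(grid$dmu, grid$period, k)]
  for (k in seq_along(panel$output_names))
    df[[paste0("out:", panel$output_names[k])]] <-
      panel$y[cbind(grid$dmu, grid$period, k)]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

fixture_names <- c("table3_mdm", "table3_global_weights", "table4_malmquist")

#' Load a packaged fixture of the published tables
#'
#' Three curated encodings ship with the package:
#' \describe{
#'   \item{\code{table3_mdm}}{the full MDM instance (four relationship
#'     matrices) as an \code{\link{mdm_spec}}, with the published AF x MF
#'     block attached as attribute \code{"printed_af_mf"}.}
#'   \item{\code{table3_global_weights}}{the published global importance
#'     column, a named 17-vector; the authoritative input for the
#'     aggregation arithmetic.}
#'   \item{\code{table4_malmquist}}{the published 31 x 6 provincial
#'     Malmquist index matrix.}
#' }
#'
#' @param name one of the fixture names above.
#' @return see Description.
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% fixture_names))
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names, collapse = ", "), call. = FALSE)
  ext <- if (name == "table4_malmquist") ".csv" else ".json"
  path <- system.file("extdata", paste0(name, ext), package = "pedeval",
                      mustWork = TRUE)
  switch(name,
    table3_mdm = {
      spec <- read_mdm_spec(path)
      j <- jsonlite::fromJSON(path)
      attr(spec, "printed_af_mf") <- decode_matrix_block(j$af_mf_printed)
      spec
    },
    table3_global_weights = {
      j <- jsonlite::fromJSON(path)
      unlist(j$weights)
    },
    table4_malmquist = {
      df <- utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      m
    })
}

#' Assemble a report table with summary footer
#'
#' Lays out a DMU x period-pair index matrix the way panel efficiency
#' results are conventionally reported: an \code{Average} column of per-DMU
#' means and footer rows \code{Average}/\code{Max}/\code{Min}/\code{SD}
#' over DMUs.
#'
#' @param x a numeric DMU x pair matrix or a \code{\link{malmquist}} fit.
#' @param title optional report title.
#' @param digits rendering precision (default 4 decimals).
#' @return an object of class \code{"report_table"}.
#' @export
report_table <- function(x, title = "Malmquist index", digits = 4) {
  if (inherits(x, "malmquist")) x <- x$index
  x <- as.matrix(x)
  if (!is.numeric(x) || length(x) == 0)
    stop("'x' must be a non-empty numeric matrix", call. = FALSE)
  s <- malmquist_summary(x)
  body <- cbind(x, Average = s$dmu_means)
  footer <- cbind(s$pair_stats,
                  Average = c(s$grand_mean, max(s$dmu_means),
                              min(s$dmu_means), stats::sd(s$dmu_means)))
  rownames(footer) <- c("Average", "Max", "Min", "SD")
  structure(list(title = title, body = body, footer = footer,
                 digits = digits),
            class = "report_table")
}

#' Render a report table as text or CSV
#'
#' @param table a \code{\link{report_table}}.
#' @param format \code{"text"} for an aligned listing, \code{"csv"} for
#'   comma-separated lines.
#' @return a character vector of lines.
#' @export
render_report <- function(table, format = c("text", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "report_table"))
  full <- rbind(table$body, table$footer)
  cells <- formatC(full, format = "f", digits = table$digits)
  if (format == "csv") {
    header <- paste(c("row", colnames(full)), collapse = ",")
    rows <- apply(cbind(rownames(full), cells), 1,
                  paste, collapse = ",")
    c(header, unname(rows))
  } else {
    wide <- max(nchar(rownames(full)), nchar(colnames(full)),
                nchar(cells)) + 2L
    pad <- function(v) formatC(v, width = wide)
    lines <- c(if (nzchar(table$title)) table$title,
               paste0(formatC("", width = wide),
                      paste(pad(colnames(full)), collapse = "")),
               vapply(seq_len(nrow(full)), function(i)
                 paste0(formatC(rownames(full)[i], width = wide,
                                flag = "-"),
                        paste(pad(cells[i, ]), collapse = "")),
                 character(1)))
    lines
  }
}

#' @export
print.report_table <- function(x, ...) {
  writeLines(render_report(x, "text"))
  invisible(x)
}
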