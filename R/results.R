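## Time-indexed result container and writers.

#' Result table
#'
#' Time-indexed matrix of quantity values produced by integration; rows
#' are strictly increasing output times, columns the indexed quantities.
#'
#' @param times numeric vector of output times.
#' @param values matrix (length(times) x quantities) with column names.
#' @param ... further attributes (e.g. `fired`, `n_steps`).
#' @return An object of class `result_table`.
#' @export
result_table <- function(times, values, ...) {
  stopifnot(nrow(values) == length(times))
  tab <- list(times = times, values = values, ids = colnames(values))
  extra <- list(...)
  for (nm in names(extra)) attr(tab, nm) <- extra[[nm]]
  class(tab) <- "result_table"
  tab
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table: ", length(x$times), " time points x ",
      ncol(x$values), " quantities [",
      paste(utils::head(x$ids, 6L), collapse = ", "),
      if (ncol(x$values) > 6L) ", ..." else "", "]>\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.result_table <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Value of one quantity at (interpolated) times
#'
#' @param table a [result_table].
#' @param id quantity identifier.
#' @param t optional times to linearly interpolate at; defaults to the
#'   table's own grid.
#' @return Numeric vector.
#' @export
result_column <- function(table, id, t = NULL) {
  if (!(id %in% table$ids))
    stop("no such quantity in results: '", id, "'", call. = FALSE)
  y <- table$values[, id]
  if (is.null(t)) return(y)
  stats::approx(table$times, y, xout = t, rule = 2)$y
}

#' Write a result table to CSV or TSV
#'
#' First column `time`, then one column per quantity; floating-point
#' values are written with 17 significant digits so a read-back
#' reproduces them bit-exactly.
#'
#' @param table a [result_table].
#' @param path output file path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- as.data.frame(table)
  txt <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(seq_len(ncol(df)), function(j)
      sprintf("%.17g", df[i, j]), character(1)), collapse = sep),
    character(1))
  writeLines(c(paste(colnames(df), collapse = sep), txt), path)
  invisible(path)
}
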