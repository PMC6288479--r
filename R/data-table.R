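#' Construct a data table from named numeric columns
#'
#' @param ... named numeric vectors of equal length, or a single data.frame.
#' @param units optional named character of per-column unit labels; columns
#'   without a declared unit get "".
#' @return A [DataTable-class].
#' @export
dataTable <- function(..., units = character(0)) {
  cols <- list(...)
  if (length(cols) == 1L && is.data.frame(cols[[1]])) df <- cols[[1]]
  else df <- as.data.frame(cols, optional = TRUE)
  u <- stats::setNames(rep("", ncol(df)), names(df))
  u[names(units)] <- units
  new("DataTable", columns = df, units = u)
}

#' Columns of a data table
#'
#' @param table a [DataTable-class].
#' @return The underlying data.frame.
#' @export
tableColumns <- function(table) table@columns

#' Declared column units of a data table
#'
#' @param table a [DataTable-class].
#' @return Named character vector ("" where undeclared).
#' @export
tableUnits <- function(table) table@units

#' Read experimental data from a CSV file
#'
#' The data file is plain comma-separated values: the first row names each
#' variable and the remaining rows hold the numeric data, one column per
#' variable ('.' decimal, optional CRLF line endings, no quoting). Ragged
#' rows, duplicate names, a missing header row and non-numeric cells are
#' all rejected. Flattened higher-dimensional arrays are not supported.
#'
#' @param path path to a CSV file, or a character vector of CSV lines.
#' @param units optional named character declaring per-column units (usually
#'   supplied later from the fitting specification's sidecar entry).
#' @return A [DataTable-class].
#' @examples
#' readDataTable(c("t,exp_IKr", "0,0.0", "1e-4,0.02"))
#' @export
readDataTable <- function(path, units = character(0)) {
  lines <- if (length(path) == 1L && !grepl("[,\n]", path)) {
    if (!file.exists(path)) stop("no such data file: ", path, call. = FALSE)
    readLines(path, warn = FALSE)
  } else unlist(strsplit(path, "\n", fixed = TRUE))
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("data file must contain a header row and at least one data row",
         call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(fields[[1]])
  if (any(!is.na(suppressWarnings(as.numeric(header)))))
    stop("missing header: the first row must specify names for each ",
         "variable, found numeric value(s)", call. = FALSE)
  if (anyDuplicated(header))
    stop("duplicate column name(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  ncolumns <- length(header)
  nf <- lengths(fields[-1])
  if (any(nf != ncolumns))
    stop("ragged rows: row(s) ", paste(utils::head(which(nf != ncolumns) + 1L, 5),
                                       collapse = ", "),
         " do not have ", ncolumns, " fields", call. = FALSE)
  body <- unlist(fields[-1], use.names = FALSE)
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals))
    stop("non-numeric cell(s) in data file, e.g. '",
         body[which(is.na(vals))[1]], "'", call. = FALSE)
  m <- matrix(vals, ncol = ncolumns, byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- header
  dataTable(df, units = units)
}

#' Write a data table to CSV
#'
#' @param table a [DataTable-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDataTable <- function(table, path) {
  utils::write.csv(table@columns, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
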