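# Uniform reader over CSV files, Excel workbooks and relational databases.
# All cells are carried as character (NA for nulls); declared types are an
# inference used for mapping diagnostics, not a coercion.

#' Construct a source table
#'
#' Internal constructor; all cells are normalized to character with the
#' configured null tokens ("", "NA", "NULL", case-insensitive) mapped to NA.
#' @noRd
new_source_table <- function(df, name) {
  stopifnot(is.data.frame(df))
  names(df) <- trimws(names(df))
  if (anyDuplicated(names(df))) {
    fc_stop("source_open", sprintf("duplicate column names in table '%s'", name))
  }
  for (j in seq_along(df)) {
    v <- as.character(df[[j]])
    v[tolower(trimws(v)) %in% NULL_TOKENS] <- NA_character_
    df[[j]] <- v
  }
  attr(df, "table_name") <- name
  attr(df, "declared_types") <- infer_column_types(df)
  class(df) <- c("source_table", "data.frame")
  df
}

#' Sample-based column type inference
#'
#' A column is promoted to integer/decimal/date/datetime only if every
#' non-null cell parses as that type; any non-conforming cell demotes the
#' column to text. Columns with no non-null cells are 'unknown'.
#' @noRd
infer_column_types <- function(df) {
  vapply(df, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return("unknown")
    if (all(grepl("^[+-]?[0-9]+$", trimws(v)))) return("integer")
    if (!anyNA(suppressWarnings(as.numeric(v)))) return("decimal")
    if (all(grepl("^\\d{4}-\\d{2}-\\d{2}T", v))) return("datetime")
    if (!any(is.na(vapply(v, parse_source_date, "")))) return("date")
    "text"
  }, "")
}

#' Open a tabular data source
#'
#' Accepts a CSV file, a directory of CSV files, an Excel workbook
#' (\code{.xlsx}, one table per sheet; requires the readxl package) or a DBI
#' connection (one table per database table, read-only). Returns one
#' \code{source_table} per table, named after the file stem, sheet or table.
#'
#' @param locator A file path, directory path, or a \code{DBIConnection}.
#' @return Named list of \code{source_table} objects.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patientid,gender,birthdate",
#'              "p1,H,1950-01-02", "p2,M,1960-03-04", "p3,M,1971-05-06"), f)
#' src <- open_source(f)
#' source_row_count(src[[1]])
#' @export
open_source <- function(locator) {
  if (inherits(locator, "DBIConnection")) {
    if (!requireNamespace("DBI", quietly = TRUE)) {
      fc_stop("source_open", "DBI is required for database sources")
    }
    tabs <- DBI::dbListTables(locator)
    out <- lapply(tabs, function(tn) {
      new_source_table(DBI::dbReadTable(locator, tn), tn)
    })
    names(out) <- tabs
    return(out)
  }
  if (!is.character(locator) || length(locator) != 1) {
    fc_stop("source_open", "locator must be a path or a DBI connection")
  }
  if (dir.exists(locator)) {
    files <- list.files(locator, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) {
      fc_stop("source_open", sprintf("no CSV files under %s", locator))
    }
    out <- lapply(files, read_csv_table)
    names(out) <- vapply(out, source_table_name, "")
    return(out)
  }
  if (!file.exists(locator)) {
    fc_stop("source_open", sprintf("source not found: %s", locator))
  }
  ext <- tolower(tools::file_ext(locator))
  if (ext == "csv") {
    t <- read_csv_table(locator)
    return(stats::setNames(list(t), source_table_name(t)))
  }
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      fc_stop("source_open", "readxl is required for Excel sources")
    }
    sheets <- readxl::excel_sheets(locator)
    out <- lapply(sheets, function(s) {
      df <- as.data.frame(readxl::read_excel(locator, sheet = s,
                                             col_types = "text"))
      new_source_table(df, s)
    })
    names(out) <- sheets
    return(out)
  }
  fc_stop("source_open", sprintf("unsupported source format: .%s", ext))
}

read_csv_table <- function(path) {
  name <- tools::file_path_sans_ext(basename(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) {
    fc_warn(sprintf("empty source file %s; table has zero columns", path))
    return(new_source_table(data.frame(), name))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8", na.strings = NULL)
  new_source_table(df, name)
}

#' @export
print.source_table <- function(x, ...) {
  cat("<source_table>", source_table_name(x), "-", nrow(x), "row(s)\n")
  tp <- attr(x, "declared_types")
  for (nm in names(tp)) cat(sprintf("  %-20s %s\n", nm, tp[[nm]]))
  invisible(x)
}

#' Table name, declared column types and row count of a source table
#' @param table A \code{source_table}.
#' @return \code{source_table_name}: the table name;
#'   \code{source_column_types}: named character vector of declared types
#'   (\code{text}, \code{integer}, \code{decimal}, \code{date},
#'   \code{datetime}, \code{unknown}); \code{source_row_count}: number of
#'   data rows (header excluded).
#' @export
source_table_name <- function(table) attr(table, "table_name")

#' @rdname source_table_name
#' @export
source_column_types <- function(table) attr(table, "declared_types")

#' @rdname source_table_name
#' @export
source_row_count <- function(table) nrow(table)

#' Peek at the first rows of a source table
#'
#' Returns the first \code{min(n, row_count)} rows in file order, as a list
#' of row cell maps (named lists keyed by column name; nulls are NA).
#'
#' @param table A \code{source_table}.
#' @param n Number of rows requested (>= 0).
#' @return List of named lists, one per row.
#' @export
peek <- function(table, n = 10L) {
  stopifnot(inherits(table, "source_table"), n >= 0)
  k <- min(n, nrow(table))
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) as.list(table[i, , drop = FALSE]))
}
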