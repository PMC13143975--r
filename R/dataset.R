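#' Construct a dataset bound to a variable table
#'
#' A dataset is an `n_rows x n_cols` numeric matrix (missing values as `NA`)
#' whose columns follow the order of an associated variable table. Binary and
#' ordinal columns must hold integer codes.
#'
#' @param values numeric matrix or data frame; column names must match the
#'   variable table exactly (any order; columns are reordered).
#' @param table a [variable_table()].
#' @param row_ids optional row identifiers (default `"1"`, `"2"`, ...).
#' @return a `tierpc_dataset`: list with elements `values` (matrix),
#'   `row_ids`, `table`.
#' @export
dataset <- function(values, table, row_ids = NULL) {
  validate_variable_table(table)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    stop("dataset values must have column names", call. = FALSE)
  }
  extra <- setdiff(colnames(values), table$name)
  if (length(extra) > 0L) {
    stop("column(s) not in variable table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(table$name, colnames(values))
  if (length(absent) > 0L) {
    stop("variable table column(s) missing from data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  values <- values[, table$name, drop = FALSE]
  if (nrow(values) < 1L) stop("dataset needs at least one row", call. = FALSE)
  if (ncol(values) < 2L) stop("dataset needs at least two columns", call. = FALSE)
  disc <- table$name[table$vtype %in% c("binary", "ordinal")]
  for (v in disc) {
    col <- values[, v]
    obs <- col[!is.na(col)]
    if (length(obs) > 0L && any(obs != round(obs))) {
      stop("binary/ordinal column '", v, "' holds non-integer codes",
           call. = FALSE)
    }
  }
  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(values)))
  structure(
    list(values = values, row_ids = as.character(row_ids), table = table),
    class = "tierpc_dataset"
  )
}

#' Read a dataset from CSV against a variable table
#'
#' The file must be comma-separated with a header row; headers must match the
#' variable-table names exactly (any order). Cells equal to
#' `missing_sentinel` are marked missing; columns are reordered to the table
#' order. Per-column missing counts are attached as attribute
#' `"missing_per_column"`.
#'
#' @param path path to the CSV file.
#' @param table a [variable_table()].
#' @param missing_sentinel string marking a missing cell (default `"NA"`).
#' @return a `tierpc_dataset`.
#' @export
read_dataset <- function(path, table, missing_sentinel = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_variable_table(table)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  extra <- setdiff(names(raw), table$name)
  if (length(extra) > 0L) {
    stop("unknown column(s) in '", path, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(table$name, names(raw))
  if (length(absent) > 0L) {
    stop("'", path, "' lacks column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = nrow(table),
                 dimnames = list(NULL, table$name))
  for (v in table$name) {
    cell <- raw[[v]]
    is_miss <- cell == missing_sentinel | is.na(cell) | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_miss & is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric value '", cell[bad[1L]], "' in column '", v,
           "', line ", bad[1L] + 1L, " of '", path, "'", call. = FALSE)
    }
    num[is_miss] <- NA_real_
    vals[, v] <- num
  }
  ds <- dataset(vals, table)
  attr(ds, "missing_per_column") <- colSums(is.na(vals))
  ds
}

#' Write a dataset to CSV
#'
#' Missing cells are written as `missing_sentinel`; the written file round
#' trips through [read_dataset()] with identical values and missingness mask.
#'
#' @param ds a `tierpc_dataset`.
#' @param path output path.
#' @param missing_sentinel string for missing cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, missing_sentinel = "NA") {
  stopifnot(inherits(ds, "tierpc_dataset"))
  df <- as.data.frame(ds$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   na = missing_sentinel)
  invisible(path)
}

#' @export
print.tierpc_dataset <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("Dataset: %d rows x %d variables (%.1f%% cells missing)\n",
              nrow(x$values), ncol(x$values),
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.tierpc_dataset <- function(x) dim(x$values)

# Coerce input that may be a tierpc_dataset, matrix or data.frame into a
# plain numeric matrix with column names.
dataset_values <- function(data) {
  if (inherits(data, "tierpc_dataset")) return(data$values)
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) stop("data must have column names", call. = FALSE)
  m
}
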