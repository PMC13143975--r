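#' Construct a variable table
#'
#' A variable table carries the per-variable metadata that drives every later
#' choice in the pipeline: the numeric type (`binary`, `ordinal` or `cardinal`)
#' selects the conditional-independence test family, and the time epoque
#' (an integer tier in 1..8) constrains edge orientation — causal edges may
#' never point from a later epoque into an earlier one.
#'
#' @param name character vector of unique variable names. Names are restricted
#'   to `[A-Za-z0-9_.:-]` so they survive SIF/GraphML export unescaped.
#' @param vtype character vector, one of `"binary"`, `"ordinal"`, `"cardinal"`
#'   per variable.
#' @param epoque integer vector of time epoques, each in 1..8.
#' @return A `tierpc_vartable`: a data frame with columns `name`, `vtype`,
#'   `epoque`.
#' @examples
#' variable_table(c("A", "B", "C"), c("cardinal", "ordinal", "binary"), c(3, 8, 1))
#' @export
variable_table <- function(name, vtype, epoque) {
  tab <- data.frame(
    name = as.character(name),
    vtype = as.character(vtype),
    epoque = as.integer(epoque),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("tierpc_vartable", "data.frame")
  validate_variable_table(tab)
  tab
}

#' Validate a variable table
#'
#' Checks name uniqueness and syntax, type membership and the 1..8 epoque
#' range; stops with an actionable message on the first violation.
#'
#' @param tab a `tierpc_vartable` or a data frame with columns
#'   `name`, `vtype`, `epoque`.
#' @return `tab`, invisibly, if valid.
#' @export
validate_variable_table <- function(tab) {
  req <- c("name", "vtype", "epoque")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0L) {
    stop("variable table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("variable table has no entries", call. = FALSE)
  if (anyNA(tab$name) || any(!nzchar(tab$name))) {
    stop("variable names must be non-empty", call. = FALSE)
  }
  bad_chr <- !grepl("^[A-Za-z0-9_.:-]+$", tab$name)
  if (any(bad_chr)) {
    stop("variable name(s) contain characters outside [A-Za-z0-9_.:-]: ",
         paste(utils::head(tab$name[bad_chr], 5L), collapse = ", "),
         call. = FALSE)
  }
  dup <- tab$name[duplicated(tab$name)]
  if (length(dup) > 0L) {
    stop("duplicate variable name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(tab$vtype), c("binary", "ordinal", "cardinal"))
  if (length(bad_type) > 0L) {
    stop("unknown vtype value(s): ", paste(bad_type, collapse = ", "),
         "; expected binary, ordinal or cardinal", call. = FALSE)
  }
  ep <- tab$epoque
  if (anyNA(ep) || any(ep != as.integer(ep)) || any(ep < 1L) || any(ep > 8L)) {
    offenders <- tab$name[is.na(ep) | ep < 1L | ep > 8L]
    stop("epoque must be an integer in 1..8; offending variable(s): ",
         paste(utils::head(offenders, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Read a variable table from a CSV file
#'
#' Expects a comma-separated UTF-8 file with a header row containing the
#' columns `name`, `vtype` and `epoque` (any column order).
#'
#' @param path path to the CSV file.
#' @return a validated [variable_table()].
#' @export
read_variable_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) {
      stop("could not parse variable table '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  missing_cols <- setdiff(c("name", "vtype", "epoque"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("variable table '", path, "' lacks header column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ep_num <- suppressWarnings(as.numeric(raw$epoque))
  bad <- which(is.na(ep_num))
  if (length(bad) > 0L) {
    stop("non-numeric epoque at line ", bad[1L] + 1L, " of '", path, "'",
         call. = FALSE)
  }
  variable_table(raw$name, raw$vtype, ep_num)
}

#' Write a variable table to CSV
#'
#' @param tab a validated variable table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variable_table <- function(tab, path) {
  validate_variable_table(tab)
  utils::write.csv(as.data.frame(tab)[, c("name", "vtype", "epoque")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.tierpc_vartable <- function(x, ...) {
  cat(sprintf("Variable table: %d variables, epoques %d..%d\n",
              nrow(x), min(x$epoque), max(x$epoque)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

# named epoque lookup used throughout orientation code
epoque_map <- function(tab) {
  stats::setNames(as.integer(tab$epoque), tab$name)
}
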