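#' Construct a category-by-attribute value table
#'
#' A `data_matrix` is the input of every rose chart: rows are categories
#' (countries, months, chart types, ...), columns are numeric attributes
#' (rates, counts, ...). All values must be finite and non-negative; zero is
#' allowed and draws a petal of zero radial extent.
#'
#' @param values numeric matrix (or object coercible to one), categories in
#'   rows, attributes in columns.
#' @param categories character vector of unique, non-empty category names.
#'   Defaults to `rownames(values)`.
#' @param attributes character vector of unique, non-empty attribute names.
#'   Defaults to `colnames(values)`.
#' @param units optional named character vector of display units per
#'   attribute (e.g. `c("Death Rate" = "%")`).
#' @return An object of class `data_matrix`: a list with elements
#'   `categories`, `attributes`, `values` (a dimnamed numeric matrix) and
#'   `units`.
#' @examples
#' m <- data_matrix(matrix(c(1, 2, 3, 4), 2, 2),
#'                  categories = c("a", "b"), attributes = c("x", "y"))
#' value_at(m, "a", "y")
#' @export
data_matrix <- function(values, categories = rownames(values),
                        attributes = colnames(values), units = NULL) {
  values <- as.matrix(values)
  if (is.null(categories) || is.null(attributes)) {
    stop("data_matrix: categories and attributes must be supplied ",
         "(or present as dimnames)", call. = FALSE)
  }
  categories <- as.character(categories)
  attributes <- as.character(attributes)
  storage.mode(values) <- "double"
  dimnames(values) <- list(categories, attributes)
  m <- structure(
    list(categories = categories, attributes = attributes,
         values = values, units = units),
    class = "data_matrix"
  )
  validate_data_matrix(m)
}

#' Validate a data_matrix
#'
#' Checks the structural invariants: dimensions match the name vectors, names
#' are unique and non-empty, and every value is finite and non-negative.
#' Called by every constructor and loader; exported so user code can re-check
#' a matrix it has manipulated by hand.
#'
#' @param m a `data_matrix`.
#' @return `m`, invisibly unchanged, or an error describing the violation.
#' @export
validate_data_matrix <- function(m) {
  stopifnot(inherits(m, "data_matrix"))
  nc <- length(m$categories); na <- length(m$attributes)
  if (nc < 1L || na < 1L) {
    stop("data_matrix: need at least one category and one attribute",
         call. = FALSE)
  }
  if (!all(dim(m$values) == c(nc, na))) {
    stop(sprintf("data_matrix: value grid is %d x %d but names imply %d x %d",
                 nrow(m$values), ncol(m$values), nc, na), call. = FALSE)
  }
  check_names(m$categories, "category")
  check_names(m$attributes, "attribute")
  bad <- which(!is.finite(m$values) | m$values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "data_matrix: invalid value %s at row '%s', column '%s' (values must be finite and >= 0)",
      format(m$values[bad[1L, , drop = FALSE]]),
      m$categories[bad[1L, 1L]], m$attributes[bad[1L, 2L]]), call. = FALSE)
  }
  if (!is.null(m$units)) {
    unknown <- setdiff(names(m$units), m$attributes)
    if (length(unknown) > 0L) {
      stop("data_matrix: units given for unknown attribute(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  m
}

check_names <- function(x, what) {
  if (any(!nzchar(x)) || anyNA(x)) {
    stop(sprintf("data_matrix: %s names must be non-empty", what),
         call. = FALSE)
  }
  if (anyDuplicated(x)) {
    stop(sprintf("data_matrix: duplicate %s name '%s'", what,
                 x[duplicated(x)][1L]), call. = FALSE)
  }
  invisible(x)
}

#' Look up one cell of a data_matrix
#'
#' @param m a `data_matrix`.
#' @param category,attribute names of the cell.
#' @return the numeric value.
#' @export
value_at <- function(m, category, attribute) {
  stopifnot(inherits(m, "data_matrix"))
  if (!category %in% m$categories) {
    stop("unknown category: ", category, call. = FALSE)
  }
  if (!attribute %in% m$attributes) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  unname(m$values[category, attribute])
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix: %d categories x %d attributes>\n",
              length(x$categories), length(x$attributes)))
  print(x$values, ...)
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' @export
as.data.frame.data_matrix <- function(x, ...) {
  data.frame(category = x$categories, as.data.frame(x$values),
             check.names = FALSE, row.names = NULL)
}

#' Read a value table from CSV, TSV or JSON
#'
#' For the delimited formats the first column holds the category names and
#' the header row names the attributes (first header cell is the category
#' column title and is ignored). The JSON form is
#' `{"categories": [...], "attributes": [...], "values": [[row-major]],
#' "units": {...}}`. Row and column order of the file is preserved.
#'
#' @param source path to a file, or a connection.
#' @param format one of `"csv"`, `"tsv"`, `"json"`; the default guesses from
#'   the file extension and falls back to csv.
#' @return a validated [data_matrix()].
#' @examples
#' path <- system.file("extdata", "covid_rates.csv", package = "multirose")
#' m <- load_table(path)
#' value_at(m, "France", "Death Rate")
#' @export
load_table <- function(source, format = c("auto", "csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (is.character(source) && grepl("\\.json$", source,
                                                ignore.case = TRUE)) {
      "json"
    } else if (is.character(source) && grepl("\\.tsv$", source,
                                             ignore.case = TRUE)) {
      "tsv"
    } else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(source, simplifyVector = TRUE)
    required <- c("categories", "attributes", "values")
    if (!all(required %in% names(obj))) {
      stop("load_table: JSON table needs fields ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    vals <- obj$values
    if (!is.matrix(vals)) vals <- matrix(unlist(vals), nrow = length(obj$categories), byrow = TRUE)
    units <- if (!is.null(obj$units)) unlist(obj$units) else NULL
    return(data_matrix(vals, obj$categories, obj$attributes, units))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "",
                          encoding = "UTF-8")
  if (ncol(df) < 2L) {
    stop("load_table: header must have a category column plus at least one attribute",
         call. = FALSE)
  }
  if (nrow(df) < 1L) stop("load_table: no data rows", call. = FALSE)
  attributes <- colnames(df)[-1L]
  categories <- df[[1L]]
  vals <- matrix(NA_real_, nrow(df), length(attributes))
  for (j in seq_along(attributes)) {
    col <- trimws(df[[j + 1L]])
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(col))
    if (length(bad) > 0L) {
      stop(sprintf("load_table: non-numeric or missing cell '%s' at row '%s', column '%s'",
                   col[bad[1L]], categories[bad[1L]], attributes[j]),
           call. = FALSE)
    }
    vals[, j] <- num
  }
  data_matrix(vals, categories, attributes)
}

#' Write a value table to CSV, TSV or JSON
#'
#' Values round-trip at full double precision:
#' `load_table(write_table(m, f), ...)` reproduces `m` exactly.
#'
#' @param m a `data_matrix`.
#' @param path output file path or writable connection.
#' @param format one of `"csv"`, `"tsv"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(m, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  validate_data_matrix(m)
  if (format == "json") {
    obj <- list(categories = m$categories, attributes = m$attributes,
                values = unname(m$values))
    if (!is.null(m$units)) obj$units <- as.list(m$units)
    # I(17) significant digits: doubles survive the text round-trip exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         matrix = "rowmajor")
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  # format() would truncate doubles; print full precision explicitly
  chr <- matrix(vapply(m$values, function(v) sprintf("%.17g", v), ""),
                nrow = nrow(m$values))
  quote_field <- function(x) {
    need <- grepl(paste0("[\"\n", sep, "]"), x)
    x[need] <- paste0("\"", gsub("\"", "\"\"", x[need]), "\"")
    x
  }
  header <- paste(quote_field(c("Category", m$attributes)), collapse = sep)
  rows <- vapply(seq_along(m$categories), function(i) {
    paste(quote_field(c(m$categories[i], chr[i, ])), collapse = sep)
  }, "")
  writeLines(c(header, rows), path, useBytes = FALSE)
  invisible(path)
}

#' Scale attribute columns of a value table
#'
#' Multiplies each named column by a strictly positive factor; unnamed
#' columns keep factor 1. Scaling affects geometry only: labels and the
#' centre detail are always formatted from the unscaled values, so a chart
#' scaled for legibility still annotates the true numbers.
#'
#' @param m a `data_matrix`.
#' @param factors named numeric vector or list, `attribute = factor`.
#' @return a new `data_matrix`; the input is untouched.
#' @examples
#' m <- covid_fixture()
#' s <- apply_scale_factors(m, c("Death Rate" = 5, "Infection Rate" = 1.2))
#' value_at(s, "Russia", "Death Rate")  # 13.95
#' @export
apply_scale_factors <- function(m, factors) {
  validate_data_matrix(m)
  factors <- unlist(factors)
  if (length(factors) == 0L) return(m)
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("apply_scale_factors: factors must be named by attribute",
         call. = FALSE)
  }
  unknown <- setdiff(names(factors), m$attributes)
  if (length(unknown) > 0L) {
    stop("apply_scale_factors: unknown attribute(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(factors) | factors <= 0)) {
    stop("apply_scale_factors: factors must be finite and > 0",
         call. = FALSE)
  }
  full <- stats::setNames(rep(1, length(m$attributes)), m$attributes)
  full[names(factors)] <- factors
  vals <- sweep(m$values, 2L, full, `*`)
  data_matrix(vals, m$categories, m$attributes, m$units)
}
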