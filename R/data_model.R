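#' Construct a mixed-mode sample table
#'
#' A `mixed_mode_table` holds a samples-by-attributes grid in which each
#' attribute (column) is either continuous (finite numeric) or categorical
#' (character drawn from a finite alphabet). An optional per-sample class
#' label can be carried alongside; it is excluded from every unsupervised
#' stage and only consulted when scoring classification rules post hoc.
#'
#' Missing values are rejected outright: every downstream statistic is a
#' plug-in estimate from complete contingency tables.
#'
#' @param values data.frame of attribute columns (numeric or character).
#' @param kinds character vector, one of `"continuous"`/`"categorical"` per
#'   column; inferred from column type when `NULL`.
#' @param class_labels optional character vector of per-sample labels.
#' @return An object of class `mixed_mode_table` with elements `values`,
#'   `attribute_names`, `attribute_kinds`, `class_labels`.
#' @export
mixed_mode_table <- function(values, kinds = NULL, class_labels = NULL) {
  if (!is.data.frame(values) || ncol(values) < 1L || nrow(values) < 1L)
    stop("values must be a non-empty data.frame")
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (anyNA(values))
    stop("missing values are not supported; remove or filter incomplete samples")
  if (is.null(kinds)) {
    kinds <- vapply(values, function(col) {
      if (is.numeric(col)) "continuous" else "categorical"
    }, character(1))
  }
  kinds <- match.arg(kinds, c("continuous", "categorical"), several.ok = TRUE)
  if (length(kinds) != ncol(values))
    stop("kinds must name one mode per column")
  for (j in seq_along(values)) {
    if (kinds[j] == "continuous") {
      col <- values[[j]]
      if (!is.numeric(col)) {
        col <- suppressWarnings(as.numeric(col))
        if (anyNA(col)) stop("column ", names(values)[j],
                             " declared continuous but is not numeric")
      }
      if (!all(is.finite(col)))
        stop("column ", names(values)[j], " contains non-finite values")
      values[[j]] <- col
    } else {
      values[[j]] <- as.character(values[[j]])
    }
  }
  if (!is.null(class_labels)) {
    class_labels <- as.character(class_labels)
    if (length(class_labels) != nrow(values))
      stop("class_labels must have one entry per sample")
  }
  structure(
    list(values = values,
         attribute_names = names(values),
         attribute_kinds = stats::setNames(kinds, names(values)),
         class_labels = class_labels),
    class = "mixed_mode_table")
}

#' @export
print.mixed_mode_table <- function(x, ...) {
  cat(sprintf("mixed_mode_table: %d samples x %d attributes (%d continuous, %d categorical)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$attribute_kinds == "continuous"),
              sum(x$attribute_kinds == "categorical"),
              if (is.null(x$class_labels)) "" else "; class labels attached"))
  invisible(x)
}

#' Number of samples in a mixed-mode table
#' @param table a `mixed_mode_table`.
#' @return integer sample count.
#' @export
n_samples <- function(table) nrow(table$values)

#' Number of attributes in a mixed-mode table
#' @param table a `mixed_mode_table`.
#' @return integer attribute count.
#' @export
n_attributes <- function(table) ncol(table$values)

#' Drop the class column from a table
#'
#' Convenience for asserting that unsupervised stages are label-free.
#' @param table a `mixed_mode_table`.
#' @return the same table with `class_labels = NULL`.
#' @export
strip_class <- function(table) {
  table$class_labels <- NULL
  table
}

#' Read a delimited mixed-mode table
#'
#' Reads a CSV or TSV file with a mandatory header row. Columns on which every
#' entry parses as a number are typed continuous; all others categorical.
#' `kind_hints` overrides the inference per named column. When `class_column`
#' is given, that column is removed from the attribute set and stored as the
#' table's class labels.
#'
#' @param path file path.
#' @param kind_hints optional named character vector
#'   (`"continuous"`/`"categorical"`) overriding type inference.
#' @param class_column optional name of the class-label column.
#' @param sep field separator; `NULL` auto-detects comma vs tab from the
#'   header line (anything else requires an explicit value).
#' @return a [mixed_mode_table()].
#' @export
read_table <- function(path, kind_hints = NULL, class_column = NULL, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) stop("empty file: ", path)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("table has no data rows: ", path)
  class_labels <- NULL
  if (!is.null(class_column)) {
    if (!class_column %in% names(raw))
      stop("class_column '", class_column, "' not found in header")
    class_labels <- raw[[class_column]]
    raw[[class_column]] <- NULL
  }
  kinds <- vapply(names(raw), function(nm) {
    if (!is.null(kind_hints) && nm %in% names(kind_hints))
      return(match.arg(kind_hints[[nm]], c("continuous", "categorical")))
    parsed <- suppressWarnings(as.numeric(raw[[nm]]))
    if (anyNA(parsed)) "categorical" else "continuous"
  }, character(1))
  for (nm in names(raw)) {
    if (kinds[[nm]] == "continuous") raw[[nm]] <- as.numeric(raw[[nm]])
  }
  mixed_mode_table(raw, kinds = unname(kinds), class_labels = class_labels)
}

#' Write a mixed-mode table as delimited text
#'
#' @param table a `mixed_mode_table`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @param class_column name under which to append the class column, when the
#'   table carries labels (default `"Class"`; `NULL` omits it).
#' @export
write_table <- function(table, path, sep = "\t", class_column = "Class") {
  out <- table$values
  if (!is.null(table$class_labels) && !is.null(class_column))
    out[[class_column]] <- table$class_labels
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an event table (interval labels) as TSV
#'
#' One column per attribute, one row per sample, entries are interval or
#' category labels. Round-trips losslessly through [read_events()].
#'
#' @param events data.frame of character labels.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path input path.
#' @return data.frame of character labels.
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
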