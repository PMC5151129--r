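#' Construct a two-class expression set
#'
#' The container used throughout the package: a samples-by-molecules matrix of
#' normalized expression (-dCp scale for qPCR data: higher = more abundant),
#' with NA marking undetected entries, plus a two-level class factor (first
#' level = controls, second = cases).
#'
#' @param values numeric matrix, samples in rows, molecules in columns; both
#'   dimnames required. NA entries are treated as undetected downstream.
#' @param class factor or character vector of length `nrow(values)` with
#'   exactly two levels; the first level is taken as the control class.
#' @return an object of class `"expression_set"`: a list with elements
#'   `values`, `class`, `samples`, `molecules`.
#' @export
expression_set <- function(values, class) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (samples x molecules)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have sample rownames and molecule colnames")
  }
  class <- as.factor(class)
  if (length(class) != nrow(values)) {
    stop("'class' must have one label per sample (row)")
  }
  class <- droplevels(class)
  if (nlevels(class) != 2) {
    stop("exactly two non-empty classes are required, got: ",
         paste(levels(class), collapse = ", "))
  }
  structure(list(values = values, class = class,
                 samples = rownames(values), molecules = colnames(values)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("expression_set: %d samples x %d molecules\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  classes: %s (n=%d, control) / %s (n=%d, case)\n",
              names(tab)[1], tab[1], names(tab)[2], tab[2]))
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  undetected entries: %d (%.1f%%)\n",
              nmiss, 100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Read / write an expression set as delimited text
#'
#' The layout is one row per sample: `sample_id`, `class`, then one column per
#' molecule holding normalized expression (empty / NA = undetected).
#'
#' @param x an [expression_set()].
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `read_expression()` returns an [expression_set()];
#'   `write_expression()` returns `path` invisibly.
#' @export
write_expression <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "expression_set"))
  df <- data.frame(sample_id = x$samples, class = as.character(x$class),
                   x$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)[1:2])) {
    stop("expression file must start with 'sample_id' and 'class' columns: ", path)
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- df$sample_id
  cls <- factor(df$class)
  if ("control" %in% levels(cls)) cls <- stats::relevel(cls, "control")
  expression_set(vals, cls)
}
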