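#' Construct a metabolite abundance matrix
#'
#' The central data container: a samples x metabolites numeric matrix with
#' optional per-sample group labels and a provenance trail recording the
#' transforms applied so far.
#'
#' @param values numeric matrix, samples in rows (unique rownames) and
#'   metabolites in columns (unique colnames, e.g. `CHEBI:` identifiers).
#' @param groups optional factor (or coercible) of per-sample group labels,
#'   either unnamed in row order or named by sample id.
#' @param provenance character vector of transform tags already applied
#'   (e.g. `"log2"`, `"standardize"`).
#' @return An object of class `MetaboliteMatrix`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("m", 1:4)))
#' mm <- metabolite_matrix(x, groups = c("A", "A", "B"))
#' @export
metabolite_matrix <- function(values, groups = NULL, provenance = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stopf("`values` must have metabolite identifiers as column names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate metabolite ids")
  if (!is.null(groups)) {
    if (!is.null(names(groups))) {
      missing <- setdiff(rownames(values), names(groups))
      if (length(missing))
        stopf("group labels missing for samples: %s",
              paste(head(missing, 5), collapse = ", "))
      groups <- groups[rownames(values)]
    }
    if (length(groups) != nrow(values))
      stopf("`groups` must cover all %d samples", nrow(values))
    groups <- as.factor(unname(groups))
  }
  structure(list(values = values, groups = groups,
                 provenance = as.character(provenance)),
            class = "MetaboliteMatrix")
}

#' Coerce to MetaboliteMatrix
#' @param x a `MetaboliteMatrix` or a numeric matrix with dimnames.
#' @param groups optional group labels (ignored if `x` already carries them).
#' @export
as_metabolite_matrix <- function(x, groups = NULL) {
  if (inherits(x, "MetaboliteMatrix")) return(x)
  metabolite_matrix(x, groups = groups)
}

#' @rdname metabolite_matrix
#' @param x a `MetaboliteMatrix`.
#' @export
abundances <- function(x) as_metabolite_matrix(x)$values

#' @rdname metabolite_matrix
#' @export
sample_ids <- function(x) rownames(abundances(x))

#' @rdname metabolite_matrix
#' @export
metabolite_ids <- function(x) colnames(abundances(x))

#' @rdname metabolite_matrix
#' @export
group_labels <- function(x) as_metabolite_matrix(x)$groups

#' @export
print.MetaboliteMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("MetaboliteMatrix: %d samples x %d metabolites\n", nrow(v), ncol(v)))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s (%d)", levels(x$groups),
                                 tabulate(x$groups)), collapse = ", "), "\n")
  if (length(x$provenance))
    cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  if (anyNA(v)) cat(sprintf("missing values: %d\n", sum(is.na(v))))
  invisible(x)
}

#' Read a metabolite matrix from a delimited file
#'
#' Expects the first column to hold sample ids and the header row metabolite
#' ids. Empty cells or `NA` are read as missing values. An optional two-column
#' labels file (sample id, group) supplies group labels.
#'
#' @param path path to the matrix file.
#' @param labels_path optional path to a sample id / group file.
#' @param sep field separator, tab by default.
#' @return A [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(path, labels_path = NULL, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(df) < 2L) stopf("matrix file needs a sample-id column plus data")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  groups <- NULL
  if (!is.null(labels_path)) {
    lab <- read.delim(labels_path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE)
    groups <- setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  }
  metabolite_matrix(m, groups = groups)
}

#' Write a metabolite matrix (and optionally its labels) to delimited files
#' @param x a `MetaboliteMatrix`.
#' @inheritParams read_metabolite_matrix
#' @export
write_metabolite_matrix <- function(x, path, labels_path = NULL, sep = "\t") {
  x <- as_metabolite_matrix(x)
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(x$groups)) stopf("matrix has no group labels to write")
    write.table(data.frame(sample_id = rownames(x$values),
                           group = as.character(x$groups)),
                labels_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# append a provenance tag
add_provenance <- function(x, tag) {
  x$provenance <- c(x$provenance, tag)
  x
}

has_provenance <- function(x, tag) {
  any(grepl(tag, x$provenance, fixed = TRUE))
}
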