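#' Construct a count matrix
#'
#' A thin S3 container around a numeric features-by-samples matrix carrying
#' the kind of feature in each row (`gene`, `te_copy` or `te_subfamily`)
#' and whether the values are raw integer counts or normalized reals.
#'
#' @param counts numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids); all values must be non-negative and,
#'   for raw matrices, integer-valued.
#' @param feature_kind either a single kind applying to every row, or a
#'   character vector with one kind per row (used for stacked gene + TE
#'   matrices). Allowed kinds: `"gene"`, `"te_copy"`, `"te_subfamily"`.
#' @param normalized logical; `FALSE` for raw integer counts.
#' @return a `count_matrix` object (a numeric matrix with attributes
#'   `feature_kind` and `normalized`).
#' @export
count_matrix <- function(counts, feature_kind, normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("'counts' must have feature ids as rownames")
  if (is.null(colnames(counts)))
    stop("'counts' must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (!normalized && any(counts != round(counts)))
    stop("raw count matrix must be integer-valued")
  kinds <- c("gene", "te_copy", "te_subfamily")
  if (!length(feature_kind) %in% c(1L, nrow(counts)))
    stop("'feature_kind' must have length 1 or nrow(counts)")
  if (!all(feature_kind %in% kinds))
    stop("feature_kind must be one of: ", paste(kinds, collapse = ", "))
  if (length(feature_kind) > 1L && length(unique(feature_kind)) == 1L)
    feature_kind <- feature_kind[1L]
  structure(counts,
            feature_kind = feature_kind,
            normalized = isTRUE(normalized),
            class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  kind <- feature_kind(x)
  cat(sprintf("count_matrix: %d features x %d samples (%s, %s)\n",
              nrow(x), ncol(x),
              if (length(unique(kind)) == 1L) unique(kind) else "mixed kinds",
              if (is_normalized(x)) "normalized" else "raw"))
  if (nrow(x) > 0 && ncol(x) > 0)
    print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Per-row feature kinds of a count matrix
#'
#' @param x a `count_matrix`.
#' @return character vector of length `nrow(x)`.
#' @export
feature_kind <- function(x) {
  k <- attr(x, "feature_kind")
  if (length(k) == 1L) rep(k, nrow(x)) else k
}

#' Is a count matrix normalized?
#'
#' @param x a `count_matrix`.
#' @return logical scalar.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# Subset rows/columns while keeping per-row kind in step.
#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- feature_kind(x)
  m <- unclass(x)[i, j, drop = FALSE]
  if (missing(i)) ki <- kind else ki <- kind[i]
  count_matrix(m, feature_kind = ki, normalized = is_normalized(x))
}

#' Read a TSV count matrix
#'
#' Expects a tab-delimited file whose header row holds sample ids and whose
#' first column holds feature ids. Raw matrices must be non-negative
#' integers; any negative or non-numeric cell is an error.
#'
#' @param path file path.
#' @param feature_kind kind label for every row (`gene`, `te_copy`,
#'   `te_subfamily`).
#' @param normalized logical; set `TRUE` when reading back normalized values.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, feature_kind, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 1L) stop("count matrix file has no columns: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (nrow(m) > 0 && any(!is.finite(m)))
    stop("non-numeric or missing cell in count matrix: ", path)
  if (nrow(m) > 0 && any(m < 0))
    stop("negative cell in count matrix: ", path)
  rownames(m) <- ids
  count_matrix(m, feature_kind = feature_kind, normalized = normalized)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: `read_count_matrix(write_count_matrix(m))`
#' reproduces `m` exactly. Integer-valued cells are written without a
#' decimal point.
#'
#' @param x a `count_matrix`.
#' @param path output file path.
#' @param id_column header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, id_column = "feature_id") {
  m <- unclass(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
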