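# Subfamily-level quantification: regroup per-copy counts through the
# rosetta map and drop the non-TE repeat subfamilies.

#' Default repeat-subfamily exclusion list
#'
#' The 24 snRNA, snpRNA, scRNA, satellite and rRNA repeat subfamilies that
#' are removed so that only true TE subfamilies remain (applied to a
#' 1,270-subfamily repeat library this leaves the 1,246 TE subfamilies).
#' Names are matched as opaque strings ("ALR/Alpha" contains a slash);
#' "5S" is treated as a single trailing name.
#'
#' @return character vector of 24 subfamily names.
#' @export
default_te_exclusions <- function() {
  c("7SLRNA", "7SK", "LSAU", "D20S16", "REP522", "SATR1", "SATR2",
    "ACRO1", "ALR/Alpha", "BSR/Beta", "CER", "6kbHsap", "TAR1", "SST1",
    "MSR1", "SAR", "GA-rich", "G-rich", "A-rich", "HY1", "HY3", "HY4",
    "HY5", "5S")
}

#' Aggregate per-copy counts into per-subfamily counts
#'
#' Regroups a TE-copy count matrix into subfamily counts by summing the
#' member copies of each subfamily within every sample, using a rosetta
#' copy-to-subfamily map. Total counts per sample are conserved exactly.
#'
#' @param copy_counts a `count_matrix` of kind `te_copy`.
#' @param rosetta data.frame from [read_rosetta()] (or any data.frame with
#'   `copy_id` and `subfamily` columns).
#' @return a `count_matrix` of kind `te_subfamily`; only subfamilies with
#'   at least one mapped copy in the input appear.
#' @export
aggregate_copy_counts <- function(copy_counts, rosetta) {
  stopifnot(inherits(copy_counts, "count_matrix"))
  if (!all(feature_kind(copy_counts) == "te_copy"))
    stop("'copy_counts' must be a te_copy matrix")
  idx <- match(rownames(copy_counts), rosetta$copy_id)
  if (anyNA(idx)) {
    miss <- rownames(copy_counts)[is.na(idx)]
    stop("copy ids absent from rosetta map: ",
         paste(head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L))
  }
  subfam <- rosetta$subfamily[idx]
  m <- rowsum(unclass(copy_counts), group = subfam, reorder = TRUE)
  count_matrix(m, feature_kind = "te_subfamily",
               normalized = is_normalized(copy_counts))
}

#' Remove excluded repeat subfamilies
#'
#' Drops rows whose subfamily name appears in the exclusion list; all other
#' rows are untouched. Excluding a name that is not present is a no-op
#' (reported via a message).
#'
#' @param subfamily_counts a `count_matrix` of kind `te_subfamily`.
#' @param exclude character vector of subfamily names; defaults to
#'   [default_te_exclusions()].
#' @return the filtered `count_matrix`.
#' @export
filter_subfamilies <- function(subfamily_counts,
                               exclude = default_te_exclusions()) {
  stopifnot(inherits(subfamily_counts, "count_matrix"))
  exclude <- unique(exclude)
  absent <- setdiff(exclude, rownames(subfamily_counts))
  if (length(absent))
    message(length(absent), " excluded subfamilies not present in matrix")
  keep <- !(rownames(subfamily_counts) %in% exclude)
  subfamily_counts[keep, , drop = FALSE]
}

#' Drop features with zero counts in every sample
#'
#' @param x a `count_matrix`.
#' @return `x` restricted to features with at least one positive count.
#' @export
drop_all_zero_features <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  x[rowSums(unclass(x)) > 0, , drop = FALSE]
}
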