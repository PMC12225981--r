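# Gene-anchored normalization. Size factors are computed from gene counts
# only (median-of-ratios against a geometric-mean pseudo-reference) and
# then applied to genes and TE subfamilies alike, so that a genuinely
# elevated TE load in one sample is not normalized away.

#' Median-of-ratios size factors from gene counts
#'
#' For each gene with positive counts in every sample, computes the ratio
#' of each sample's count to the gene's geometric mean across samples; a
#' sample's size factor is the median of its ratios. Only gene rows enter
#' the estimator, which is what anchors the normalization on genes.
#'
#' @param gene_counts a raw `count_matrix` of kind `gene`.
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors_from_genes <- function(gene_counts) {
  stopifnot(inherits(gene_counts, "count_matrix"))
  if (!all(feature_kind(gene_counts) == "gene"))
    stop("size factors must be computed from a gene count matrix")
  m <- unclass(gene_counts)
  if (ncol(m) < 1L) stop("no samples in gene count matrix")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("no gene has positive counts in every sample; ",
         "cannot build the median-of-ratios reference")
  ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
  ratios <- m[all_pos, , drop = FALSE] / ref
  sf <- apply(ratios, 2L, median)
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor computed")
  sf
}

#' Normalize genes and TE subfamilies with shared gene-derived factors
#'
#' Stacks the gene and TE-subfamily matrices and divides every column by
#' its sample's size factor. TE rows are rescaled by the gene-derived
#' factors even when TE totals differ strongly between samples.
#'
#' @param gene_counts raw `count_matrix` of kind `gene`.
#' @param te_counts raw `count_matrix` of kind `te_subfamily`.
#' @param factors named size-factor vector from [size_factors_from_genes()].
#' @return a normalized stacked `count_matrix` with per-row feature kinds.
#' @export
normalize_joint <- function(gene_counts, te_counts, factors) {
  stopifnot(inherits(gene_counts, "count_matrix"),
            inherits(te_counts, "count_matrix"))
  samples <- colnames(gene_counts)
  if (!identical(sort(samples), sort(colnames(te_counts))))
    stop("gene and TE matrices cover different sample sets")
  if (!identical(sort(samples), sort(names(factors))))
    stop("size factors cover a different sample set than the count matrices")
  te <- unclass(te_counts)[, samples, drop = FALSE]
  stacked <- rbind(unclass(gene_counts), te)
  if (anyDuplicated(rownames(stacked)))
    stop("feature id present in both gene and TE matrices: ",
         rownames(stacked)[duplicated(rownames(stacked))][1L])
  norm <- sweep(stacked, 2L, factors[samples], "/")
  count_matrix(norm,
               feature_kind = c(rep("gene", nrow(gene_counts)),
                                rep("te_subfamily", nrow(te_counts))),
               normalized = TRUE)
}

#' Remove an additive (log-scale) batch effect for display statistics
#'
#' Fits, per feature, a least-squares model of `log2(count + 0.5)` on the
#' biological group plus batch, subtracts the estimated batch offsets, and
#' back-transforms. Intended for descriptive statistics and plots only;
#' inferential models should include batch as a covariate instead.
#'
#' @param normalized a normalized `count_matrix`.
#' @param sheet sample sheet with a `batch` column (and the grouping
#'   column).
#' @param group name of the biological grouping column retained as a
#'   covariate while the batch offsets are estimated (default
#'   `"karyotype"`).
#' @return a `count_matrix` of batch-adjusted normalized values (clamped at
#'   zero). Single-batch input is returned unchanged.
#' @export
remove_batch_effect <- function(normalized, sheet, group = "karyotype") {
  stopifnot(inherits(normalized, "count_matrix"))
  if (!is_normalized(normalized))
    stop("batch adjustment expects a normalized matrix")
  if (!"batch" %in% names(sheet)) stop("sample sheet has no 'batch' column")
  sheet <- sheet[match(colnames(normalized), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all matrix samples")
  batch <- factor(sheet$batch)
  if (nlevels(batch) < 2L) return(normalized)
  if (any(table(batch) == 0L)) stop("empty batch level")
  grp <- if (group %in% names(sheet)) factor(sheet[[group]]) else
    factor(rep("all", ncol(normalized)))
  X_bio <- model.matrix(~grp)
  X_batch <- model.matrix(~batch)[, -1L, drop = FALSE]
  X <- cbind(X_bio, X_batch)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with the biological group; ",
         "offsets are not estimable")
  y <- log2(unclass(normalized) + 0.5)
  # one QR solve shared across all features
  beta <- t(qr.coef(qr(X), t(y)))
  k <- ncol(X_bio)
  adj <- y - beta[, (k + 1L):ncol(X), drop = FALSE] %*% t(X_batch)
  out <- pmax(2^adj - 0.5, 0)
  count_matrix(out, feature_kind = feature_kind(normalized),
               normalized = TRUE)
}

#' Write size factors as a two-column TSV
#'
#' @param factors named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(factors, path) {
  write.table(data.frame(sample_id = names(factors),
                         size_factor = unname(factors)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
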