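# Negative-binomial differential expression for genes and TE subfamilies.
# Per feature: NB GLM with log link and log size-factor offset, per-feature
# ML dispersion, Wald z-tests on pairwise contrasts of the primary factor
# and a likelihood-ratio test of the primary factor as a whole. This is a
# deliberately simple estimator (no dispersion shrinkage, no outlier
# refitting); its operating characteristics are established by simulation.

#' Describe a differential-expression design
#'
#' @param primary name of the primary factor column in the sample sheet
#'   (e.g., `"karyotype"` or `"sex"`).
#' @param covariates character vector of additional model terms (column
#'   names, or interaction terms like `"sex:age_group"`).
#' @param reference reference level of the primary factor; defaults to
#'   `"XX"` for karyotype designs, otherwise the first level.
#' @return a `design_spec` list.
#' @export
design_spec <- function(primary = "karyotype", covariates = "batch",
                        reference = NULL) {
  if (is.null(reference) && primary == "karyotype") reference <- "XX"
  structure(list(primary = primary, covariates = covariates,
                 reference = reference),
            class = "design_spec")
}

de_model_frame <- function(sheet, design) {
  vars <- unique(c(design$primary,
                   unlist(strsplit(design$covariates, "[:*]"))))
  vars <- vars[nzchar(vars)]
  miss <- setdiff(vars, names(sheet))
  if (length(miss))
    stop("design variables absent from sample sheet: ",
         paste(miss, collapse = ", "))
  mf <- sheet[vars]
  mf[] <- lapply(mf, factor)
  if (!is.null(design$reference)) {
    if (!design$reference %in% levels(mf[[design$primary]]))
      stop("reference level '", design$reference,
           "' absent from ", design$primary)
    mf[[design$primary]] <- relevel(mf[[design$primary]], design$reference)
  }
  sizes <- table(mf[[design$primary]])
  if (any(sizes < 2L))
    stop("primary factor level with fewer than 2 samples: ",
         names(sizes)[sizes < 2L][1L])
  mf
}

# Cox-Reid adjusted profile log-likelihood of the dispersion: the NB
# log-likelihood at the fitted means minus 0.5 * log det(X'WX). The
# adjustment compensates for the coefficients being estimated, which
# otherwise biases per-feature ML dispersions low at small n and inflates
# the Wald test.
nb_cr_dispersion <- function(y, X, off, alpha_floor = 1e-8,
                             alpha_max = 20) {
  apl <- function(log_alpha) {
    alpha <- exp(log_alpha)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y, family = MASS::negative.binomial(theta = 1 / alpha),
        offset = off)),
      error = function(e) NULL)
    if (is.null(fit)) return(-Inf)
    ll <- sum(stats::dnbinom(y, mu = fit$fitted.values, size = 1 / alpha,
                             log = TRUE))
    cr <- determinant(crossprod(sqrt(fit$weights) * X),
                      logarithm = TRUE)$modulus
    ll - 0.5 * as.numeric(cr)
  }
  opt <- tryCatch(stats::optimize(apl, c(log(alpha_floor), log(alpha_max)),
                                  maximum = TRUE),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) return(alpha_floor)
  max(exp(opt$maximum), alpha_floor)
}

nb_fit_feature <- function(y, X_full, X_red, off) {
  alpha <- nb_cr_dispersion(y, X_full, off)
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit_full <- tryCatch(
    suppressWarnings(stats::glm.fit(X_full, y, family = fam, offset = off)),
    error = function(e) NULL)
  fit_red <- tryCatch(
    suppressWarnings(stats::glm.fit(X_red, y, family = fam, offset = off)),
    error = function(e) NULL)
  if (is.null(fit_full) || is.null(fit_red) || !fit_full$converged)
    return(NULL)
  XtWX <- crossprod(sqrt(fit_full$weights) * X_full)
  vcov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(vcov)) return(NULL)
  list(beta = fit_full$coefficients, vcov = vcov, dispersion = alpha,
       df_resid = fit_full$df.residual,
       lr_stat = fit_red$deviance - fit_full$deviance,
       lr_df = fit_red$df.residual - fit_full$df.residual)
}

#' Negative-binomial differential expression
#'
#' Fits, per feature, an NB GLM with log link on the raw counts with
#' `log(size factor)` as offset. The dispersion is estimated per feature
#' by maximizing the Cox-Reid adjusted profile likelihood under the full
#' model (floored at 1e-8, so the fit degrades gracefully to Poisson);
#' the adjustment removes the small-sample downward bias of the plain ML
#' dispersion. Every unordered pair of primary-factor levels yields a
#' Wald test on the contrast (log2 fold-change of predicted normalized
#' means) referred to a t distribution with the residual degrees of
#' freedom, and the primary factor as a whole is tested with a
#' likelihood-ratio chi-square test against the design without it.
#' P-values are BH-adjusted within each test family (per contrast for
#' Wald, one family for LR).
#'
#' Features whose total count across samples is below `min_total` are not
#' tested. A feature whose fit does not converge is reported with `NA`
#' p-values rather than aborting the run.
#'
#' @param raw_counts raw `count_matrix` (genes or TE subfamilies).
#' @param factors named size-factor vector, see
#'   [size_factors_from_genes()].
#' @param sheet sample sheet covering all samples.
#' @param design a [design_spec()].
#' @param min_total low-count filter: minimal total raw count across
#'   samples for a feature to be tested.
#' @return data.frame with columns `feature_id`, `contrast`, `log2fc`,
#'   `p`, `padj`, `test` (`"wald"` or `"lr"`; LR rows have contrast
#'   `"omnibus"` and no log2fc).
#' @export
fit_nb_de <- function(raw_counts, factors, sheet,
                      design = design_spec(), min_total = 10) {
  stopifnot(inherits(raw_counts, "count_matrix"))
  if (is_normalized(raw_counts))
    stop("the NB model is fit on raw counts (normalization enters as an offset)")
  m <- unclass(raw_counts)
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all matrix samples")
  if (!all(colnames(m) %in% names(factors)))
    stop("size factors missing for some samples")
  off <- log(factors[colnames(m)])
  mf <- de_model_frame(sheet, design)
  rhs_full <- paste(c(design$primary, design$covariates[nzchar(design$covariates)]),
                    collapse = " + ")
  rhs_red <- if (any(nzchar(design$covariates)))
    paste(design$covariates[nzchar(design$covariates)], collapse = " + ")
  else "1"
  X_full <- model.matrix(stats::as.formula(paste("~", rhs_full)), mf)
  X_red <- model.matrix(stats::as.formula(paste("~", rhs_red)), mf)
  if (qr(X_full)$rank < ncol(X_full))
    stop("rank-deficient design matrix (confounded factors?)")

  lev <- levels(mf[[design$primary]])
  pairs <- combn(lev, 2L)
  # contrast of level b vs level a in treatment coding with lev[1] reference
  coef_names <- colnames(X_full)
  lvl_coef <- function(l) {
    if (l == lev[1L]) return(numeric(length(coef_names)))
    as.numeric(coef_names == paste0(design$primary, l))
  }

  keep <- rowSums(m) >= min_total
  if (!all(keep))
    message(sum(!keep), " features below the low-count filter (total < ",
            min_total, ") not tested")
  feats <- rownames(m)[keep]

  wald <- vector("list", length(feats))
  lr <- vector("list", length(feats))
  n_fail <- 0L
  for (i in seq_along(feats)) {
    y <- m[feats[i], ]
    fit <- nb_fit_feature(y, X_full, X_red, off)
    if (is.null(fit)) {
      n_fail <- n_fail + 1L
      est <- rep(NA_real_, ncol(pairs)); pw <- est
      plr <- NA_real_
    } else {
      res <- apply(pairs, 2L, function(pr) {
        cvec <- lvl_coef(pr[2L]) - lvl_coef(pr[1L])
        est <- sum(cvec * fit$beta)
        se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
        # t reference with the residual df: together with the Cox-Reid
        # dispersion this keeps the test calibrated at small n
        c(est / log(2), 2 * stats::pt(-abs(est / se), df = fit$df_resid))
      })
      est <- res[1L, ]; pw <- res[2L, ]
      plr <- pchisq(max(fit$lr_stat, 0), df = fit$lr_df, lower.tail = FALSE)
    }
    wald[[i]] <- data.frame(
      feature_id = feats[i],
      contrast = paste(pairs[2L, ], "vs", pairs[1L, ]),
      log2fc = est, p = pw, test = "wald", stringsAsFactors = FALSE)
    lr[[i]] <- data.frame(
      feature_id = feats[i], contrast = "omnibus", log2fc = NA_real_,
      p = plr, test = "lr", stringsAsFactors = FALSE)
  }
  if (n_fail > 0L)
    message(n_fail, " features did not converge; reported with NA p-values")
  out <- rbind(do.call(rbind, wald), do.call(rbind, lr))
  if (is.null(out))
    return(data.frame(feature_id = character(), contrast = character(),
                      log2fc = numeric(), p = numeric(), padj = numeric(),
                      test = character(), stringsAsFactors = FALSE))
  out$padj <- NA_real_
  for (fam in unique(paste(out$test, out$contrast))) {
    sel <- paste(out$test, out$contrast) == fam
    out$padj[sel] <- bh_adjust(out$p[sel])
  }
  rownames(out) <- NULL
  out[c("feature_id", "contrast", "log2fc", "p", "padj", "test")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; monotone, capped at 1, order preserved, `NA`s
#' passed through (and not counted in the family size).
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted vector of the same length.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Test the median log2 fold-change of one contrast against zero
#'
#' Two-sided Wilcoxon signed-rank test of the log2 fold-change vector of a
#' contrast against 0 (zeros dropped, standard convention). A significant
#' result indicates an overall shift of TE-subfamily expression between
#' the two groups even when few individual subfamilies pass FDR.
#'
#' @param log2fc numeric vector of finite log2 fold-changes for a single
#'   contrast (at least 5 values).
#' @return list with `median` and `p`.
#' @export
median_log2fc_test <- function(log2fc) {
  log2fc <- log2fc[is.finite(log2fc)]
  if (length(log2fc) < 5L)
    stop("need at least 5 finite log2 fold-changes")
  wt <- suppressWarnings(wilcox.test(log2fc, mu = 0,
                                     alternative = "two.sided"))
  list(median = median(log2fc), p = wt$p.value)
}

#' Top-ranked features of a DE result
#'
#' Orders one test family by ascending adjusted p-value, breaking ties by
#' raw p-value and then feature id (deterministic).
#'
#' @param results data.frame from [fit_nb_de()].
#' @param k number of features to return (capped at the result size).
#' @param test which test family to rank (default `"lr"`).
#' @return data.frame of the `k` top rows.
#' @export
rank_top_features <- function(results, k, test = "lr") {
  sel <- results[results$test == test, , drop = FALSE]
  if (!nrow(sel)) stop("no results for test '", test, "'")
  ord <- order(sel$padj, sel$p, sel$feature_id, na.last = TRUE)
  sel[ord[seq_len(min(k, nrow(sel)))], , drop = FALSE]
}
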