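# The headline statistic: per-sample proportion of normalized TE counts
# among all normalized counts (genes + TE subfamilies), overall or within a
# TE class/group, plus the rank-based group comparisons.

#' Default name-prefix rules for named TE groups
#'
#' Membership of the transcriptionally active named groups (HERVK, AluS,
#' L1, AluY, SVA) is resolved from the subfamily name when lineage columns
#' are not specific enough. The rule table is plain data and can be edited
#' or extended by the caller.
#'
#' @return data.frame with columns `group` and `pattern` (regular
#'   expression applied to subfamily names).
#' @export
default_group_rules <- function() {
  data.frame(group = c("HERVK", "AluS", "L1", "AluY", "SVA"),
             pattern = c("^HERVK", "^AluS", "^L1", "^AluY", "^SVA"),
             stringsAsFactors = FALSE)
}

#' Build TE subsets from lineage labels and name rules
#'
#' Produces the membership lists used by [global_te_proportion()]: one
#' subset per lineage class found in the rosetta table (LTR, SINE, LINE,
#' SVA, DNA, ...), one per named group from the rule table, and the `ALL`
#' subset of every TE subfamily.
#'
#' @param lineage data.frame with columns `subfamily` and `class`
#'   (typically unique rows of a rosetta table).
#' @param rules name-prefix rule table, see [default_group_rules()].
#' @return named list of character vectors of subfamily names.
#' @export
build_te_subsets <- function(lineage, rules = default_group_rules()) {
  lineage <- unique(lineage[, c("subfamily", "class")])
  subsets <- list(ALL = unique(lineage$subfamily))
  for (cl in sort(unique(lineage$class)))
    subsets[[cl]] <- lineage$subfamily[lineage$class == cl]
  for (i in seq_len(nrow(rules))) {
    hit <- unique(lineage$subfamily[grepl(rules$pattern[i], lineage$subfamily)])
    if (length(hit)) subsets[[rules$group[i]]] <- hit
  }
  subsets
}

#' Per-sample global TE-expression proportion
#'
#' Sums the normalized counts of the TE subfamilies in `subset` for each
#' sample and divides by the sample's total normalized counts over genes
#' plus all TE subfamilies. The denominator always includes every gene and
#' every TE subfamily, also when `subset` is a strict subset.
#'
#' @param normalized a normalized stacked `count_matrix` containing both
#'   `gene` and `te_subfamily` rows (from [normalize_joint()]).
#' @param subset character vector of subfamily names, or `NULL` for all TE
#'   subfamilies.
#' @return named numeric vector in `[0, 1]`, one value per sample.
#' @export
global_te_proportion <- function(normalized, subset = NULL) {
  stopifnot(inherits(normalized, "count_matrix"))
  if (!is_normalized(normalized))
    stop("global TE proportion is defined on normalized counts")
  kind <- feature_kind(normalized)
  if (!any(kind == "gene") || !any(kind == "te_subfamily"))
    stop("matrix must contain both gene and te_subfamily rows")
  m <- unclass(normalized)
  te_rows <- rownames(m)[kind == "te_subfamily"]
  members <- if (is.null(subset)) te_rows else intersect(subset, te_rows)
  total <- colSums(m)
  if (any(total == 0))
    stop("sample with zero total normalized count: ",
         colnames(m)[total == 0][1L])
  num <- if (length(members)) colSums(m[members, , drop = FALSE]) else
    setNames(numeric(ncol(m)), colnames(m))
  num / total
}

#' Pairwise rank-sum comparison of a per-sample statistic between groups
#'
#' Runs a two-sided Wilcoxon rank-sum test for every unordered pair of
#' groups. The exact distribution is used when both groups have at most
#' `exact_max` samples and no ties straddle the pair; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' P-values are reported raw (no multiplicity correction), which can be
#' changed via `p_adjust`.
#'
#' @param values numeric vector of per-sample statistics.
#' @param groups group label per sample (coerced to factor).
#' @param exact_max largest per-group size for the exact branch.
#' @param p_adjust method passed to [stats::p.adjust()]; default `"none"`.
#' @return data.frame with columns `group_a`, `group_b`, `statistic`, `p`,
#'   `method`.
#' @export
pairwise_group_test <- function(values, groups, exact_max = 8L,
                                p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group with fewer than 2 samples: ",
         names(sizes)[sizes < 2L][1L])
  pairs <- combn(levels(groups), 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    ties <- any(duplicated(c(x, y)))
    exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    c(statistic = unname(wt$statistic), p = wt$p.value,
      method = if (exact) "exact" else "normal-approx")
  })
  out <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                    statistic = as.numeric(res["statistic", ]),
                    p = as.numeric(res["p", ]),
                    method = unname(res["method", ]),
                    stringsAsFactors = FALSE)
  out$p <- p.adjust(out$p, method = p_adjust)
  out
}

#' Omnibus multi-group test (Kruskal-Wallis)
#'
#' Kruskal-Wallis rank test with tie correction across all groups. If every
#' value is identical the test statistic is degenerate and p = 1 is
#' returned with a message.
#'
#' @param values numeric vector.
#' @param groups group label per sample.
#' @return the p-value.
#' @export
multi_group_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(unique(values)) == 1L) {
    message("all values identical; omnibus test degenerate, p = 1")
    return(1)
  }
  kruskal.test(values, groups)$p.value
}

#' Sex effect on a per-sample statistic, adjusted on age group
#'
#' Fits a least-squares linear model `value ~ sex + age_group` and returns
#' the two-sided t-test p-value on the sex coefficient. When the age group
#' is constant the model collapses to a two-sample t-test on sex.
#'
#' @param values numeric vector of per-sample statistics.
#' @param sheet sample sheet with `sex` and `age_group` columns aligned to
#'   `values` (same order).
#' @return list with `p`, `estimate` (sex coefficient: male minus female)
#'   and the fitted `model`.
#' @export
adjusted_sex_effect_test <- function(values, sheet) {
  if (!all(c("sex", "age_group") %in% names(sheet)))
    stop("sample sheet needs 'sex' and 'age_group' columns")
  sex <- factor(sheet$sex, levels = c("female", "male"))
  if (nlevels(droplevels(sex)) < 2L) stop("both sexes must be present")
  age <- factor(sheet$age_group)
  df <- data.frame(value = values, sex = sex, age_group = age)
  fit <- if (nlevels(droplevels(age)) >= 2L) lm(value ~ sex + age_group, df)
         else lm(value ~ sex, df)
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit)))
    stop("rank-deficient design (sex confounded with age group?)")
  sm <- summary(fit)$coefficients
  list(p = sm["sexmale", "Pr(>|t|)"],
       estimate = sm["sexmale", "Estimate"],
       model = fit)
}

#' Flag males suspected of sex-chromosome aneuploidy
#'
#' Curation rule for cohorts of nominally normal karyotype: a male sample
#' is flagged when its X-inactivation marker (e.g., XIST) is expressed at a
#' level comparable to females (above `x_fraction` of the female median)
#' while the Y marker (e.g., USP9Y) is also expressed, a pattern consistent
#' with an XXY-like complement. Female samples are never flagged by this
#' rule.
#'
#' @param gene_counts normalized `count_matrix` containing both markers.
#' @param sheet sample sheet with a `sex` column, covering all samples.
#' @param marker_x X-inactivation marker gene id.
#' @param marker_y Y-linked marker gene id.
#' @param x_fraction fraction of the female median expression of
#'   `marker_x` above which a male is considered X-marker positive.
#' @param y_min minimal `marker_y` count for Y-marker positivity.
#' @return named logical vector, one flag per sample.
#' @export
flag_aneuploidy_suspects <- function(gene_counts, sheet,
                                     marker_x = "XIST",
                                     marker_y = "USP9Y",
                                     x_fraction = 0.5, y_min = 1) {
  stopifnot(inherits(gene_counts, "count_matrix"))
  m <- unclass(gene_counts)
  for (mk in c(marker_x, marker_y))
    if (!mk %in% rownames(m)) stop("marker gene absent from matrix: ", mk)
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (!"sex" %in% names(sheet)) stop("sample sheet needs a 'sex' column")
  female <- sheet$sex == "female"
  if (!any(female))
    stop("no female samples to anchor the X-marker threshold")
  thr <- x_fraction * median(m[marker_x, female])
  flag <- !female & m[marker_x, ] > thr & m[marker_y, ] >= y_min
  setNames(as.logical(flag), colnames(m))
}
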