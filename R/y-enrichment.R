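# Chromosome-enrichment classification of TE subfamilies: an exact
# two-sided binomial test of each subfamily's share of copies on a focal
# chromosome (Y by default) against the chromosome's length share of the
# genome, followed by BH correction and a six-group partition.

#' Default human chromosome lengths (kb)
#'
#' Lengths used to compute the expected copy share of the sex chromosomes:
#' Y = 57,200 kb and X = 156,040 kb out of a 3,088,200 kb genome, so the
#' expected Y share is 57200/3088200 (printed as 1.85%).
#'
#' @return list with `lengths` (named numeric, kb) and `total` (kb).
#' @export
default_chrom_lengths <- function() {
  list(lengths = c(Y = 57200, X = 156040), total = 3088200)
}

#' Expected copy proportion of a focal chromosome
#'
#' Length of the focal chromosome divided by the summed length of all
#' chromosomes; the null proportion of the enrichment test.
#'
#' @param lengths list as returned by [default_chrom_lengths()].
#' @param focal chromosome name.
#' @return proportion in `(0, 1]`.
#' @export
expected_proportion <- function(lengths = default_chrom_lengths(),
                                focal = "Y") {
  if (!focal %in% names(lengths$lengths))
    stop("no length recorded for chromosome ", focal)
  len <- lengths$lengths[[focal]]
  if (len <= 0 || lengths$total <= 0 || len > lengths$total)
    stop("invalid chromosome lengths")
  len / lengths$total
}

# Two-sided exact binomial p by the minimum-likelihood rule: sum the
# probabilities of all outcomes no more likely than the observed one.
# binom.test implements exactly this (with a 1e-7 relative guard against
# floating-point ties); the doubled-one-sided alternative is available via
# `method = "doubling"`.
binom_two_sided <- function(k, n, p, method = c("minlike", "doubling")) {
  method <- match.arg(method)
  if (method == "minlike")
    return(binom.test(k, n, p, alternative = "two.sided")$p.value)
  lo <- stats::pbinom(k, n, p)
  hi <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Exact binomial chromosome-enrichment test for one subfamily
#'
#' Tests whether the observed proportion of a subfamily's copies on the
#' focal chromosome equals the length-based expectation, with a two-sided
#' exact binomial test (minimum-likelihood two-sidedness by default).
#'
#' @param copies repeat-copy data.frame with `chrom` and `subfamily`
#'   columns.
#' @param subfamily subfamily name (must have at least one copy).
#' @param expected null proportion, see [expected_proportion()].
#' @param focal focal chromosome name.
#' @param method two-sided rule: `"minlike"` (default) or `"doubling"`.
#' @return one-row data.frame: `subfamily`, `n_total`, `n_focal`,
#'   `expected_prop`, `observed_prop`, `p`.
#' @export
binomial_focal_test <- function(copies, subfamily,
                                expected = expected_proportion(),
                                focal = "Y", method = "minlike") {
  sub <- copies[copies$subfamily == subfamily, , drop = FALSE]
  if (!nrow(sub)) stop("subfamily has no copies: ", subfamily)
  n <- nrow(sub)
  k <- sum(sub$chrom == focal)
  data.frame(subfamily = subfamily, n_total = n, n_focal = k,
             expected_prop = expected, observed_prop = k / n,
             p = binom_two_sided(k, n, expected, method),
             stringsAsFactors = FALSE)
}

#' Classify all TE subfamilies by focal-chromosome enrichment
#'
#' Runs [binomial_focal_test()] for every subfamily with at least one
#' copy, BH-adjusts across all tested subfamilies, and assigns the
#' test-based status `enriched` (padj < alpha and observed > expected),
#' `depleted` (padj < alpha and observed < expected) or `neither`. Three
#' additional predicate groups, independent of the test, record
#' subfamilies with no copies on the focal chromosome, none on the second
#' chromosome, and none on either.
#'
#' @param copies repeat-copy data.frame with `chrom` and `subfamily`.
#' @param lengths chromosome-length list, see [default_chrom_lengths()].
#' @param focal focal chromosome (default `"Y"`).
#' @param other second sex chromosome used by the predicate groups
#'   (default `"X"`).
#' @param alpha FDR threshold for the enriched/depleted calls.
#' @param method two-sided rule passed to [binomial_focal_test()].
#' @return data.frame with one row per subfamily (`subfamily`, `n_total`,
#'   `n_focal`, `n_other`, `expected_prop`, `observed_prop`, `p`, `padj`,
#'   `status`) and an attribute `groups`: a named list of the six
#'   subfamily groups.
#' @export
classify_y_enrichment <- function(copies, lengths = default_chrom_lengths(),
                                  focal = "Y", other = "X", alpha = 0.05,
                                  method = "minlike") {
  if (!nrow(copies)) stop("no repeat copies supplied")
  if (anyNA(copies$subfamily))
    stop("copies without subfamily label; run attach_subfamilies() first")
  expected <- expected_proportion(lengths, focal)
  tab <- table(copies$subfamily)
  k_focal <- table(factor(copies$subfamily[copies$chrom == focal],
                          levels = names(tab)))
  k_other <- table(factor(copies$subfamily[copies$chrom == other],
                          levels = names(tab)))
  res <- data.frame(subfamily = names(tab),
                    n_total = as.integer(tab),
                    n_focal = as.integer(k_focal),
                    n_other = as.integer(k_other),
                    expected_prop = expected,
                    stringsAsFactors = FALSE)
  res$observed_prop <- res$n_focal / res$n_total
  res$p <- mapply(binom_two_sided, res$n_focal, res$n_total,
                  MoreArgs = list(p = expected, method = method))
  res$padj <- bh_adjust(res$p)
  res$status <- "neither"
  res$status[res$padj < alpha & res$observed_prop > expected] <- "enriched"
  res$status[res$padj < alpha & res$observed_prop < expected] <- "depleted"
  groups <- list(
    enriched = res$subfamily[res$status == "enriched"],
    depleted = res$subfamily[res$status == "depleted"],
    neither = res$subfamily[res$status == "neither"],
    no_focal_copies = res$subfamily[res$n_focal == 0L],
    no_other_copies = res$subfamily[res$n_other == 0L],
    no_focal_no_other = res$subfamily[res$n_focal == 0L & res$n_other == 0L])
  attr(res, "groups") <- groups
  res
}

#' Is a selected set of subfamilies richer in enriched members than the
#' background?
#'
#' One-sided exact binomial test of the number of focal-enriched
#' subfamilies within a selection (e.g., the top differentially expressed
#' subfamilies) against the genome-wide share of enriched subfamilies.
#'
#' @param selected character vector of subfamily names (subset of the
#'   classified records).
#' @param records classification from [classify_y_enrichment()].
#' @param background_share share of enriched subfamilies expected under
#'   the null; defaults to the share observed in `records`.
#' @return list with `n_selected`, `n_enriched`, `background_share`, `p`.
#' @export
enriched_share_test <- function(selected, records,
                                background_share = NULL) {
  if (!length(selected)) stop("empty selection")
  miss <- setdiff(selected, records$subfamily)
  if (length(miss))
    stop("selected subfamilies not present in records: ",
         paste(head(miss, 5L), collapse = ", "))
  if (is.null(background_share))
    background_share <- mean(records$status == "enriched")
  k <- sum(records$status[match(selected, records$subfamily)] == "enriched")
  p <- binom.test(k, length(selected), background_share,
                  alternative = "greater")$p.value
  list(n_selected = length(selected), n_enriched = k,
       background_share = background_share, p = p)
}
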