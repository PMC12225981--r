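# Shared fixture builders and independent oracles. Oracles are written as
# direct enumerations/brute force, independent of the package code paths
# they check.

make_cm <- function(m, kind = "gene", normalized = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  count_matrix(m, feature_kind = kind, normalized = normalized)
}

toy_copies <- function(chrom, start, end, strand = "+", subfamily = "SF1") {
  n <- length(start)
  data.frame(copy_id = sprintf("c%03d", seq_len(n)),
             chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n),
             subfamily = rep_len(subfamily, n), stringsAsFactors = FALSE)
}

toy_genes <- function(chrom, start, end, strand = "+") {
  n <- length(start)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

# two-sided minimum-likelihood exact binomial p by full enumeration over
# all n+1 outcomes (1e-7 relative guard against floating-point ties)
oracle_minlike <- function(k, n, p) {
  d <- dbinom(0:n, n, p)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# exact two-sided rank-sum p by complete enumeration of all labelings
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n)])
  mu <- n * (length(pooled) + 1) / 2
  combs <- combn(length(pooled), n)
  sums <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# all-pairs interval overlap oracle on 0-based half-open intervals
oracle_overlaps <- function(regions, copies, count_once = TRUE) {
  hit_any <- logical(nrow(regions))
  pairs <- 0L
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(copies))) {
      if (regions$chrom[i] == copies$chrom[j] &&
          regions$start[i] < copies$end[j] &&
          copies$start[j] < regions$end[i]) {
        hit_any[i] <- TRUE
        pairs <- pairs + 1L
      }
    }
  }
  if (count_once) sum(hit_any) else pairs
}

# brute-force BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# median-of-ratios size factors by direct per-sample enumeration
oracle_size_factors <- function(m) {
  all_pos <- apply(m > 0, 1, all)
  ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
  vapply(seq_len(ncol(m)), function(j)
    median(m[all_pos, j] / ref), numeric(1))
}

small_sim <- function(seed, ...) {
  sim_design(n_genes = 80L, n_subfamilies = 20L,
             copies_per_subfamily = 40L, seed = seed, ...)
}
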