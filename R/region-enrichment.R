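# Region-level enrichment: 3 kb upstream regions of genes, count-once
# overlap counting against TE copies, a resampled-regions permutation null
# and a strand-aware intragenic binomial test.

#' 3 kb upstream regions from transcription start sites
#'
#' For a `+` strand gene `[s, e)` the upstream region is
#' `[max(0, s - span), s)`; for a `-` strand gene it is `[e, e + span)`.
#' Regions are clipped at position 0 and, when chromosome lengths are
#' given, at the chromosome end.
#'
#' @param genes gene data.frame from [read_gene_annotation()].
#' @param span upstream span in bp (default 3000).
#' @param chrom_sizes optional named vector of chromosome lengths (bp) for
#'   end clipping.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one region per gene).
#' @export
upstream_regions <- function(genes, span = 3000, chrom_sizes = NULL) {
  if (span <= 0) stop("span must be positive")
  if (any(!genes$strand %in% c("+", "-")))
    stop("unstranded gene (TSS undefined)")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, genes$start - span), genes$end)
  end <- ifelse(plus, genes$start, genes$end + span)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    if (anyNA(lim)) stop("chromosome without recorded size: ",
                         genes$chrom[is.na(lim)][1L])
    end <- pmin(end, lim)
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = start, end = end, strand = genes$strand,
                    stringsAsFactors = FALSE)
  # a + strand gene starting at 0 has an empty upstream region; keep it
  # with zero length removed so that downstream overlap logic stays sane
  out[out$end > out$start, , drop = FALSE]
}

#' Count overlaps between regions and repeat copies
#'
#' Overlap requires at least 1 shared bp under half-open semantics
#' (abutting intervals do not overlap). With `count_once = TRUE` (the
#' region statistic used throughout) each region counts at most once no
#' matter how many copies it intersects; otherwise all region/copy pairs
#' are counted. Strand is ignored.
#'
#' @param regions region data.frame (e.g., from [upstream_regions()]).
#' @param copies repeat-copy data.frame.
#' @param count_once logical, see above.
#' @return integer overlap count.
#' @export
count_overlaps <- function(regions, copies, count_once = TRUE) {
  if (!nrow(regions) || !nrow(copies)) return(0L)
  check_shared_chroms(regions, copies, "regions", "copies")
  hits <- GenomicRanges::findOverlaps(as_granges(regions, use_strand = FALSE),
                                      as_granges(copies, use_strand = FALSE),
                                      ignore.strand = TRUE)
  if (count_once) length(unique(S4Vectors::queryHits(hits)))
  else length(hits)
}

#' Resampled-regions permutation enrichment test
#'
#' Tests whether the selected regions (e.g., upstream regions of
#' differentially expressed genes) overlap TE copies more or less often
#' than equally sized random subsets of the region universe. Each of the
#' `n_perm` permutations draws `|selected|` regions from the universe
#' without replacement and recomputes the count-once overlap statistic.
#' The test side is chosen automatically (greater when the observed count
#' is at least the null mean, less otherwise) and the empirical p-value is
#' smoothed: `p = (1 + #{null >= observed}) / (n_perm + 1)` for the
#' greater side. Results are reproducible for a fixed `seed`.
#'
#' @param selected region data.frame, a subset of `universe` (matched by
#'   `gene_id`).
#' @param universe region data.frame of all candidate regions.
#' @param copies repeat-copy data.frame.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer RNG seed (required).
#' @return list with `observed`, `n_perm`, `null_mean`, `null_sd`, `p`,
#'   `alternative`, `seed`.
#' @export
permutation_enrichment <- function(selected, universe, copies,
                                   n_perm = 5000, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (!nrow(selected)) stop("no selected regions")
  if (!all(selected$gene_id %in% universe$gene_id))
    stop("selected regions are not all contained in the universe")
  # precompute, per universe region, whether it overlaps any copy; the
  # count-once statistic of any subset is then a simple indicator sum
  flags <- rep(FALSE, nrow(universe))
  if (nrow(copies)) {
    check_shared_chroms(universe, copies, "universe regions", "copies")
    hits <- GenomicRanges::findOverlaps(
      as_granges(universe, use_strand = FALSE),
      as_granges(copies, use_strand = FALSE), ignore.strand = TRUE)
    flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  observed <- sum(flags[match(selected$gene_id, universe$gene_id)])
  n_sel <- nrow(selected)
  null_counts <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(seq_len(n_perm),
           function(i) sum(flags[sample.int(nrow(universe), n_sel)]),
           integer(1L))
  })
  alt <- if (observed >= mean(null_counts)) "greater" else "less"
  extreme <- if (alt == "greater") sum(null_counts >= observed)
             else sum(null_counts <= observed)
  list(observed = observed, n_perm = n_perm,
       null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
       p = (1 + extreme) / (n_perm + 1),
       alternative = alt, seed = seed)
}

#' Strand-aware intragenic TE-copy overlap test
#'
#' A gene "contains" a copy when their intervals share at least 1 bp and
#' their strands match (strand matching can be disabled). The observed
#' proportion of differentially expressed (DE) genes containing at least
#' one copy from the supplied copy set is compared with the proportion
#' over all genes (same copy set) by a two-sided exact binomial test.
#'
#' @param de_genes gene data.frame of DE genes (subset of `all_genes`).
#' @param all_genes gene data.frame of all genes.
#' @param copies repeat-copy data.frame (typically copies of the DE
#'   subfamilies in the matching direction).
#' @param strand_aware logical; `TRUE` mirrors an intersection with strand
#'   matching enforced.
#' @return list with `observed_prop`, `expected_prop`, `n_de`,
#'   `n_overlapping`, `p`, `status` (`"tested"`, or `"skipped"` when no
#'   gene at all contains a copy).
#' @export
intragenic_overlap_test <- function(de_genes, all_genes, copies,
                                    strand_aware = TRUE) {
  if (!nrow(de_genes)) stop("no differentially expressed genes supplied")
  if (!all(de_genes$gene_id %in% all_genes$gene_id))
    stop("de_genes must be a subset of all_genes")
  contains <- function(genes) {
    if (!nrow(copies)) return(logical(nrow(genes)))
    check_shared_chroms(genes, copies, "genes", "copies")
    hits <- GenomicRanges::findOverlaps(
      as_granges(genes, use_strand = strand_aware),
      as_granges(copies, use_strand = strand_aware),
      ignore.strand = !strand_aware)
    out <- logical(nrow(genes))
    out[unique(S4Vectors::queryHits(hits))] <- TRUE
    out
  }
  all_flag <- contains(all_genes)
  expected <- mean(all_flag)
  de_flag <- all_flag[match(de_genes$gene_id, all_genes$gene_id)]
  k <- sum(de_flag)
  if (expected == 0)
    return(list(observed_prop = k / nrow(de_genes), expected_prop = 0,
                n_de = nrow(de_genes), n_overlapping = k, p = NA_real_,
                status = "skipped"))
  p <- binom.test(k, nrow(de_genes), expected,
                  alternative = "two.sided")$p.value
  list(observed_prop = k / nrow(de_genes), expected_prop = expected,
       n_de = nrow(de_genes), n_overlapping = k, p = p, status = "tested")
}

#' Write regions as BED6
#'
#' @param regions region data.frame with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start, regions$end,
                   regions$gene_id, 0L, regions$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
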