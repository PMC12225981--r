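# Karyotype-structured synthetic data with known ground truth. The
# generator emulates the study design this package targets: four
# sex-chromosome karyotypes (XX, XY, XXY, XYY), negative-binomially
# distributed counts, Y-linked TE-copy dosage, mostly-inactivated extra X
# dosage, log-normal library-size variation and a two-level batch effect.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

karyotype_dosage <- function(karyotype) {
  switch(karyotype,
         XX = c(X = 2L, Y = 0L), XY = c(X = 1L, Y = 1L),
         XXY = c(X = 2L, Y = 1L), XYY = c(X = 1L, Y = 2L),
         stop("unknown karyotype: ", karyotype))
}

#' Simulation design
#'
#' Collects every knob of the synthetic cohort. Defaults mirror the kind
#' of cohort the package is built for: 6 XX, 6 XY, 8 XXY and 4 XYY
#' samples, an extra Y doubling the expression of Y-located TE copies
#' (`y_dosage_effect = 2`, the Y staying fully active) and an extra X
#' contributing only weakly (`x_dosage_effect = 1.1`, X inactivation), a
#' toy genome whose Y holds about 2% of the sequence, and a subset of TE
#' subfamilies preferentially inserting on the Y.
#'
#' @param n_per_karyotype named integer vector of cohort sizes.
#' @param n_genes,n_subfamilies,copies_per_subfamily genome size knobs.
#' @param y_enriched_fraction share of subfamilies that preferentially
#'   insert on the Y chromosome.
#' @param y_placement_prob per-copy probability of landing on Y for those
#'   subfamilies (vs. the ~2% length share otherwise).
#' @param y_dosage_effect multiplicative expression factor per extra Y on
#'   Y-located features.
#' @param x_dosage_effect multiplicative factor per extra X on X-located
#'   features (near 1: inactivation).
#' @param dispersion shared NB dispersion of counts.
#' @param libsize_sd SD of the log-normal per-sample library factor.
#' @param batch_effect_sd SD of the per-feature log-normal multiplier
#'   applied to second-batch samples.
#' @param gene_base_mean,copy_base_mean log-normal location of baseline
#'   expression means.
#' @param chrom_lengths named vector of toy chromosome lengths (bp); must
#'   include `chrX` and `chrY`.
#' @param include_markers add `XIST_sim` / `USP9Y_sim` marker genes whose
#'   expression tracks the X and Y complement (for aneuploidy flagging).
#' @param seed mandatory integer seed; the whole bundle is a pure function
#'   of the design.
#' @return a `sim_design` list.
#' @export
sim_design <- function(n_per_karyotype = c(XX = 6L, XY = 6L, XXY = 8L, XYY = 4L),
                       n_genes = 300L, n_subfamilies = 40L,
                       copies_per_subfamily = 60L,
                       y_enriched_fraction = 0.1,
                       y_placement_prob = 0.5,
                       y_dosage_effect = 2.0, x_dosage_effect = 1.1,
                       dispersion = 0.05, libsize_sd = 0.3,
                       batch_effect_sd = 0.1,
                       gene_base_mean = 500, copy_base_mean = 5,
                       chrom_lengths = c(chr1 = 500000, chr2 = 300000,
                                         chrX = 156000, chrY = 20000),
                       include_markers = TRUE, seed) {
  if (missing(seed)) stop("a seed is mandatory in a simulation design")
  stopifnot(all(c("chrX", "chrY") %in% names(chrom_lengths)),
            y_enriched_fraction >= 0, y_enriched_fraction <= 1,
            y_placement_prob >= 0, y_placement_prob <= 1,
            y_dosage_effect > 0, x_dosage_effect > 0, dispersion > 0)
  design <- list(n_per_karyotype = n_per_karyotype, n_genes = n_genes,
                 n_subfamilies = n_subfamilies,
                 copies_per_subfamily = copies_per_subfamily,
                 y_enriched_fraction = y_enriched_fraction,
                 y_placement_prob = y_placement_prob,
                 y_dosage_effect = y_dosage_effect,
                 x_dosage_effect = x_dosage_effect,
                 dispersion = dispersion, libsize_sd = libsize_sd,
                 batch_effect_sd = batch_effect_sd,
                 gene_base_mean = gene_base_mean,
                 copy_base_mean = copy_base_mean,
                 chrom_lengths = chrom_lengths,
                 include_markers = include_markers, seed = as.integer(seed))
  structure(design, class = "sim_design")
}

#' Simulate a toy genome with annotations and rosetta map
#'
#' Places TE copies and genes on the toy chromosomes of the design.
#' Y-enriched subfamilies (an exact `round(y_enriched_fraction *
#' n_subfamilies)` of them, chosen at random) put each copy on chrY with
#' probability `y_placement_prob`, far above the Y length share; all other
#' placement is proportional to chromosome length. Genes are uniform on
#' both strands.
#'
#' @param design a [sim_design()].
#' @return list with `chrom_lengths` (compatible with
#'   [expected_proportion()]), `copies`, `genes`, `rosetta`, and
#'   `truth` (data.frame: `subfamily`, `y_enriched`).
#' @export
simulate_genome <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    lens <- design$chrom_lengths
    copy_len <- 300L; gene_len <- 2000L
    if (any(lens < copy_len + 1L))
      stop("chromosome shorter than a TE copy; placement infeasible")
    nsub <- design$n_subfamilies
    subfams <- sprintf("SF%03d", seq_len(nsub))
    classes <- rep(c("LTR", "LINE", "SINE", "DNA", "SVA"), length.out = nsub)
    n_enr <- round(design$y_enriched_fraction * nsub)
    enriched <- sort(sample.int(nsub, n_enr))
    place <- function(n, probs) {
      chrom <- sample(names(lens), n, replace = TRUE, prob = probs)
      start <- floor(runif(n) * (lens[chrom] - copy_len))
      data.frame(chrom = chrom, start = start, end = start + copy_len,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    len_probs <- lens / sum(lens)
    copies <- vector("list", nsub)
    for (i in seq_len(nsub)) {
      n <- design$copies_per_subfamily
      if (i %in% enriched) {
        on_y <- runif(n) < design$y_placement_prob
        probs_non_y <- len_probs; probs_non_y["chrY"] <- 0
        df <- place(n, probs_non_y / sum(probs_non_y))
        if (any(on_y)) {
          y_start <- floor(runif(sum(on_y)) * (lens["chrY"] - copy_len))
          df$chrom[on_y] <- "chrY"
          df$start[on_y] <- y_start
          df$end[on_y] <- y_start + copy_len
        }
      } else {
        df <- place(n, len_probs)
      }
      df$subfamily <- subfams[i]
      copies[[i]] <- df
    }
    copies <- do.call(rbind, copies)
    copies$copy_id <- sprintf("%s_c%04d", copies$subfamily,
                              stats::ave(seq_len(nrow(copies)),
                                         copies$subfamily, FUN = seq_along))
    copies <- copies[c("copy_id", "chrom", "start", "end", "strand",
                       "subfamily")]
    rownames(copies) <- NULL

    if (any(lens < gene_len + 1L))
      stop("chromosome shorter than a gene; placement infeasible")
    g_chrom <- sample(names(lens), design$n_genes, replace = TRUE,
                      prob = len_probs)
    g_start <- floor(runif(design$n_genes) * (lens[g_chrom] - gene_len))
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(design$n_genes)),
                        chrom = g_chrom, start = g_start,
                        end = g_start + gene_len,
                        strand = sample(c("+", "-"), design$n_genes,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    if (design$include_markers) {
      mk <- data.frame(
        gene_id = c("XIST_sim", "USP9Y_sim"),
        chrom = c("chrX", "chrY"),
        start = c(0, 0), end = c(gene_len, gene_len),
        strand = c("+", "+"), stringsAsFactors = FALSE)
      genes <- rbind(genes, mk)
    }
    rownames(genes) <- NULL

    rosetta <- data.frame(copy_id = copies$copy_id,
                          subfamily = copies$subfamily,
                          class = classes[match(copies$subfamily, subfams)],
                          family = classes[match(copies$subfamily, subfams)],
                          stringsAsFactors = FALSE)
    list(chrom_lengths = list(lengths = lens, total = sum(lens)),
         copies = copies, genes = genes, rosetta = rosetta,
         truth = data.frame(subfamily = subfams,
                            y_enriched = seq_len(nsub) %in% enriched,
                            stringsAsFactors = FALSE))
  })
}

sim_dosage_factor <- function(chrom, karyotype, design) {
  d <- karyotype_dosage(karyotype)
  ifelse(chrom == "chrY",
         ifelse(d["Y"] == 0, 0, design$y_dosage_effect^(d["Y"] - 1)),
         ifelse(chrom == "chrX", design$x_dosage_effect^(d["X"] - 1), 1))
}

#' Simulate karyotype-structured count matrices
#'
#' Per-copy (and per-gene) expected counts are `baseline x chromosome
#' dosage x library factor x batch factor`; observed counts are negative
#' binomial with the design's dispersion. Y-located features have zero
#' mean in XX samples, and each extra Y multiplies their mean by
#' `y_dosage_effect`; X-located features scale by `x_dosage_effect` per
#' extra X. Marker genes, when enabled, express `XIST_sim` only with two
#' X's and `USP9Y_sim` only with at least one Y.
#'
#' @param design a [sim_design()].
#' @param genome output of [simulate_genome()] for the same design.
#' @return list with `gene_counts` and `copy_counts` (raw
#'   [count_matrix()] objects), `sheet` (sample metadata), and `truth`
#'   (list: `subfamily` truth table with expected log2 fold-changes for
#'   every pairwise karyotype contrast, `lib_factors`, `batch_factors`).
#' @export
simulate_counts <- function(design, genome) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed + 1L, {
    nk <- design$n_per_karyotype
    nk <- nk[nk > 0]
    karyo <- rep(names(nk), nk)
    n <- length(karyo)
    ids <- sprintf("s%02d", seq_len(n))
    sheet <- data.frame(
      sample_id = ids, karyotype = karyo,
      sex = ifelse(karyo == "XX", "female", "male"),
      age_group = sample(c("[20-30]", "]30-40]", "]40-50]", "]50-60]",
                           "]60-70]"), n, replace = TRUE),
      batch = sample(rep(c("b1", "b2"), length.out = n)),
      stringsAsFactors = FALSE)

    copies <- genome$copies
    genes <- genome$genes
    is_marker <- genes$gene_id %in% c("XIST_sim", "USP9Y_sim")
    base_copy <- stats::rlnorm(nrow(copies),
                               meanlog = log(design$copy_base_mean),
                               sdlog = 0.5)
    base_gene <- stats::rlnorm(nrow(genes),
                               meanlog = log(design$gene_base_mean),
                               sdlog = 0.7)
    base_gene[is_marker] <- design$gene_base_mean

    lib <- exp(rnorm(n, 0, design$libsize_sd))
    names(lib) <- ids
    nfeat <- nrow(copies) + nrow(genes)
    batch_mult <- exp(rnorm(nfeat, 0, design$batch_effect_sd))

    mean_for <- function(base, chrom, kt) base * sim_dosage_factor(chrom, kt, design)
    copy_mu <- vapply(seq_len(n), function(j) {
      mu <- mean_for(base_copy, copies$chrom, karyo[j]) * lib[j]
      if (sheet$batch[j] == "b2") mu <- mu * batch_mult[seq_len(nrow(copies))]
      mu
    }, numeric(nrow(copies)))
    gene_mu <- vapply(seq_len(n), function(j) {
      d <- karyotype_dosage(karyo[j])
      mu <- mean_for(base_gene, genes$chrom, karyo[j]) * lib[j]
      if (design$include_markers) {
        mu[genes$gene_id == "XIST_sim"] <-
          design$gene_base_mean * lib[j] * as.numeric(d["X"] >= 2)
        mu[genes$gene_id == "USP9Y_sim"] <-
          design$gene_base_mean * lib[j] * as.numeric(d["Y"] >= 1)
      }
      if (sheet$batch[j] == "b2")
        mu <- mu * batch_mult[nrow(copies) + seq_len(nrow(genes))]
      mu
    }, numeric(nrow(genes)))

    size <- 1 / design$dispersion
    draw <- function(mu) {
      out <- matrix(rnbinom(length(mu), mu = mu, size = size), nrow(mu))
      out
    }
    copy_counts <- draw(copy_mu)
    dimnames(copy_counts) <- list(copies$copy_id, ids)
    gene_counts <- draw(gene_mu)
    dimnames(gene_counts) <- list(genes$gene_id, ids)

    # exact expected subfamily log2FCs from the noise-free means
    kts <- names(nk)
    sub_mean <- sapply(kts, function(kt)
      rowsum(mean_for(base_copy, copies$chrom, kt),
             copies$subfamily)[, 1L, drop = TRUE])
    sub_mean <- matrix(sub_mean, ncol = length(kts),
                       dimnames = list(sort(unique(copies$subfamily)), kts))
    truth_sub <- genome$truth[genome$truth$subfamily %in%
                                rownames(sub_mean), , drop = FALSE]
    for (pr in utils::combn(kts, 2L, simplify = FALSE)) {
      col <- paste0("lfc_", pr[2L], "_vs_", pr[1L])
      truth_sub[[col]] <- log2(sub_mean[truth_sub$subfamily, pr[2L]] /
                               sub_mean[truth_sub$subfamily, pr[1L]])
    }
    list(gene_counts = count_matrix(gene_counts, "gene"),
         copy_counts = count_matrix(copy_counts, "te_copy"),
         sheet = sheet,
         truth = list(subfamily = truth_sub, lib_factors = lib,
                      batch_factors = batch_mult))
  })
}

#' Write a complete fixture bundle to disk
#'
#' Materializes a simulated study as the plain-text files the readers of
#' this package consume: `genes.bed`, `repeats.bed` (BED6 + subfamily
#' column), `rosetta.tsv`, `gene_counts.tsv`, `te_copy_counts.tsv`,
#' `samples.tsv`, `chrom_lengths.tsv`, the ground truth
#' (`truth_subfamilies.tsv`, `truth_samples.tsv`) and a `MANIFEST.yaml`
#' recording the design.
#'
#' @param dir output directory (created if absent).
#' @param design a [sim_design()].
#' @return the directory path, invisibly; the simulated objects are
#'   attached as the attribute `"objects"`.
#' @export
write_fixture_bundle <- function(dir, design) {
  stopifnot(inherits(design, "sim_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(design)
  sim <- simulate_counts(design, genome)
  p <- function(f) file.path(dir, f)
  write.table(data.frame(genome$genes$chrom, genome$genes$start,
                         genome$genes$end, genome$genes$gene_id, 0L,
                         genome$genes$strand),
              p("genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(genome$copies$chrom, genome$copies$start,
                         genome$copies$end, genome$copies$copy_id, 0L,
                         genome$copies$strand, genome$copies$subfamily),
              p("repeats.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(genome$rosetta, p("rosetta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_count_matrix(sim$gene_counts, p("gene_counts.tsv"), "gene_id")
  write_count_matrix(sim$copy_counts, p("te_copy_counts.tsv"), "copy_id")
  write.table(sim$sheet, p("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(chrom = names(genome$chrom_lengths$lengths),
                         length = unname(genome$chrom_lengths$lengths)),
              p("chrom_lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$subfamily, p("truth_subfamilies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(sim$truth$lib_factors),
                         lib_factor = unname(sim$truth$lib_factors)),
              p("truth_samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- unclass(design)
  manifest$n_per_karyotype <- as.list(manifest$n_per_karyotype)
  manifest$chrom_lengths <- as.list(manifest$chrom_lengths)
  yaml::write_yaml(manifest, p("MANIFEST.yaml"))
  invisible(structure(dir, objects = list(genome = genome, sim = sim)))
}
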