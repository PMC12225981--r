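# Configuration-driven orchestration of the full analysis: quantify ->
# normalize -> global TE statistics -> differential expression -> Y
# enrichment -> region enrichment, with per-stage TSV outputs, a run log
# and one machine-readable JSON summary.

#' Default pipeline configuration
#'
#' @param input_dir directory holding a fixture bundle as written by
#'   [write_fixture_bundle()] (individual paths can be overridden).
#' @param output_dir where stage outputs, the run log and `summary.json`
#'   are written.
#' @param seed integer seed for the stochastic stages.
#' @param span upstream span in bp.
#' @param n_perm permutations of the region-enrichment null.
#' @param alpha FDR threshold used for significance calls.
#' @param focal_chrom,other_chrom sex-chromosome names as used in the
#'   annotation files.
#' @param exclude repeat subfamilies to drop; defaults to
#'   [default_te_exclusions()].
#' @return configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(input_dir, output_dir, seed,
                            span = 3000, n_perm = 5000, alpha = 0.05,
                            focal_chrom = "chrY", other_chrom = "chrX",
                            exclude = default_te_exclusions()) {
  list(paths = list(genes = file.path(input_dir, "genes.bed"),
                    repeats = file.path(input_dir, "repeats.bed"),
                    rosetta = file.path(input_dir, "rosetta.tsv"),
                    gene_counts = file.path(input_dir, "gene_counts.tsv"),
                    copy_counts = file.path(input_dir, "te_copy_counts.tsv"),
                    samples = file.path(input_dir, "samples.tsv"),
                    chrom_lengths = file.path(input_dir, "chrom_lengths.tsv")),
       output_dir = output_dir, seed = seed, span = span, n_perm = n_perm,
       alpha = alpha, focal_chrom = focal_chrom, other_chrom = other_chrom,
       exclude = exclude)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$exclude)) cfg$exclude <- default_te_exclusions()
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every problem instead of stopping at the first one.
#'
#' @param config configuration list.
#' @return character vector of problems; empty when runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- c("genes", "repeats", "rosetta", "gene_counts", "copy_counts",
            "samples", "chrom_lengths")
  for (nm in need) {
    pth <- config$paths[[nm]]
    if (is.null(pth)) problems <- c(problems, paste0("missing path: ", nm))
    else if (!file.exists(pth))
      problems <- c(problems, paste0("file not found (", nm, "): ", pth))
  }
  if (is.null(config$output_dir))
    problems <- c(problems, "output_dir is required")
  if (is.null(config$seed))
    problems <- c(problems, "seed is required for the stochastic stages")
  if (!is.null(config$span) && config$span <= 0)
    problems <- c(problems, "span must be positive")
  if (!is.null(config$n_perm) && config$n_perm < 1)
    problems <- c(problems, "n_perm must be at least 1")
  if (!is.null(config$alpha) && (config$alpha <= 0 || config$alpha >= 1))
    problems <- c(problems, "alpha must lie in (0, 1)")
  if (!is.null(config$paths$samples) && file.exists(config$paths$samples)) {
    sheet <- tryCatch(read_sample_sheet(config$paths$samples),
                      error = function(e) conditionMessage(e))
    if (is.character(sheet)) problems <- c(problems, sheet)
  }
  problems
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs, writing one TSV per
#' result, a `run.log`, and a `summary.json` holding the headline numbers
#' (global TE proportions per karyotype, pairwise karyotype p-values, DE
#' counts at the configured FDR, the Y-enrichment partition, median
#' log2 fold-change tests and region-enrichment p-values). The run is
#' deterministic given the configuration: identical config and seed give
#' a byte-identical `summary.json`.
#'
#' @param config configuration list, see [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return the summary, invisibly (a nested list mirroring
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  logln <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cat(name, file = file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  alpha <- config$alpha %||% 0.05
  logln("config: seed=", config$seed, " span=", config$span %||% 3000,
        " n_perm=", config$n_perm %||% 5000, " alpha=", alpha,
        " focal=", config$focal_chrom %||% "chrY")

  inputs <- stage("read_inputs", {
    list(genes = read_gene_annotation(config$paths$genes, "bed"),
         copies = read_repeat_annotation(config$paths$repeats, "bed"),
         rosetta = read_rosetta(config$paths$rosetta),
         gene_counts = read_count_matrix(config$paths$gene_counts, "gene"),
         copy_counts = read_count_matrix(config$paths$copy_counts, "te_copy"),
         sheet = read_sample_sheet(config$paths$samples),
         lens = {
           lt <- read.delim(config$paths$chrom_lengths,
                            stringsAsFactors = FALSE)
           list(lengths = setNames(lt$length, lt$chrom),
                total = sum(lt$length))
         })
  })
  inputs$copies <- stage("read_inputs",
    if (all(is.na(inputs$copies$subfamily)))
      attach_subfamilies(inputs$copies, inputs$rosetta) else inputs$copies)
  logln("read_inputs: genes=", nrow(inputs$genes), " copies=",
        nrow(inputs$copies), " samples=", nrow(inputs$sheet))

  quant <- stage("quantify", {
    sub <- aggregate_copy_counts(inputs$copy_counts, inputs$rosetta)
    sub <- suppressMessages(filter_subfamilies(sub, config$exclude))
    sub <- drop_all_zero_features(sub)
    genes <- drop_all_zero_features(inputs$gene_counts)
    write_count_matrix(sub, file.path(out, "subfamily_counts.tsv"),
                       "subfamily")
    list(te = sub, genes = genes)
  })
  logln("quantify: subfamilies_in=", nrow(inputs$copy_counts),
        " subfamilies_out=", nrow(quant$te), " genes_out=", nrow(quant$genes))

  norm <- stage("normalize", {
    sf <- size_factors_from_genes(quant$genes)
    joint <- normalize_joint(quant$genes, quant$te, sf)
    write_size_factors(sf, file.path(out, "size_factors.tsv"))
    list(sf = sf, joint = joint)
  })
  logln("normalize: size_factor_range=",
        paste(signif(range(norm$sf), 4), collapse = "-"))

  glob <- stage("global_te", {
    display <- if ("batch" %in% names(inputs$sheet) &&
                   length(unique(inputs$sheet$batch)) >= 2L)
      remove_batch_effect(norm$joint, inputs$sheet) else norm$joint
    subsets <- build_te_subsets(inputs$rosetta)
    props <- lapply(subsets, function(mem)
      global_te_proportion(display, mem))
    karyo <- inputs$sheet$karyotype[match(colnames(norm$joint),
                                          inputs$sheet$sample_id)]
    tests <- do.call(rbind, lapply(names(subsets), function(nm) {
      tst <- pairwise_group_test(props[[nm]], karyo)
      tst$subset <- nm
      tst
    }))
    write.table(tests, file.path(out, "global_te_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    prop_tab <- data.frame(sample_id = colnames(norm$joint),
                           karyotype = karyo,
                           do.call(cbind, props), check.names = FALSE)
    write.table(prop_tab, file.path(out, "global_te_proportions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(props = props, tests = tests, karyo = karyo, subsets = subsets)
  })
  logln("global_te: subsets=", length(glob$subsets))

  de <- stage("differential_expression", {
    covar <- if (length(unique(inputs$sheet$batch)) >= 2L) "batch"
             else character()
    dsg <- design_spec("karyotype", covar)
    res_te <- suppressMessages(
      fit_nb_de(quant$te, norm$sf, inputs$sheet, dsg))
    res_gene <- suppressMessages(
      fit_nb_de(quant$genes, norm$sf, inputs$sheet, dsg))
    write.table(res_te, file.path(out, "de_te_subfamilies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res_gene, file.path(out, "de_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    med <- lapply(split(res_te[res_te$test == "wald", ],
                        res_te$contrast[res_te$test == "wald"]),
                  function(d) tryCatch(median_log2fc_test(d$log2fc),
                                       error = function(e) NULL))
    top <- rank_top_features(res_te, 15L, "lr")
    list(te = res_te, genes = res_gene, median_tests = med, top = top)
  })
  logln("differential_expression: te_features=",
        length(unique(de$te$feature_id)),
        " gene_features=", length(unique(de$genes$feature_id)))

  yenr <- stage("y_enrichment", {
    rec <- classify_y_enrichment(inputs$copies, inputs$lens,
                                 focal = config$focal_chrom %||% "chrY",
                                 other = config$other_chrom %||% "chrX",
                                 alpha = alpha)
    write.table(rec, file.path(out, "y_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    share <- tryCatch(
      enriched_share_test(intersect(de$top$feature_id, rec$subfamily), rec),
      error = function(e) NULL)
    list(records = rec, groups = attr(rec, "groups"), top_share = share)
  })
  logln("y_enrichment: tested=", nrow(yenr$records), " enriched=",
        sum(yenr$records$status == "enriched"))

  regions <- stage("region_enrichment", {
    universe <- upstream_regions(inputs$genes, span = config$span %||% 3000,
                                 chrom_sizes = inputs$lens$lengths)
    wald_te <- de$te[de$te$test == "wald", ]
    wald_gene <- de$genes[de$genes$test == "wald", ]
    sig_ids <- function(d, dir)
      d$feature_id[!is.na(d$padj) & d$padj < alpha &
                     if (dir == "up") d$log2fc > 0 else d$log2fc < 0]
    perms <- list()
    intra <- list()
    for (ctr in unique(wald_te$contrast)) {
      dte <- wald_te[wald_te$contrast == ctr, ]
      dg <- wald_gene[wald_gene$contrast == ctr, ]
      for (dir in c("up", "down")) {
        sig_sub <- sig_ids(dte, dir)
        sig_gene <- sig_ids(dg, dir)
        if (!length(sig_sub) || !length(sig_gene)) next
        sel_copies <- inputs$copies[inputs$copies$subfamily %in% sig_sub, ]
        sel_regions <- universe[universe$gene_id %in% sig_gene, ]
        if (!nrow(sel_regions)) next
        key <- paste0(gsub(" ", "_", ctr), "_", dir)
        perms[[key]] <- permutation_enrichment(
          sel_regions, universe, sel_copies,
          n_perm = config$n_perm %||% 5000,
          seed = (config$seed + length(perms)) %% .Machine$integer.max)
        intra[[key]] <- intragenic_overlap_test(
          inputs$genes[inputs$genes$gene_id %in% sig_gene, ],
          inputs$genes, sel_copies, strand_aware = TRUE)
      }
    }
    list(universe = universe, perms = perms, intra = intra)
  })
  logln("region_enrichment: universe=", nrow(regions$universe),
        " tests=", length(regions$perms))

  summary <- list(
    n_samples = ncol(norm$joint),
    n_te_subfamilies = nrow(quant$te),
    n_genes = nrow(quant$genes),
    global_te_proportion_by_karyotype = lapply(
      split(glob$props$ALL, glob$karyo), function(v) round(median(v), 10)),
    pairwise_global_tests = lapply(seq_len(nrow(glob$tests)), function(i)
      list(subset = glob$tests$subset[i], group_a = glob$tests$group_a[i],
           group_b = glob$tests$group_b[i],
           p = round(glob$tests$p[i], 10))),
    de_counts = lapply(split(de$te[de$te$test == "wald", ],
                             de$te$contrast[de$te$test == "wald"]),
                       function(d) sum(!is.na(d$padj) & d$padj < alpha)),
    median_log2fc = lapply(de$median_tests, function(m)
      if (is.null(m)) NULL else list(median = round(m$median, 10),
                                     p = round(m$p, 10))),
    y_enrichment = list(
      expected_prop = expected_proportion(inputs$lens,
                                          config$focal_chrom %||% "chrY"),
      n_enriched = sum(yenr$records$status == "enriched"),
      n_depleted = sum(yenr$records$status == "depleted"),
      n_neither = sum(yenr$records$status == "neither"),
      n_no_focal = length(yenr$groups$no_focal_copies),
      top_share_p = if (is.null(yenr$top_share)) NULL
                    else round(yenr$top_share$p, 10)),
    permutation = lapply(regions$perms, function(pr)
      list(observed = pr$observed, p = round(pr$p, 10),
           alternative = pr$alternative)),
    intragenic = lapply(regions$intra, function(ir)
      list(observed_prop = round(ir$observed_prop, 10),
           expected_prop = round(ir$expected_prop, 10),
           p = if (is.na(ir$p)) NULL else round(ir$p, 10),
           status = ir$status)),
    seed = config$seed)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out, "summary.json"))
  logln("done")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
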