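# Readers for the genomic annotation formats consumed by the pipeline.
# Everything downstream works on plain data.frames with 0-based half-open
# intervals; GenomicRanges is used internally for overlap machinery.

validate_intervals <- function(df, what, lines = NULL) {
  bad <- which(!(df$start >= 0 & df$start < df$end) | !nzchar(df$chrom))
  if (length(bad)) {
    where <- if (is.null(lines)) bad[1L] else lines[bad[1L]]
    stop(sprintf("invalid %s interval at line %d: start=%s end=%s chrom='%s'",
                 what, where, df$start[bad[1L]], df$end[bad[1L]],
                 df$chrom[bad[1L]]))
  }
  invisible(df)
}

split_fields <- function(txt, path) {
  strsplit(trimws(txt), "[ \t]+")
}

#' Read a repeat-copy annotation
#'
#' Parses genomic locations of individual TE insertion copies from either a
#' BED file or a RepeatMasker `.out` table. Coordinates are returned 0-based
#' half-open regardless of dialect (RepeatMasker's 1-based inclusive `begin`
#' is shifted down by one).
#'
#' @param path file path.
#' @param dialect `"bed"` (columns: chrom, start, end, copy_id, score,
#'   strand, and optionally a 7th subfamily column) or `"rmsk_out"`
#'   (standard RepeatMasker `.out` layout; the repeat name column supplies
#'   the subfamily and a copy id is built from name and position when no ID
#'   column is present).
#' @return data.frame with columns `copy_id`, `chrom`, `start`, `end`,
#'   `strand`, `subfamily` (`NA` when the source carries none; see
#'   [attach_subfamilies()]).
#' @export
read_repeat_annotation <- function(path, dialect = c("bed", "rmsk_out")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path)
  if (dialect == "bed") {
    keep <- which(nzchar(trimws(txt)) & !startsWith(trimws(txt), "#"))
    fields <- split_fields(txt[keep], path)
    n <- lengths(fields)
    if (any(n < 6L))
      stop("malformed BED line ", keep[which(n < 6L)[1L]],
           ": fewer than 6 fields")
    get <- function(i) vapply(fields, `[[`, "", i)
    start <- suppressWarnings(as.numeric(get(2L)))
    end <- suppressWarnings(as.numeric(get(3L)))
    if (anyNA(start) || anyNA(end))
      stop("malformed BED line ", keep[which(is.na(start) | is.na(end))[1L]],
           ": non-numeric coordinate")
    subfam <- vapply(fields, function(f)
      if (length(f) >= 7L) f[[7L]] else NA_character_, "")
    df <- data.frame(copy_id = get(4L), chrom = get(1L),
                     start = start, end = end, strand = get(6L),
                     subfamily = subfam, stringsAsFactors = FALSE)
    validate_intervals(df, "repeat", keep)
  } else {
    keep <- which(nzchar(trimws(txt)))
    # skip the two header lines + blank line of the .out format
    fields <- split_fields(txt[keep], path)
    is_data <- vapply(fields, function(f)
      length(f) >= 11L && !is.na(suppressWarnings(as.numeric(f[[1L]]))), TRUE)
    keep <- keep[is_data]
    fields <- fields[is_data]
    if (!length(fields)) stop("no data rows in RepeatMasker file: ", path)
    get <- function(i) vapply(fields, `[[`, "", i)
    begin <- suppressWarnings(as.numeric(get(6L)))
    end <- suppressWarnings(as.numeric(get(7L)))
    if (anyNA(begin) || anyNA(end))
      stop("malformed RepeatMasker line ",
           keep[which(is.na(begin) | is.na(end))[1L]])
    strand <- ifelse(get(9L) == "C", "-", "+")
    subfam <- get(10L)
    id <- vapply(fields, function(f) if (length(f) >= 15L) f[[15L]] else NA_character_, "")
    copy_id <- ifelse(is.na(id) | duplicated(id) | id == "",
                      paste0(subfam, "_", get(5L), "_", begin),
                      paste0(subfam, "_", id))
    df <- data.frame(copy_id = copy_id, chrom = get(5L),
                     start = begin - 1, end = end, strand = strand,
                     subfamily = subfam, stringsAsFactors = FALSE)
    validate_intervals(df, "repeat", keep)
  }
  if (anyDuplicated(df$copy_id))
    stop("duplicate copy_id in ", path, ": ",
         df$copy_id[duplicated(df$copy_id)][1L])
  df
}

#' Read a gene annotation
#'
#' Reads gene models from a BED6 file or a GTF restricted to `gene`-typed
#' rows ("GTF-lite"). Genes must be stranded (`+` or `-`) because the
#' transcription start site is undefined otherwise. GTF's 1-based inclusive
#' coordinates are converted to 0-based half-open.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"gtf_lite"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "gtf_lite")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed") {
    bed <- read_repeat_annotation(path, "bed")
    df <- data.frame(gene_id = bed$copy_id, chrom = bed$chrom,
                     start = bed$start, end = bed$end, strand = bed$strand,
                     stringsAsFactors = FALSE)
  } else {
    txt <- readLines(path)
    keep <- which(nzchar(trimws(txt)) & !startsWith(txt, "#"))
    fields <- strsplit(txt[keep], "\t", fixed = TRUE)
    n <- lengths(fields)
    if (any(n < 9L))
      stop("malformed GTF line ", keep[which(n < 9L)[1L]],
           ": fewer than 9 tab-separated fields")
    type <- vapply(fields, `[[`, "", 3L)
    fields <- fields[type == "gene"]
    if (!length(fields)) stop("no 'gene' rows in GTF file: ", path)
    attrs <- vapply(fields, `[[`, "", 9L)
    gene_id <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", attrs)
    if (any(gene_id == attrs))
      stop("GTF record without gene_id attribute in ", path)
    start <- as.numeric(vapply(fields, `[[`, "", 4L))
    end <- as.numeric(vapply(fields, `[[`, "", 5L))
    df <- data.frame(gene_id = gene_id,
                     chrom = vapply(fields, `[[`, "", 1L),
                     start = start - 1, end = end,
                     strand = vapply(fields, `[[`, "", 7L),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         df$gene_id[duplicated(df$gene_id)][1L])
  if (any(!df$strand %in% c("+", "-")))
    stop("unstranded gene (TSS undefined): ",
         df$gene_id[!df$strand %in% c("+", "-")][1L])
  validate_intervals(df, "gene")
  df
}

#' Transcription start sites
#'
#' The TSS is the interval start for `+` strand genes and the interval end
#' for `-` strand genes (0-based).
#'
#' @param genes data.frame from [read_gene_annotation()].
#' @return integer-like numeric vector of TSS positions, named by gene id.
#' @export
gene_tss <- function(genes) {
  setNames(ifelse(genes$strand == "+", genes$start, genes$end),
           genes$gene_id)
}

#' Read a rosetta copy-to-subfamily map
#'
#' A tab-delimited table with columns `copy_id`, `subfamily`, `class`,
#' `family`, mapping every TE insertion copy to its subfamily and the
#' subfamily to its lineage (class/order labels such as LTR, LINE, SINE,
#' SVA, DNA).
#'
#' @param path file path.
#' @return data.frame with those four character columns.
#' @export
read_rosetta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("copy_id", "subfamily", "class", "family")
  if (!all(need %in% names(df)))
    stop("rosetta file must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$copy_id))
    stop("rosetta maps a copy_id more than once: ",
         df$copy_id[duplicated(df$copy_id)][1L])
  if (any(!nzchar(df$subfamily)))
    stop("rosetta contains an empty subfamily name")
  df
}

#' Attach subfamily labels to repeat copies from a rosetta map
#'
#' @param copies data.frame from [read_repeat_annotation()].
#' @param rosetta data.frame from [read_rosetta()].
#' @return `copies` with its `subfamily` column filled from the map.
#' @export
attach_subfamilies <- function(copies, rosetta) {
  idx <- match(copies$copy_id, rosetta$copy_id)
  if (anyNA(idx))
    stop("copies absent from rosetta map: ",
         paste(head(copies$copy_id[is.na(idx)], 5L), collapse = ", "))
  copies$subfamily <- rosetta$subfamily[idx]
  copies
}

#' Read a sample sheet
#'
#' Tab-delimited per-sample metadata with at least `sample_id` and
#' `karyotype` columns; `sex`, `age_group`, `batch` and `cohort` are kept
#' when present. Karyotype must be consistent with sex: XX is female,
#' XY/XXY/XYY are male.
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet
#'
#' @param df data.frame of per-sample metadata.
#' @return `df`, with character columns, after validation.
#' @export
validate_sample_sheet <- function(df) {
  if (!all(c("sample_id", "karyotype") %in% names(df)))
    stop("sample sheet needs 'sample_id' and 'karyotype' columns")
  df$sample_id <- as.character(df$sample_id)
  df$karyotype <- as.character(df$karyotype)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  ok <- c("XX", "XY", "XXY", "XYY")
  bad <- !df$karyotype %in% ok
  if (any(bad))
    stop("unknown karyotype '", df$karyotype[bad][1L], "' for sample ",
         df$sample_id[bad][1L])
  if ("sex" %in% names(df)) {
    df$sex <- as.character(df$sex)
    expected <- ifelse(df$karyotype == "XX", "female", "male")
    off <- df$sex != expected
    if (any(off))
      stop("sex/karyotype mismatch for sample ", df$sample_id[off][1L],
           " (", df$karyotype[off][1L], " must be ", expected[off][1L], ")")
  }
  df
}

# 0-based half-open data.frame -> GRanges (1-based closed) for overlap work.
as_granges <- function(df, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand)
}

# Mismatched chromosome naming between two interval sets is almost always a
# chr-prefix problem; fail loudly instead of returning an empty overlap.
check_shared_chroms <- function(a, b, what_a, what_b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(invisible(TRUE))
  if (!length(intersect(unique(a$chrom), unique(b$chrom))))
    stop("no chromosome name shared between ", what_a, " (",
         paste(head(unique(a$chrom), 3L), collapse = ","), ") and ",
         what_b, " (", paste(head(unique(b$chrom), 3L), collapse = ","),
         "); check naming conventions")
  invisible(TRUE)
}
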