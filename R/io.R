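#' Read a Bismark-style cytosine report
#'
#' Ingests the standard seven-column cytosine/CX report (one row per cytosine:
#' chromosome, 1-based position, strand, methylated count, unmethylated count,
#' context, trinucleotide) into a tidy per-site count table. Sites whose total
#' coverage (methylated + unmethylated) falls below `min_coverage` are dropped;
#' retained counts are preserved exactly.
#'
#' @param path Path to a tab-separated cytosine report (no header).
#' @param sample_id Sample identifier attached to every row. Defaults to the
#'   file name without extension.
#' @param group Group label (e.g. `"WT"`, a treatment state) attached to every
#'   row.
#' @param min_coverage Minimum total read coverage for a site to be retained.
#'   The default of 4 suppresses zero-information sites while keeping
#'   shallow-coverage cytosines available to the divergence stage.
#'
#' @return A tibble with columns `sample_id`, `group`, `chrom`, `pos`,
#'   `strand`, `context`, `trinucleotide`, `meth`, `unmeth`.
#' @export
read_cytosine_report <- function(path, sample_id = NULL, group = NA_character_,
                                 min_coverage = 4) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "meth", "unmeth", "context",
                  "trinucleotide"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      strand = readr::col_character(),
      meth = readr::col_double(),
      unmeth = readr::col_double(),
      context = readr::col_character(),
      trinucleotide = readr::col_character()
    ),
    progress = FALSE, lazy = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop_bad_arg("malformed cytosine report %s: parse error at line %d (%s)",
                 path, probs$row[1], probs$expected[1])
  }
  validate_methylome(raw, path)
  out <- tibble::tibble(sample_id = sample_id, group = group,
                        dplyr::as_tibble(raw))
  out$pos <- as.integer(out$pos)
  out$meth <- as.integer(out$meth)
  out$unmeth <- as.integer(out$unmeth)
  dplyr::filter(out, .data$meth + .data$unmeth >= min_coverage)
}

validate_methylome <- function(df, label = "methylome table") {
  if (anyNA(df$pos) || anyNA(df$meth) || anyNA(df$unmeth)) {
    stop_bad_arg("%s: missing values in pos/meth/unmeth columns", label)
  }
  if (any(df$meth < 0) || any(df$unmeth < 0)) {
    stop_bad_arg("%s: negative methylation counts", label)
  }
  if (any(df$pos < 1)) stop_bad_arg("%s: positions must be >= 1", label)
  bad_strand <- setdiff(unique(df$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    stop_bad_arg("%s: invalid strand value(s) %s", label,
                 paste(bad_strand, collapse = ", "))
  }
  key <- site_key(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_bad_arg("%s: duplicate (chrom, pos, strand) record %s", label, dup)
  }
  invisible(df)
}

#' Write a methylome count table as a cytosine report
#'
#' Inverse of [read_cytosine_report()]: emits the seven standard columns as a
#' headerless TSV, sorted by chromosome then position then strand.
#'
#' @param meth Tidy methylome tibble (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(meth, path) {
  out <- meth |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand) |>
    dplyr::select("chrom", "pos", "strand", "meth", "unmeth", "context",
                  "trinucleotide")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read genomic features from BED or GFF3
#'
#' Coordinates are normalized to the internal 1-based, inclusive convention
#' (the convention of the cytosine report): BED's 0-based half-open intervals
#' are shifted on ingest, GFF3 coordinates pass through unchanged.
#'
#' @param path Path to a BED or GFF3 file.
#' @param kind Feature kind label: one of `"gene"`, `"TE"`, `"sRNA_cluster"`.
#' @param format `"auto"` (by file extension), `"bed"`, or `"gff3"`.
#' @return A tibble with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `kind`.
#' @export
read_features <- function(path, kind = c("gene", "TE", "sRNA_cluster"),
                          format = c("auto", "bed", "gff3")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3", gtf = "gff3",
      stop_bad_arg("cannot autodetect feature format from extension '.%s'", ext)
    )
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  ids <- if (!is.null(gr$name) && !anyNA(gr$name)) {
    as.character(gr$name)
  } else if (!is.null(gr$ID) && !anyNA(gr$ID)) {
    as.character(gr$ID)
  } else {
    paste0(kind, "_", seq_along(gr))
  }
  out <- tibble::tibble(
    feature_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind
  )
  if (any(out$start > out$end)) {
    stop_bad_arg("feature file %s: start > end after normalization", path)
  }
  out
}

#' Write genomic features to BED or GFF3
#'
#' @param features Feature tibble as returned by [read_features()].
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
  gr$name <- features$feature_id
  if (format == "gff3") {
    gr$ID <- features$feature_id
    gr$type <- features$kind
    gr$source <- "methylodecode"
  }
  rtracklayer::export(gr, path, format = if (format == "bed") "BED" else "GFF3")
  invisible(path)
}

#' Write a results table as deterministic TSV
#'
#' Rows are sorted by genomic coordinate (`chrom`, `pos`) when present,
#' otherwise by the first identifier column (`gene_id`, `cluster_id`,
#' `node_id`, or `feature_id`); columns keep their tibble order. Numbers are
#' written at full precision so a write/read round trip preserves at least
#' 12 significant digits.
#'
#' @param records A tibble of DMPs, DMG results, cluster summaries, etc.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  sort_cols <- intersect(c("chrom", "pos", "gene_id", "cluster_id", "node_id",
                           "feature_id", "sample_id"), names(records))
  if (length(sort_cols) > 0) {
    records <- dplyr::arrange(records,
                              dplyr::across(dplyr::all_of(sort_cols)))
  }
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
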