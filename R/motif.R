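#' Extract fixed-width sequence windows around recurrent DMPs
#'
#' A window is emitted for every site carrying a DMP at the identical
#' (chrom, pos, strand) coordinate in at least `min_samples` samples. The
#' window is `width` bp with the DMP cytosine at position `anchor_offset`
#' (default: 14 bp, cytosine at nucleotide 7): on the plus strand
#' `genome[pos-6 .. pos+7]`, on the minus strand the reverse complement of
#' `genome[pos-7 .. pos+6]`, so the anchor is a C in window coordinates on
#' either strand. Windows running past a contig end are dropped with a
#' warning; an anchor base that is not C after strand normalization is a
#' validation error.
#'
#' @param dmps Combined DMP tibble across samples (`sample_id`, `chrom`,
#'   `pos`, `strand`).
#' @param genome Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences.
#' @param min_samples Minimum number of samples sharing the DMP (default 3).
#' @param width Window width (default 14).
#' @param anchor_offset 1-based anchor position within the window (default 7).
#' @return Tibble: `chrom`, `anchor_pos`, `strand`, `seq`, `support`.
#' @export
extract_windows <- function(dmps, genome, min_samples = 3, width = 14,
                            anchor_offset = 7) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  recurrent <- dmps |>
    dplyr::distinct(.data$sample_id, .data$chrom, .data$pos, .data$strand) |>
    dplyr::count(.data$chrom, .data$pos, .data$strand, name = "support") |>
    dplyr::filter(.data$support >= min_samples)
  if (nrow(recurrent) == 0) {
    return(tibble::tibble(chrom = character(0), anchor_pos = integer(0),
                          strand = character(0), seq = character(0),
                          support = integer(0)))
  }
  missing_chrom <- setdiff(unique(recurrent$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop_bad_arg("extract_windows(): genome lacks contig(s) %s",
                 paste(missing_chrom, collapse = ", "))
  }
  left_plus <- anchor_offset - 1L
  right_plus <- width - anchor_offset
  starts <- ifelse(recurrent$strand == "+",
                   recurrent$pos - left_plus, recurrent$pos - right_plus)
  ends <- starts + width - 1L
  contig_len <- nchar(genome)[recurrent$chrom]
  inside <- starts >= 1 & ends <= contig_len
  if (any(!inside)) {
    warn(sprintf("extract_windows(): dropped %d window(s) overlapping contig ends",
                 sum(!inside)))
  }
  recurrent <- recurrent[inside, ]
  starts <- starts[inside]; ends <- ends[inside]
  seqs <- substr(genome[recurrent$chrom], starts, ends)
  minus <- recurrent$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement_chr(seqs[minus])
  anchor_base <- substr(seqs, anchor_offset, anchor_offset)
  bad <- anchor_base != "C"
  if (any(bad)) {
    i <- which(bad)[1]
    stop_bad_arg("extract_windows(): anchor base is '%s', not C, at %s:%d(%s)",
                 anchor_base[i], recurrent$chrom[i], recurrent$pos[i],
                 recurrent$strand[i])
  }
  tibble::tibble(chrom = recurrent$chrom,
                 anchor_pos = as.integer(recurrent$pos),
                 strand = recurrent$strand,
                 seq = unname(seqs),
                 support = recurrent$support)
}

#' Pairwise evolutionary distances between equal-length windows
#'
#' Computed with `ape::dist.dna`: `"raw"` is the proportion of mismatching
#' sites, `"k80"` the Kimura two-parameter distance. Pairs for which the K80
#' transform is undefined (too divergent) are set to a large sentinel (10)
#' with a warning.
#'
#' @param windows Window tibble from [extract_windows()] or a character
#'   vector of equal-length sequences.
#' @param model `"raw"` (default) or `"k80"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(windows, model = c("raw", "k80")) {
  model <- match.arg(model)
  seqs <- if (is.data.frame(windows)) windows$seq else windows
  mat <- seqs_to_matrix(seqs)
  bin <- ape::as.DNAbin(tolower(mat))
  ape_model <- switch(model, raw = "raw", k80 = "K80")
  d <- as.matrix(ape::dist.dna(bin, model = ape_model,
                               pairwise.deletion = TRUE))
  bad <- !is.finite(d)
  if (any(bad)) {
    warn(sprintf("pairwise_distance(): %d undefined %s distance(s) set to sentinel 10",
                 sum(bad & upper.tri(d)), model))
    d[bad] <- 10
    diag(d) <- 0
  }
  dimnames(d) <- NULL
  d
}

#' UPGMA clustering of windows with a size filter
#'
#' Average-linkage (UPGMA) agglomeration of the distance matrix, cut into
#' `min(k, n)` flat clusters; clusters with fewer than `min_size` members are
#' discarded.
#'
#' @param dist_matrix Symmetric distance matrix (zero diagonal).
#' @param k Number of flat clusters to cut (default 100).
#' @param min_size Minimum surviving cluster size (default 10).
#' @return Tibble `item` (row index into the input), `cluster_id`, restricted
#'   to surviving clusters; the full assignment (including discarded
#'   clusters) is attached as attribute `assignment`, the hclust tree as
#'   attribute `tree`.
#' @export
upgma_clusters <- function(dist_matrix, k = 100, min_size = 10) {
  n <- nrow(dist_matrix)
  if (is.null(n) || n < 2) stop_bad_arg("upgma_clusters(): need >= 2 items")
  if (k < 1) stop_bad_arg("upgma_clusters(): k must be >= 1")
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  kk <- min(k, n)
  # cut at the k-cluster merge height rather than by count: tied merges
  # (e.g. identical sequences, height 0) then stay in one cluster instead of
  # being split arbitrarily
  assignment <- if (kk >= n) {
    stats::cutree(hc, k = n)
  } else {
    stats::cutree(hc, h = hc$height[n - kk])
  }
  sizes <- table(assignment)
  kept <- as.integer(names(sizes)[sizes >= min_size])
  out <- tibble::tibble(item = seq_len(n), cluster_id = as.integer(assignment)) |>
    dplyr::filter(.data$cluster_id %in% kept)
  attr(out, "assignment") <- as.integer(assignment)
  attr(out, "tree") <- hc
  out
}

#' Align the members of a motif cluster
#'
#' Windows are fixed-width and coordinate-anchored at the DMP cytosine, so
#' the default `"anchored"` mode simply returns them as a gap-free MSA — the
#' alignment is positional by construction. `"external"` shells out to a
#' user-configured aligner binary (e.g. `mafft`), reads its FASTA output,
#' and enforces equal row lengths.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param mode `"anchored"` (default) or `"external"`.
#' @param aligner External aligner command; it must accept a FASTA path as
#'   last argument and write aligned FASTA to stdout.
#' @param args Extra command-line arguments for the aligner.
#' @return Character vector of aligned rows (equal lengths).
#' @export
align_cluster <- function(seqs, mode = c("anchored", "external"),
                          aligner = "mafft", args = c("--auto", "--quiet")) {
  mode <- match.arg(mode)
  if (mode == "anchored") {
    seqs_to_matrix(seqs)  # validates equal lengths
    return(seqs)
  }
  if (Sys.which(aligner) == "") {
    stop_bad_arg("align_cluster(): external aligner '%s' not found", aligner)
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fa)
  res <- suppressWarnings(system2(aligner, c(args, fa), stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    stop_bad_arg("align_cluster(): aligner failed (status %d): %s", status,
                 paste(utils::head(res, 5), collapse = " | "))
  }
  out <- toupper(as.character(Biostrings::readDNAStringSet(
    textConnection(res), format = "fasta")))
  seqs_to_matrix(out)
  unname(out)
}

#' Motif score and information content of an MSA
#'
#' For every unordered pair (j, k) of the M aligned rows, the pairwise score
#' is the base-2 logarithm of the number of matching bases,
#' \eqn{s_{jk} = \log_2 \sum_i 1[b_j^i = b_k^i]} (gap or ambiguous positions
#' never match). The motif score is the mean over the m = M(M-1)/2 pairs,
#' \eqn{S = \frac{1}{m}\sum_{j<k} s_{jk}}, bounded above by
#' \eqn{\log_2 N} for an alignment of width N, and the information
#' (uncertainty change) carried by the MSA is \eqn{I = \log_2 N - S}. A pair
#' with zero matches has \eqn{s_{jk} = -\infty}, which propagates to
#' \eqn{S = -\infty} unless a positive `min_matches` floor is supplied.
#'
#' @param msa Character vector of equal-length rows, or a character matrix.
#' @param min_matches Optional floor on pairwise match counts (default 0:
#'   faithful \eqn{-\infty} propagation).
#' @return Object of class `md_motif_score`: `s_matrix` (M x M pairwise
#'   scores, diagonal NA), `score_s`, `info_i`, `m_rows`, `n_cols`.
#' @export
motif_score <- function(msa, min_matches = 0) {
  mat <- seqs_to_matrix(msa)
  M <- nrow(mat); N <- ncol(mat)
  if (M < 2) stop_bad_arg("motif_score(): need >= 2 aligned rows")
  matches <- matrix(0, M, M)
  for (b in DNA_BASES) {
    ind <- (mat == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  matches <- pmax(matches, min_matches)
  s <- log2(matches)
  diag(s) <- NA_real_
  pair_scores <- s[upper.tri(s)]
  score_s <- mean(pair_scores)
  structure(list(s_matrix = s, score_s = score_s,
                 info_i = log2(N) - score_s,
                 m_rows = M, n_cols = N),
            class = "md_motif_score")
}

#' @export
print.md_motif_score <- function(x, ...) {
  cat("<md_motif_score> M =", x$m_rows, "N =", x$n_cols,
      " S =", signif(x$score_s, 6), " I =", signif(x$info_i, 6), "\n")
  invisible(x)
}

#' Position frequency matrix of an MSA
#'
#' Column-wise base frequencies (N x 4, positions by A/C/G/T), optionally
#' Laplace-smoothed; gaps and ambiguous characters are excluded from the
#' denominator. An all-gap column is an error.
#'
#' @param msa Character vector of equal-length rows or character matrix.
#' @param pseudocount Added to every cell before normalization (default 0).
#' @return N x 4 numeric matrix, rows summing to 1, columns named A, C, G, T.
#' @export
frequency_matrix <- function(msa, pseudocount = 0) {
  mat <- seqs_to_matrix(msa)
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, DNA_BASES))
  if (any(rowSums(counts) == 0)) {
    stop_bad_arg("frequency_matrix(): all-gap column at position %d",
                 which(rowSums(counts) == 0)[1])
  }
  counts <- counts + pseudocount
  freq <- counts / rowSums(counts)
  rownames(freq) <- seq_len(nrow(freq))
  freq
}

#' Cluster recurrent-DMP windows and score each cluster's motif
#'
#' Convenience wrapper for the motif stage: pairwise distances, UPGMA cut
#' into `k` clusters, size filter, anchored alignment, and the motif score
#' S / information I per surviving cluster.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param k,min_size,distance See [upgma_clusters()] / [pairwise_distance()].
#' @return List of class `md_motif_clusters`: `clusters` (tibble
#'   `cluster_id`, `n_members`, `score_s`, `info_i`), `members` (windows with
#'   `cluster_id`), `msas` (named list of character MSAs).
#' @export
motif_clusters <- function(windows, k = 100, min_size = 10,
                           distance = c("raw", "k80")) {
  distance <- match.arg(distance)
  if (nrow(windows) < 2) {
    stop_bad_arg("motif_clusters(): need >= 2 windows, got %d", nrow(windows))
  }
  d <- pairwise_distance(windows, model = distance)
  cl <- upgma_clusters(d, k = k, min_size = min_size)
  members <- windows[cl$item, ] |>
    dplyr::mutate(cluster_id = cl$cluster_id)
  ids <- sort(unique(cl$cluster_id))
  msas <- lapply(ids, function(id) {
    align_cluster(members$seq[members$cluster_id == id], mode = "anchored")
  })
  names(msas) <- as.character(ids)
  clusters <- purrr::map_dfr(ids, function(id) {
    sc <- motif_score(msas[[as.character(id)]])
    tibble::tibble(cluster_id = id,
                   n_members = sum(members$cluster_id == id),
                   score_s = sc$score_s, info_i = sc$info_i)
  })
  structure(list(clusters = clusters, members = members, msas = msas),
            class = "md_motif_clusters")
}

#' @export
print.md_motif_clusters <- function(x, ...) {
  cat("<md_motif_clusters>", nrow(x$clusters), "surviving cluster(s),",
      nrow(x$members), "windows\n")
  invisible(x)
}
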