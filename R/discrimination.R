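#' Gene x sample matrix of summed divergence statistics
#'
#' Each individual is represented as a vector over genes: entry (g, s) is the
#' sum of the chosen per-DMP statistic (`hd` or `bayes_diff`) over sample s's
#' DMPs lying inside gene g. Genes without DMPs in a sample contribute 0.
#'
#' @param dmps Combined DMP tibble (all samples; needs `sample_id`, `group`,
#'   `chrom`, `pos` and the statistic column).
#' @param genes Feature tibble.
#' @param statistic `"sum_hd"` (default) or `"sum_bayes_diff"`.
#' @param samples Optional sample universe tibble (`sample_id`, `group`).
#' @return Wide tibble: `gene_id` plus one numeric column per sample, with
#'   attributes `statistic` and `groups` (named vector sample -> group).
#' @export
gene_matrix <- function(dmps, genes, statistic = c("sum_hd", "sum_bayes_diff"),
                        samples = NULL) {
  statistic <- match.arg(statistic)
  value_col <- switch(statistic, sum_hd = "hd", sum_bayes_diff = "bayes_diff")
  if (nrow(dmps) > 0 && !value_col %in% names(dmps)) {
    stop_bad_arg("gene_matrix(): dmps lack the '%s' column", value_col)
  }
  if (is.null(samples)) {
    samples <- dplyr::distinct(dmps, .data$sample_id, .data$group)
  }
  sums <- if (nrow(dmps) == 0) {
    tibble::tibble(gene_id = character(0), sample_id = character(0),
                   value = numeric(0))
  } else {
    dplyr::bind_rows(lapply(split(seq_len(nrow(dmps)), dmps$chrom),
      function(idx) {
        chrom <- dmps$chrom[idx[1]]
        g <- genes[genes$chrom == chrom, , drop = FALSE]
        if (nrow(g) == 0) return(NULL)
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(start = dmps$pos[idx], width = 1L),
          IRanges::IRanges(start = g$start, end = g$end)
        )
        tibble::tibble(
          gene_id = g$feature_id[S4Vectors::subjectHits(ov)],
          sample_id = dmps$sample_id[idx[S4Vectors::queryHits(ov)]],
          value = dmps[[value_col]][idx[S4Vectors::queryHits(ov)]]
        )
      })) |>
      dplyr::group_by(.data$gene_id, .data$sample_id) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop")
  }
  wide <- tidyr::crossing(gene_id = genes$feature_id,
                          sample_id = samples$sample_id) |>
    dplyr::left_join(sums, by = c("gene_id", "sample_id")) |>
    dplyr::mutate(value = tidyr::replace_na(.data$value, 0)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") |>
    dplyr::arrange(.data$gene_id)
  attr(wide, "statistic") <- statistic
  attr(wide, "groups") <- setNames(samples$group, samples$sample_id)
  wide
}

# wide gene tibble -> genes x samples numeric matrix
as_gene_matrix <- function(gmat) {
  m <- as.matrix(gmat[, setdiff(names(gmat), "gene_id"), drop = FALSE])
  rownames(m) <- gmat$gene_id
  m
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the per-sample gene vectors with Ward's
#' minimum-variance linkage on Euclidean distances of the raw (uncentered)
#' vectors. Deterministic given input order.
#'
#' @param gmat Gene matrix from [gene_matrix()].
#' @param k Optional number of flat clusters to cut.
#' @return List of class `md_ward`: `hclust` (an [stats::hclust] object over
#'   samples) and, when `k` is given, `labels` (named cluster assignment).
#' @export
ward_cluster <- function(gmat, k = NULL) {
  x <- t(as_gene_matrix(gmat))
  if (nrow(x) < 2) stop_bad_arg("ward_cluster(): need >= 2 samples")
  if (!is.null(k) && k > nrow(x)) {
    stop_bad_arg("ward_cluster(): k = %d exceeds %d samples", k, nrow(x))
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  out <- list(hclust = hc,
              labels = if (!is.null(k)) stats::cutree(hc, k = k) else NULL,
              groups = attr(gmat, "groups"))
  class(out) <- "md_ward"
  out
}

#' @export
print.md_ward <- function(x, ...) {
  cat("<md_ward>", length(x$hclust$labels), "samples, Ward (ward.D2) linkage\n")
  invisible(x)
}

#' PCA with Guttman-Kaiser retention followed by LDA
#'
#' Samples are observations and genes variables. Genes are centered
#' (optionally scaled), principal components computed, and components
#' retained when each carries at least `var_min` (1%) of the sample variance
#' and together they accumulate at least `cum_target` (95%) of it (all
#' components if that is unattainable). A linear discriminant analysis is
#' then fitted on the retained component scores. For numerical stability the
#' LDA itself uses at most `n_samples - n_classes - 1` leading retained
#' components (the within-class scatter is otherwise singular); the PCA
#' retention `K` reported — and used by [pc_scores()] — follows the variance
#' rule alone.
#'
#' @param gmat Gene matrix from [gene_matrix()].
#' @param groups Optional named group vector (sample -> class); defaults to
#'   the matrix's `groups` attribute.
#' @param scale. Scale genes to unit variance before PCA (default `FALSE`:
#'   divergence sums share a scale).
#' @param var_min Per-component variance-fraction floor (default 0.01).
#' @param cum_target Cumulative variance target (default 0.95).
#' @return Object of class `md_pca_lda`: loadings, variance fractions,
#'   retained `K`, per-sample PC scores and discriminant coordinates, class
#'   centroids, and the underlying fits.
#' @export
pca_lda <- function(gmat, groups = NULL, scale. = FALSE,
                    var_min = 0.01, cum_target = 0.95) {
  x <- t(as_gene_matrix(gmat))
  groups <- groups %||% attr(gmat, "groups")[rownames(x)]
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_bad_arg("pca_lda(): need >= 2 classes")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop_bad_arg("pca_lda(): class '%s' has a single sample",
                 names(sizes)[which(sizes < 2)[1]])
  }
  if (scale.) {
    keep <- apply(x, 2, stats::sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  if (sum(apply(x, 2, stats::var)) == 0) {
    stop_bad_arg("pca_lda(): input matrix has no variance")
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = scale.)
  var_frac <- pca$sdev^2 / sum(pca$sdev^2)
  eligible <- cumsum(var_frac >= var_min) == seq_along(var_frac) &
    var_frac >= var_min
  n_eligible <- sum(eligible)
  cum <- cumsum(var_frac)
  k_reach <- which(cum[seq_len(max(n_eligible, 1))] >= cum_target)
  K <- if (n_eligible > 0 && length(k_reach) > 0) {
    min(k_reach)
  } else if (n_eligible > 0 && cum[n_eligible] < cum_target) {
    length(var_frac)  # target unattainable within eligible set: keep all
  } else {
    length(var_frac)
  }
  n <- nrow(x)
  k_lda <- max(1, min(K, n - nlevels(groups) - 1))
  scores <- pca$x[, seq_len(max(K, k_lda)), drop = FALSE]
  lda_fit <- MASS::lda(scores[, seq_len(k_lda), drop = FALSE],
                       grouping = groups)
  pred <- stats::predict(lda_fit)
  ld <- as.matrix(pred$x)
  disc <- tibble::tibble(sample_id = rownames(x), group = as.character(groups),
                         tibble::as_tibble(ld))
  centroids <- disc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("LD"), mean),
                     .groups = "drop")
  out <- list(
    loadings = pca$rotation,
    var_frac = var_frac,
    K = K,
    k_lda = k_lda,
    center = pca$center,
    scale = if (scale.) pca$scale else NULL,
    scores = tibble::tibble(sample_id = rownames(x),
                            group = as.character(groups),
                            tibble::as_tibble(pca$x)),
    lda = lda_fit,
    discriminants = disc,
    centroids = centroids,
    assigned = as.character(pred$class)
  )
  class(out) <- "md_pca_lda"
  out
}

#' @export
print.md_pca_lda <- function(x, ...) {
  cat("<md_pca_lda> K =", x$K, "retained components (",
      round(100 * sum(x$var_frac[seq_len(x$K)]), 1), "% variance ), LDA on",
      x$k_lda, "\n")
  invisible(x)
}

#' Project new samples through a fitted PCA-LDA model
#'
#' @param object `md_pca_lda` fit.
#' @param gmat Gene matrix of the new samples (same genes).
#' @param ... Unused.
#' @return Tibble with predicted class and discriminant coordinates.
#' @export
predict.md_pca_lda <- function(object, gmat, ...) {
  x <- t(as_gene_matrix(gmat))
  x <- x[, names(object$center), drop = FALSE]
  xc <- sweep(x, 2, object$center)
  if (!is.null(object$scale)) xc <- sweep(xc, 2, object$scale, "/")
  sc <- xc %*% object$loadings[, seq_len(object$k_lda), drop = FALSE]
  pred <- stats::predict(object$lda, sc)
  tibble::tibble(sample_id = rownames(x),
                 predicted = as.character(pred$class),
                 tibble::as_tibble(as.matrix(pred$x)))
}

#' Per-gene PC scores over the retained components
#'
#' The PC score of a gene is the Euclidean norm of its loading vector across
#' the retained components. Because loadings are orthonormal per component,
#' the squared scores sum to the retained component count K, and a gene's
#' squared score measures the fraction of retained variance it explains.
#'
#' @param model `md_pca_lda` fit from [pca_lda()].
#' @return Tibble `gene_id`, `pc_score`, sorted by decreasing score.
#' @export
pc_scores <- function(model) {
  stopifnot(inherits(model, "md_pca_lda"))
  L <- model$loadings[, seq_len(model$K), drop = FALSE]
  tibble::tibble(gene_id = rownames(L),
                 pc_score = sqrt(rowSums(L^2))) |>
    dplyr::arrange(dplyr::desc(.data$pc_score))
}

#' Thresholded gene correlation network
#'
#' Pairwise correlations between gene rows across samples; an edge is
#' retained iff |correlation| >= `tau` (or the signed correlation >= `tau`
#' with `signed = TRUE`). Constant gene rows, whose correlation is
#' undefined, are excluded with a warning.
#'
#' @param gmat Gene matrix from [gene_matrix()].
#' @param tau Correlation threshold (default 0.5).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param signed Threshold the signed rather than the absolute correlation.
#' @return Object of class `md_network`: `edges` (tibble `gene_a`, `gene_b`,
#'   `correlation`), `nodes` (tibble `gene_id`, `degree`),
#'   `connected_genes` (count of nodes with degree >= 1), `tau`, `method`.
#' @export
correlation_network <- function(gmat, tau = 0.5,
                                method = c("spearman", "pearson"),
                                signed = FALSE) {
  method <- match.arg(method)
  x <- as_gene_matrix(gmat)
  if (ncol(x) < 4) {
    stop_bad_arg("correlation_network(): need >= 4 samples, got %d", ncol(x))
  }
  constant <- apply(x, 1, function(r) length(unique(r)) == 1)
  if (any(constant)) {
    warn(sprintf("correlation_network(): excluding %d constant gene row(s)",
                 sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  genes <- rownames(x)
  edges <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                          correlation = numeric(0))
  if (nrow(x) >= 2) {
    cm <- suppressWarnings(stats::cor(t(x), method = method))
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    val <- cm[ut]
    keep <- if (signed) val >= tau else abs(val) >= tau
    keep[is.na(keep)] <- FALSE
    edges <- tibble::tibble(gene_a = genes[ut[keep, 1]],
                            gene_b = genes[ut[keep, 2]],
                            correlation = val[keep]) |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  }
  degree <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  nodes <- tibble::tibble(gene_id = genes, degree = as.integer(degree))
  out <- list(edges = edges, nodes = nodes,
              connected_genes = sum(nodes$degree >= 1),
              tau = tau, method = method, signed = signed)
  class(out) <- "md_network"
  out
}

#' @export
print.md_network <- function(x, ...) {
  cat("<md_network>", nrow(x$edges), "edges;", x$connected_genes,
      "connected genes at |", x$method, "| >=", x$tau, "\n")
  invisible(x)
}

#' Fisher exact test of overlap between two gene sets
#'
#' Two-sided Fisher exact test on the 2x2 table
#' \[\[|A∩B|, |A\\B|\], \[|B\\A|, |universe \\ (A∪B)|\]\].
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all candidate IDs.
#' @return One-row tibble: `overlap`, `n_a`, `n_b`, `n_universe`,
#'   `odds_ratio`, `p_value`.
#' @export
set_overlap_fisher <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop_bad_arg("set_overlap_fisher(): sets must be contained in universe")
  }
  ab <- length(intersect(set_a, set_b))
  a_only <- length(setdiff(set_a, set_b))
  b_only <- length(setdiff(set_b, set_a))
  neither <- length(universe) - ab - a_only - b_only
  ft <- stats::fisher.test(matrix(c(ab, a_only, b_only, neither), nrow = 2,
                                  byrow = TRUE))
  tibble::tibble(overlap = ab, n_a = length(set_a), n_b = length(set_b),
                 n_universe = length(universe),
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
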