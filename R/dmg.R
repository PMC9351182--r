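#' Count DMPs per gene and sample
#'
#' A DMP is counted for a gene iff its position lies within the annotated
#' interval `[start, end]` (1-based inclusive); a DMP inside overlapping
#' genes counts for each of them. The result is completed with explicit
#' zeros for every gene x sample combination.
#'
#' @param dmps DMP tibble (needs `sample_id`, `group`, `chrom`, `pos`).
#'   May be empty.
#' @param genes Feature tibble (`feature_id`, `chrom`, `start`, `end`).
#' @param samples Optional tibble with `sample_id`, `group` defining the full
#'   sample universe (so samples without any DMP get zero rows). Defaults to
#'   the samples present in `dmps`.
#' @return Long tibble: `gene_id`, `length_bp`, `sample_id`, `group`,
#'   `n_dmps`.
#' @export
count_dmps_per_gene <- function(dmps, genes, samples = NULL) {
  if (any(genes$start > genes$end)) {
    stop_bad_arg("count_dmps_per_gene(): degenerate gene interval")
  }
  if (is.null(samples)) {
    samples <- dplyr::distinct(dmps, .data$sample_id, .data$group)
  }
  gene_tbl <- tibble::tibble(
    gene_id = genes$feature_id,
    length_bp = genes$end - genes$start + 1L
  )
  if (nrow(dmps) == 0 || nrow(samples) == 0) {
    return(tidyr::crossing(gene_tbl, samples) |>
             dplyr::mutate(n_dmps = 0L) |>
             dplyr::arrange(.data$gene_id, .data$sample_id))
  }
  hits <- dplyr::bind_rows(lapply(split(seq_len(nrow(dmps)), dmps$chrom),
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
        sample_id = dmps$sample_id[idx[S4Vectors::queryHits(ov)]]
      )
    }))
  counted <- hits |>
    dplyr::count(.data$gene_id, .data$sample_id, name = "n_dmps")
  tidyr::crossing(gene_tbl, samples) |>
    dplyr::left_join(counted, by = c("gene_id", "sample_id")) |>
    dplyr::mutate(n_dmps = as.integer(tidyr::replace_na(.data$n_dmps, 0L))) |>
    dplyr::arrange(.data$gene_id, .data$sample_id)
}

#' Test genes for differential methylation (DMG calling)
#'
#' Applies the locus filters first — at least `min_dmps` DMPs in the
#' treatment group(s) and a DMP density of at least `min_density` per 10 kbp
#' of annotated gene length — then, for each surviving gene, compares group
#' DMP counts with a GLM likelihood-ratio test: the count ~ group model
#' against the intercept-only model, LRT statistic \eqn{2(\ell_1 - \ell_0)},
#' p-value from a chi-square with (groups - 1) degrees of freedom,
#' Benjamini-Hochberg adjustment across all tested genes. The fold change is
#' `log2((mean_trt + 0.5) / (mean_ctl + 0.5))`. A gene is a DMG iff it passes
#' the filters, `log2fc > lfc_min`, and `p_adj < fdr`.
#'
#' The default count family is negative binomial (genewise dispersion by
#' maximum likelihood); genes where the NB fit fails fall back to Poisson
#' with a warning.
#'
#' @param gene_counts Output of [count_dmps_per_gene()].
#' @param control Group label of the control samples (default `"WT"`).
#' @param min_dmps Minimum total treatment DMPs (default 7).
#' @param min_density Minimum DMPs per 10 kbp (default 3).
#' @param lfc_min Minimum log2 fold change (default 1).
#' @param fdr BH-adjusted p-value threshold (default 0.05).
#' @param family `"nb"` (negative binomial, default) or `"poisson"`.
#' @param scope How "at least `min_dmps`" is counted: total over treatment
#'   replicates (default) or satisfied by any single sample.
#' @return Tibble of tested genes with `gene_id`, `length_bp`,
#'   `total_treatment_dmps`, `density_per_10kb`, `log2fc`, `lrt_stat`,
#'   `p_value`, `p_adj`, `family_used`, `is_dmg`.
#' @export
test_dmgs <- function(gene_counts, control = "WT",
                      min_dmps = 7, min_density = 3,
                      lfc_min = 1, fdr = 0.05,
                      family = c("nb", "poisson"),
                      scope = c("treatment-total", "any-sample")) {
  family <- match.arg(family)
  scope <- match.arg(scope)
  groups <- unique(gene_counts$group)
  if (!control %in% groups) {
    stop_bad_arg("test_dmgs(): control group '%s' absent from counts", control)
  }
  n_per_group <- gene_counts |>
    dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$group)
  if (any(n_per_group$n < 2)) {
    stop_bad_arg("test_dmgs(): every group needs >= 2 samples")
  }
  trt <- gene_counts |> dplyr::filter(.data$group != control)
  filt <- trt |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      length_bp = .data$length_bp[1],
      total_treatment_dmps = sum(.data$n_dmps),
      max_sample_dmps = max(.data$n_dmps),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      density_per_10kb = .data$total_treatment_dmps / .data$length_bp * 1e4,
      count_ok = if (scope == "treatment-total") {
        .data$total_treatment_dmps >= min_dmps
      } else {
        .data$max_sample_dmps >= min_dmps
      },
      pass_filters = .data$count_ok & .data$density_per_10kb >= min_density
    )
  tested_ids <- filt$gene_id[filt$pass_filters]
  if (length(tested_ids) == 0) {
    out <- filt[0, ] |>
      dplyr::mutate(log2fc = numeric(0), lrt_stat = numeric(0),
                    p_value = numeric(0), p_adj = numeric(0),
                    family_used = character(0), is_dmg = logical(0))
    return(dplyr::select(out, -"count_ok", -"pass_filters",
                         -"max_sample_dmps"))
  }
  df_lrt <- length(groups) - 1
  n_fallback <- 0L
  fits <- lapply(tested_ids, function(g) {
    d <- gene_counts[gene_counts$gene_id == g, ]
    d$group <- factor(d$group)
    mean_trt <- mean(d$n_dmps[d$group != control])
    mean_ctl <- mean(d$n_dmps[d$group == control])
    fam_used <- family
    ll <- NULL
    if (family == "nb") {
      ll <- tryCatch({
        full <- suppressWarnings(MASS::glm.nb(n_dmps ~ group, data = d))
        null <- suppressWarnings(
          MASS::glm.nb(n_dmps ~ 1, data = d, init.theta = full$theta))
        c(as.numeric(stats::logLik(full)), as.numeric(stats::logLik(null)))
      }, error = function(e) NULL)
      if (is.null(ll)) {
        fam_used <- "poisson"
        n_fallback <<- n_fallback + 1L
      }
    }
    if (is.null(ll)) {
      full <- suppressWarnings(
        stats::glm(n_dmps ~ group, data = d, family = stats::poisson()))
      null <- suppressWarnings(
        stats::glm(n_dmps ~ 1, data = d, family = stats::poisson()))
      ll <- c(as.numeric(stats::logLik(full)), as.numeric(stats::logLik(null)))
    }
    lrt <- max(0, 2 * (ll[1] - ll[2]))
    tibble::tibble(
      gene_id = g,
      log2fc = log2((mean_trt + 0.5) / (mean_ctl + 0.5)),
      lrt_stat = lrt,
      p_value = stats::pchisq(lrt, df = df_lrt, lower.tail = FALSE),
      family_used = fam_used
    )
  })
  if (n_fallback > 0) {
    warn(sprintf("test_dmgs(): NB dispersion fit failed for %d gene(s); used Poisson",
                 n_fallback))
  }
  res <- dplyr::bind_rows(fits) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, method = "BH"))
  filt |>
    dplyr::filter(.data$pass_filters) |>
    dplyr::select(-"count_ok", -"pass_filters", -"max_sample_dmps") |>
    dplyr::left_join(res, by = "gene_id") |>
    dplyr::mutate(is_dmg = .data$log2fc > lfc_min & .data$p_adj < fdr) |>
    dplyr::relocate("p_adj", .after = "p_value") |>
    dplyr::arrange(.data$gene_id)
}

#' Fraction of genes within a window of any feature
#'
#' Fraction of `genes` whose interval, extended by `window_bp` on both sides,
#' intersects at least one feature (TEs or sRNA clusters). This is the
#' proximity-enrichment statistic used to relate DMGs to RdDM-associated
#' annotation.
#'
#' @param genes Feature tibble of the gene set.
#' @param features Feature tibble (e.g. TEs).
#' @param window_bp Flank width (default 2000).
#' @return A single numeric fraction in \[0, 1\].
#' @export
proximity_fraction <- function(genes, features, window_bp = 2000) {
  if (nrow(features) == 0) stop_bad_arg("proximity_fraction(): empty features")
  if (nrow(genes) == 0) return(NA_real_)
  near <- vapply(seq_len(nrow(genes)), function(i) {
    f <- features[features$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(f) == 0) return(FALSE)
    s <- max(1, genes$start[i] - window_bp)
    e <- genes$end[i] + window_bp
    any(f$start <= e & f$end >= s)
  }, logical(1))
  mean(near)
}

#' Intersection structure of named DMG sets
#'
#' Computes every Venn cell (count of elements belonging to exactly a given
#' combination of sets) and all pairwise Jaccard indices, in deterministic
#' order.
#'
#' @param sets Named list (>= 2) of character vectors of gene IDs.
#' @return List with `venn` (tibble: one logical column per set, plus
#'   `count`) and `jaccard` (tibble: `set_a`, `set_b`, `intersection`,
#'   `union`, `jaccard`).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) || any(names(sets) == "")) {
    stop_bad_arg("overlap_sets(): need >= 2 named sets")
  }
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  venn <- tibble::as_tibble(member) |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "count") |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
  pairs <- utils::combn(names(sets), 2)
  jaccard <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1, j]]]
    b <- sets[[pairs[2, j]]]
    i <- length(intersect(a, b))
    u <- length(union(a, b))
    tibble::tibble(set_a = pairs[1, j], set_b = pairs[2, j],
                   intersection = i, union = u,
                   jaccard = if (u == 0) NA_real_ else i / u)
  })
  list(venn = venn, jaccard = jaccard)
}
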