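#' Stage parameters for the end-to-end pipeline
#'
#' Every threshold defaults to its canonical analysis value: level-difference
#' gate 0.20, cutoff alpha 0.05, at least 7 DMPs and 3 per 10 kbp for DMGs,
#' log2 fold change 1, FDR 0.05, 14-bp windows anchored at nucleotide 7,
#' DMPs recurrent in at least 3 samples, 100 motif clusters with minimum
#' size 10, k-means with 3 clusters and 300 iterations, correlation
#' threshold 0.5.
#'
#' `cutoff_method` defaults to `"fdr"`: the pipeline estimates the optimal
#' divergence cutpoint from the control-derived null *and* the treatment
#' divergences in the signal-detection sense, targeting the empirical
#' false-discovery fraction of the selected sites. Youden's balanced
#' cutpoint and the pure null-quantile rule remain available; with a rare
#' signal contaminating a null-dominated mixture the FDR cutpoint is the
#' stable choice (see [fit_null_cutoff()]).
#' `motif_k = NULL` scales the cluster count to the data as
#' `max(2, ceiling(n_windows / 25))` — the fixed 100-cluster default
#' presumes thousands of candidate windows.
#'
#' @param min_coverage,tv_min,alpha,cutoff_method,hd Divergence stage.
#' @param min_dmps,min_density,lfc_min,fdr,family DMG stage.
#' @param statistic,tau,cor_method Discrimination stage.
#' @param kmeans_k,kmeans_iter Hub stage.
#' @param width,anchor_offset,min_samples,motif_k,min_cluster,distance
#'   Motif stage.
#' @param n_sims,dirichlet_method Monte-Carlo stage.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(min_coverage = 4, tv_min = 0.20, alpha = 0.05,
                            cutoff_method = "fdr", hd = "weighted",
                            min_dmps = 7, min_density = 3, lfc_min = 1,
                            fdr = 0.05, family = "nb",
                            statistic = "sum_hd", tau = 0.5,
                            cor_method = "spearman",
                            kmeans_k = 3, kmeans_iter = 300,
                            width = 14, anchor_offset = 7, min_samples = 3,
                            motif_k = NULL, min_cluster = 10,
                            distance = "raw",
                            n_sims = 999, dirichlet_method = "moment") {
  as.list(environment())
}

# Null divergence of one control replicate: compared against the centroid
# of the remaining controls (jackknife), so a control is never scored
# against a pool containing its own counts (which deflates the null). No
# coverage correction is needed for the weighted HD: its coverage factor
# cancels the sampling variance of the proportions, so the null expectation
# is coverage-invariant and the leave-one-out comparison already lives on
# the treatment-vs-full-centroid scale. Falls back to the full centroid
# when there is a single control replicate.
control_null_divergence <- function(sample, other_controls, full_centroid,
                                    hd = "weighted") {
  if (nrow(other_controls) == 0) {
    warn("control_null_divergence(): single control replicate; null uses the pooled centroid itself")
    return(methylation_divergence(sample, full_centroid, hd = hd))
  }
  methylation_divergence(sample, pool_reference(other_controls), hd = hd)
}

#' Group-level (replicated) DMP sites
#'
#' Collapses per-sample DMP calls to treatment-associated sites: a site is a
#' group-level DMP for a treatment state when it is called in more than
#' `min_fraction` of that state's replicates. Requiring replicated evidence
#' suppresses the single-replicate false calls that survive any per-sample
#' divergence cutoff.
#'
#' @param dmps Combined per-sample DMP tibble (`sample_id`, `group`,
#'   `chrom`, `pos`, `strand`).
#' @param samples Tibble `sample_id`, `group` giving the replicate universe.
#' @param control Control group label (excluded).
#' @param min_fraction Fraction of a state's replicates that must carry the
#'   call (default 0.5, i.e. a strict majority).
#' @return Tibble `group`, `chrom`, `pos`, `strand`, `n_called`, `n_reps`.
#' @export
replicated_dmp_sites <- function(dmps, samples, control,
                                 min_fraction = 0.5) {
  reps <- samples |>
    dplyr::filter(.data$group != control) |>
    dplyr::count(.data$group, name = "n_reps")
  dmps |>
    dplyr::filter(.data$group != control) |>
    dplyr::distinct(.data$group, .data$sample_id, .data$chrom, .data$pos,
                    .data$strand) |>
    dplyr::count(.data$group, .data$chrom, .data$pos, .data$strand,
                 name = "n_called") |>
    dplyr::inner_join(reps, by = "group") |>
    dplyr::filter(.data$n_called > min_fraction * .data$n_reps) |>
    dplyr::arrange(.data$group, .data$chrom, .data$pos, .data$strand)
}

#' Run the full methylome-decoding pipeline on a study
#'
#' Executes the stages in order — reference pooling, divergence and cutoff
#' estimation, DMP calling for every sample, DMG testing, discrimination
#' (gene matrix, Ward clustering, PCA-LDA, PC scores, correlation network),
#' hub selection, motif extraction/clustering/scoring, and the Monte-Carlo
#' randomness test — and returns all stage outputs plus a machine-readable
#' manifest (parameters, seeds, input hash, per-stage record counts).
#' Deterministic given the study and `seed`: stage sub-seeds are derived
#' from `seed` by a fixed offset rule.
#'
#' @param study `md_study` from [generate_study()], or a list with elements
#'   `meth` (long tidy count table with `sample_id`, `group`), `genes`
#'   (feature tibble), and `genome` (named sequences; optional — without it
#'   the motif stage is skipped).
#' @param params [pipeline_params()] list.
#' @param control Control group label; defaults to the first group.
#' @param seed Integer master seed (default 1).
#' @return List of class `md_run` with elements `cutoff`, `dmps`, `dmg`,
#'   `gene_matrix`, `ward`, `pca_lda`, `pc_scores`, `network`, `hubs`,
#'   `windows`, `motif`, and `manifest`.
#' @export
run_pipeline <- function(study, params = pipeline_params(), control = NULL,
                         seed = 1L) {
  t0 <- Sys.time()
  meth <- dplyr::filter(study$meth,
                        .data$meth + .data$unmeth >= params$min_coverage)
  groups <- unique(meth$group)
  control <- control %||% groups[1]
  samples <- dplyr::distinct(meth, .data$sample_id, .data$group)
  message(sprintf("[divergence] %d samples, %d covered site records",
                  nrow(samples), nrow(meth)))

  centroid <- pool_reference(dplyr::filter(meth, .data$group == control))
  divs <- lapply(samples$sample_id, function(s) {
    methylation_divergence(dplyr::filter(meth, .data$sample_id == s),
                           centroid, hd = params$hd)
  })
  names(divs) <- samples$sample_id
  # the cutoff is estimated on the candidate sites — those already passing
  # the level-difference gate — matching the two-step selection: candidates
  # by |tv| > tv_min, then divergence filtering by the estimated cutpoint.
  # Control null divergences come from a leave-one-out jackknife (each
  # control vs the centroid of the others): scoring a control against a
  # pool containing its own counts deflates the null.
  candidate_hd <- function(d) d$hd[abs(d$tv) > params$tv_min]
  ctl_ids <- samples$sample_id[samples$group == control]
  null_hd <- unlist(lapply(ctl_ids, function(s) {
    candidate_hd(control_null_divergence(
      dplyr::filter(meth, .data$sample_id == s),
      dplyr::filter(meth, .data$group == control, .data$sample_id != s),
      centroid, hd = params$hd))
  }), use.names = FALSE)
  trt_hd <- unlist(lapply(divs[samples$sample_id[samples$group != control]],
                          candidate_hd), use.names = FALSE)
  cutoff <- if (length(null_hd) < 50 || all(null_hd == 0) ||
                length(trt_hd) == 0) {
    # too few candidate sites to support a null fit (e.g. a degenerate
    # level gate): the level-difference filter stands alone
    warn("run_pipeline(): insufficient candidate sites to fit a divergence cutoff; using the level gate alone")
    structure(list(method = "none", alpha = params$alpha, cutoff = 0,
                   n_null = length(null_hd)), class = "md_cutoff")
  } else {
    fit_null_cutoff(null_hd, method = params$cutoff_method,
                    alpha = params$alpha, treatment_hd = trt_hd)
  }
  dmps <- dplyr::bind_rows(lapply(divs, function(d) {
    d |>
      dplyr::filter(abs(.data$tv) > params$tv_min,
                    .data$hd >= cutoff$cutoff) |>
      dplyr::mutate(direction = as.character(ifelse(.data$tv > 0, "hyper", "hypo")))
  }))
  dmp_sites <- replicated_dmp_sites(dmps, samples, control)
  message(sprintf("[dmps] cutoff %.4g (%s); %d DMP records; %d replicated sites",
                  cutoff$cutoff, cutoff$method, nrow(dmps), nrow(dmp_sites)))

  gene_counts <- count_dmps_per_gene(dmps, study$genes, samples = samples)
  dmg <- test_dmgs(gene_counts, control = control,
                   min_dmps = params$min_dmps,
                   min_density = params$min_density,
                   lfc_min = params$lfc_min, fdr = params$fdr,
                   family = params$family)
  message(sprintf("[dmgs] %d genes tested, %d DMGs", nrow(dmg),
                  sum(dmg$is_dmg)))

  gmat <- gene_matrix(dmps, study$genes, statistic = params$statistic,
                      samples = samples)
  ward <- ward_cluster(gmat, k = length(groups))
  sizes <- table(samples$group)
  pca <- if (length(groups) >= 2 && all(sizes >= 2)) {
    tryCatch(pca_lda(gmat), error = function(e) {
      warn(sprintf("run_pipeline(): PCA-LDA skipped (%s)", conditionMessage(e)))
      NULL
    })
  } else NULL
  scores <- if (!is.null(pca)) pc_scores(pca) else NULL

  dmg_ids <- dmg$gene_id[dmg$is_dmg]
  network <- NULL
  hubs <- NULL
  if (length(dmg_ids) >= 2 && nrow(samples) >= 4) {
    sub <- gmat[gmat$gene_id %in% dmg_ids, , drop = FALSE]
    attr(sub, "groups") <- attr(gmat, "groups")
    network <- suppressWarnings(
      correlation_network(sub, tau = params$tau, method = params$cor_method))
    if (nrow(network$edges) > 0 &&
        network$connected_genes >= params$kmeans_k) {
      attrs <- suppressWarnings(node_attributes(network$edges))
      hubs <- select_hubs(attrs, k = params$kmeans_k,
                          iterations = params$kmeans_iter,
                          seed = derive_seed(seed, 4L))
    }
  }
  message(sprintf("[network] %s edges, %s hub(s)",
                  if (is.null(network)) 0 else nrow(network$edges),
                  if (is.null(hubs)) 0 else length(hubs$hubs)))

  windows <- NULL
  motif <- NULL
  if (!is.null(study$genome)) {
    trt_dmps <- dplyr::filter(dmps, .data$group != control)
    windows <- extract_windows(trt_dmps, study$genome,
                               min_samples = params$min_samples,
                               width = params$width,
                               anchor_offset = params$anchor_offset)
    if (nrow(windows) >= max(2, params$min_cluster)) {
      k <- params$motif_k %||% max(2, ceiling(nrow(windows) / 25))
      clusters <- motif_clusters(windows, k = k,
                                 min_size = params$min_cluster,
                                 distance = params$distance)
      motif <- if (nrow(clusters$clusters) > 0) {
        tested <- test_motif_clusters(clusters, n_sims = params$n_sims,
                                      seed = derive_seed(seed, 6L),
                                      method = params$dirichlet_method)
        list(clusters = clusters, summary = tested,
             model = attr(tested, "model"))
      } else {
        list(clusters = clusters, summary = clusters$clusters, model = NULL)
      }
    }
  }
  message(sprintf("[motifs] %d candidate windows, %d surviving cluster(s)",
                  if (is.null(windows)) 0 else nrow(windows),
                  if (is.null(motif)) 0 else nrow(motif$summary)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("methylodecode")),
    seed = seed,
    params = params,
    control = control,
    input_hash = rlang::hash(study$meth),
    n_samples = nrow(samples),
    n_site_records = nrow(meth),
    cutoff = cutoff$cutoff,
    n_dmps = nrow(dmps),
    n_replicated_sites = nrow(dmp_sites),
    n_genes_tested = nrow(dmg),
    n_dmgs = sum(dmg$is_dmg),
    n_network_edges = if (is.null(network)) 0L else nrow(network$edges),
    n_hubs = if (is.null(hubs)) 0L else length(hubs$hubs),
    n_windows = if (is.null(windows)) 0L else nrow(windows),
    n_motif_clusters = if (is.null(motif)) 0L else nrow(motif$summary),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(centroid = centroid, cutoff = cutoff, dmps = dmps,
                 dmp_sites = dmp_sites,
                 gene_counts = gene_counts, dmg = dmg,
                 gene_matrix = gmat, ward = ward, pca_lda = pca,
                 pc_scores = scores, network = network, hubs = hubs,
                 windows = windows, motif = motif, manifest = manifest),
            class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  m <- x$manifest
  cat("<md_run>\n",
      " samples:", m$n_samples, "\n",
      " DMP records:", m$n_dmps, " (cutoff", signif(m$cutoff, 4), ")\n",
      " DMGs:", m$n_dmgs, "of", m$n_genes_tested, "tested\n",
      " network edges:", m$n_network_edges, " hubs:", m$n_hubs, "\n",
      " motif windows:", m$n_windows, " clusters:", m$n_motif_clusters, "\n")
  invisible(x)
}

#' Write the result tables of a pipeline run to a directory
#'
#' @param run `md_run` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(run$dmps, file.path(dir, "dmps.tsv"))
  write_results_table(run$dmg, file.path(dir, "dmgs.tsv"))
  if (!is.null(run$pc_scores)) {
    write_results_table(run$pc_scores, file.path(dir, "pc_scores.tsv"))
  }
  if (!is.null(run$motif)) {
    write_results_table(run$motif$summary, file.path(dir, "motif_clusters.tsv"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
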