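#' Configuration for a synthetic multi-state methylome study
#'
#' Bundles every knob of the ground-truthed simulator. The defaults define
#' the reference study conditions used throughout the package's tests: a
#' 300 kb chromosome at GC 0.36, 120 genes, wild type plus one treatment
#' state with three replicates each, negative-binomial coverage (mean 30,
#' dispersion 5), context-specific background methylation (CG bimodal-high,
#' CHG intermediate, CHH low), and 20 planted differentially methylated
#' genes carrying 10 DMPs each with a +0.6 methylation level shift, every
#' planted DMP sitting at position 7 of a planted 14-bp motif copy.
#'
#' @param genome_length Chromosome length in bp.
#' @param gc GC content of the background sequence.
#' @param n_genes,n_tes,n_srna Number of genes / TEs / sRNA clusters.
#' @param states Named integer vector of replicate counts; the first entry
#'   is the control group.
#' @param coverage_mean,coverage_disp Negative-binomial coverage mean and
#'   dispersion (size) per site and sample.
#' @param rep_precision Beta precision of replicate-level biological noise
#'   around each site's true methylation level.
#' @param context_baseline Per-context Beta mixture for background
#'   methylation levels: a list of lists with weights `w` and shape vectors
#'   `a`, `b`.
#' @param n_planted_genes Differentially methylated genes planted per
#'   treatment state (0 disables planting: a null study).
#' @param dmps_per_gene Planted DMPs (= motif copies) per planted gene.
#' @param effect Methylation level shift at planted DMPs (baselines are held
#'   low there, so the level difference exceeds 0.2 by construction).
#' @param shared_fraction With several treatment states, the fraction of
#'   each state's planted genes drawn from a common core set (mirroring a
#'   shared-core/state-specific design).
#' @param motif_consensus Character vector of 14-mer consensi written at
#'   planted DMPs (character 7 must be C in each). Planted genes are
#'   assigned to consensi round-robin, so the default four motifs emulate a
#'   candidate-window set mixing several motif families, as clustering-based
#'   motif discovery presumes.
#' @param mutation_rate Per-base mutation probability of each planted motif
#'   copy (the anchor C is never mutated).
#' @param seed Mandatory integer seed; the study is a pure function of the
#'   configuration.
#' @return A list of class `md_sim_config`.
#' @export
sim_config <- function(genome_length = 3e5, gc = 0.36,
                       n_genes = 120, n_tes = 60, n_srna = 60,
                       states = c(WT = 3, state1 = 3),
                       coverage_mean = 30, coverage_disp = 5,
                       rep_precision = 100,
                       context_baseline = list(
                         CG = list(w = c(0.55, 0.45), a = c(8, 1.5),
                                   b = c(2, 8)),
                         CHG = list(w = 1, a = 1.2, b = 4),
                         CHH = list(w = 1, a = 0.8, b = 8)
                       ),
                       n_planted_genes = 20, dmps_per_gene = 10,
                       effect = 0.6, shared_fraction = 0.6,
                       motif_consensus = c("AGCTCTCGCATCGC",
                                           "CTGAAGCAGTGGTT",
                                           "TCTCGACCAGATAA",
                                           "GAAGTCCTTCCACG"),
                       mutation_rate = 0.1,
                       seed) {
  if (missing(seed)) stop_bad_arg("sim_config(): a seed is mandatory")
  if (is.null(names(states)) || any(names(states) == "")) {
    stop_bad_arg("sim_config(): states must be a named replicate-count vector")
  }
  if (effect < 0 || effect > 1) {
    stop_bad_arg("sim_config(): effect must be in [0, 1]")
  }
  if (any(nchar(motif_consensus) != 14) ||
      any(substr(motif_consensus, 7, 7) != "C")) {
    stop_bad_arg("sim_config(): every motif consensus must be a 14-mer with C at position 7")
  }
  structure(as.list(environment()), class = "md_sim_config")
}

#' Four-state study preset
#'
#' A preset mirroring a four-state epigenetic design: wild type plus four
#' treatment states whose planted gene sets share a common core (controlled
#' by `shared_fraction`) plus state-specific additions, so set-overlap
#' analyses have structured truth to recover.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @param seed Integer seed.
#' @return `md_sim_config`.
#' @export
preset_four_states <- function(..., seed) {
  sim_config(states = c(WT = 3, mutant = 3, memory = 3, graft = 3, epi = 3),
             shared_fraction = 0.6, seed = seed, ...)
}

sample_mixture_beta <- function(n, spec) {
  comp <- sample.int(length(spec$w), n, replace = TRUE, prob = spec$w)
  stats::rbeta(n, spec$a[comp], spec$b[comp])
}

#' Generate a ground-truthed synthetic methylome study
#'
#' Builds, deterministically from the configuration seed: a random genome at
#' the configured GC content; non-overlapping gene annotations plus TE and
#' sRNA-cluster intervals (a fraction placed within 2 kb of genes); mutated
#' copies of the motif consensus written into each planted gene with the
#' anchor cytosine at consensus position 7; the full per-strand cytosine
#' site list with context and trinucleotide derived from the (post-planting)
#' sequence; and per-sample methylated/unmethylated counts with
#' negative-binomial coverage, Beta replicate noise, and the planted
#' treatment level shifts (baselines at planted sites are held in
#' \[0.05, 0.15\] so the shifted level difference exceeds the 20% gate by
#' construction).
#'
#' @param config `md_sim_config` from [sim_config()].
#' @return List of class `md_study`: `genome` ([Biostrings::DNAStringSet]),
#'   `genes`, `tes`, `srna` (feature tibbles), `meth` (long tidy count
#'   table over all samples, including zero-coverage rows), `truth` (list:
#'   `dmps`, `dmgs`, `motif`), `samples`, `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "md_sim_config"))
  with_local_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  L <- cfg$genome_length
  base_probs <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
                  T = (1 - cfg$gc) / 2)
  genome <- sample(DNA_BASES, L, replace = TRUE, prob = base_probs)

  # --- annotations ----------------------------------------------------
  slot <- floor(L / cfg$n_genes)
  if (slot < 600) stop_bad_arg("generate_study(): genome too short for n_genes")
  gene_len <- pmin(slot - 200L,
                   as.integer(round(stats::runif(cfg$n_genes, 1200, 2100))))
  gene_start <- as.integer((seq_len(cfg$n_genes) - 1) * slot + 1 +
    floor(stats::runif(cfg$n_genes, 50, pmax(51, slot - gene_len - 50))))
  genes <- tibble::tibble(
    feature_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
    chrom = "chr1", start = gene_start,
    end = gene_start + gene_len - 1L,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    kind = "gene"
  )
  place_features <- function(n, len_range, near_frac, prefix, kind) {
    len <- as.integer(round(stats::runif(n, len_range[1], len_range[2])))
    near <- stats::runif(n) < near_frac
    start <- integer(n)
    anchor_gene <- sample.int(nrow(genes), n, replace = TRUE)
    start[near] <- pmin(L - len[near],
                        genes$end[anchor_gene[near]] +
                          as.integer(stats::runif(sum(near), 50, 1800)))
    start[!near] <- as.integer(stats::runif(sum(!near), 1, L - max(len)))
    tibble::tibble(
      feature_id = sprintf("%s_%03d", prefix, seq_len(n)),
      chrom = "chr1", start = pmax(1L, start),
      end = pmax(1L, start) + len - 1L,
      strand = "+", kind = kind
    )
  }
  tes <- place_features(cfg$n_tes, c(200, 800), 0.5, "TE", "TE")
  srna <- place_features(cfg$n_srna, c(100, 300), 0.6, "sRNA", "sRNA_cluster")

  # --- planted DMGs, DMPs, motif copies -------------------------------
  state_names <- names(cfg$states)
  control <- state_names[1]
  trt_states <- state_names[-1]
  planted <- tibble::tibble(state = character(0), gene_id = character(0))
  placements <- tibble::tibble(gene_id = character(0), anchor_pos = integer(0))
  if (cfg$n_planted_genes > 0 && cfg$effect > 0 && length(trt_states) > 0) {
    n_core <- if (length(trt_states) > 1) {
      round(cfg$shared_fraction * cfg$n_planted_genes)
    } else cfg$n_planted_genes
    n_specific <- cfg$n_planted_genes - n_core
    needed <- n_core + n_specific * length(trt_states)
    if (needed > nrow(genes)) {
      stop_bad_arg("generate_study(): not enough genes for the planting plan")
    }
    pool <- sample(genes$feature_id, needed)
    core <- pool[seq_len(n_core)]
    rest <- setdiff(pool, core)
    planted <- purrr::map_dfr(seq_along(trt_states), function(i) {
      specific <- if (n_specific > 0) {
        rest[((i - 1) * n_specific + 1):(i * n_specific)]
      } else character(0)
      tibble::tibble(state = trt_states[i], gene_id = c(core, specific))
    })
    consensi <- lapply(cfg$motif_consensus, function(s) strsplit(s, "")[[1]])
    planted_genes <- unique(planted$gene_id)
    motif_of_gene <- setNames(
      rep(seq_along(consensi), length.out = length(planted_genes)),
      planted_genes)
    placements <- purrr::map_dfr(planted_genes, function(g) {
      row <- genes[genes$feature_id == g, ]
      lo <- row$start + 10L
      hi <- row$end - 10L
      grid <- seq(lo, hi, by = 25L)
      anchors <- sort(sample(grid, cfg$dmps_per_gene))
      tibble::tibble(gene_id = g, anchor_pos = as.integer(anchors),
                     motif = unname(motif_of_gene[g]))
    })
    # write the (mutated) motif copies into the genome, anchor C preserved
    for (r in seq_len(nrow(placements))) {
      pos <- placements$anchor_pos[r]
      copy <- consensi[[placements$motif[r]]]
      mutate_at <- which(stats::runif(14) < cfg$mutation_rate & seq_len(14) != 7)
      for (i in mutate_at) {
        copy[i] <- sample(setdiff(DNA_BASES, copy[i]), 1)
      }
      genome[(pos - 6):(pos + 7)] <- copy
    }
  }

  # --- cytosine sites: context from the post-planting sequence --------
  plus_pos <- which(genome == "C")
  plus_pos <- plus_pos[plus_pos <= L - 2]
  minus_pos <- which(genome == "G")
  minus_pos <- minus_pos[minus_pos >= 3]
  tri_plus <- paste0(genome[plus_pos], genome[plus_pos + 1], genome[plus_pos + 2])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tri_minus <- paste0(comp[genome[minus_pos]], comp[genome[minus_pos - 1]],
                      comp[genome[minus_pos - 2]])
  context_of <- function(tri) {
    b2 <- substr(tri, 2, 2)
    b3 <- substr(tri, 3, 3)
    ifelse(b2 == "G", "CG", ifelse(b3 == "G", "CHG", "CHH"))
  }
  sites <- tibble::tibble(
    chrom = "chr1",
    pos = c(plus_pos, minus_pos),
    strand = rep(c("+", "-"), c(length(plus_pos), length(minus_pos))),
    trinucleotide = c(tri_plus, tri_minus)
  ) |>
    dplyr::mutate(context = context_of(.data$trinucleotide)) |>
    dplyr::arrange(.data$pos, .data$strand)

  # --- baseline methylation levels ------------------------------------
  n_sites <- nrow(sites)
  baseline <- numeric(n_sites)
  for (ctx in c("CG", "CHG", "CHH")) {
    idx <- which(sites$context == ctx)
    baseline[idx] <- sample_mixture_beta(length(idx),
                                         cfg$context_baseline[[ctx]])
  }
  planted_idx <- integer(0)
  if (nrow(placements) > 0) {
    planted_idx <- match(site_key("chr1", placements$anchor_pos, "+"),
                         site_key(sites$chrom, sites$pos, sites$strand))
    baseline[planted_idx] <- stats::runif(length(planted_idx), 0.05, 0.15)
  }

  # per-state site levels: baseline everywhere, shifted at each state's
  # planted anchors
  state_levels <- lapply(state_names, function(s) baseline)
  names(state_levels) <- state_names
  if (nrow(placements) > 0) {
    for (s in trt_states) {
      g_s <- planted$gene_id[planted$state == s]
      idx_s <- planted_idx[placements$gene_id %in% g_s]
      state_levels[[s]][idx_s] <- pmin(0.99, baseline[idx_s] + cfg$effect)
    }
  }

  # --- per-sample counts ----------------------------------------------
  samples <- tibble::tibble(
    sample_id = unlist(lapply(state_names, function(s) {
      paste0(s, "_r", seq_len(cfg$states[[s]]))
    })),
    group = rep(state_names, unname(cfg$states))
  )
  meth <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    lvl <- pmin(pmax(state_levels[[samples$group[i]]], 1e-3), 1 - 1e-3)
    cov <- stats::rnbinom(n_sites, mu = cfg$coverage_mean,
                          size = cfg$coverage_disp)
    p_rep <- stats::rbeta(n_sites, lvl * cfg$rep_precision,
                          (1 - lvl) * cfg$rep_precision)
    m <- stats::rbinom(n_sites, cov, p_rep)
    tibble::tibble(sample_id = samples$sample_id[i],
                   group = samples$group[i],
                   sites,
                   meth = m, unmeth = cov - m)
  })

  truth_dmps <- if (nrow(placements) > 0) {
    planted |>
      dplyr::inner_join(placements, by = "gene_id",
                        relationship = "many-to-many") |>
      dplyr::transmute(.data$state, chrom = "chr1", pos = .data$anchor_pos,
                       strand = "+", .data$gene_id)
  } else {
    tibble::tibble(state = character(0), chrom = character(0),
                   pos = integer(0), strand = character(0),
                   gene_id = character(0))
  }
  structure(list(
    genome = Biostrings::DNAStringSet(setNames(paste(genome, collapse = ""),
                                               "chr1")),
    genes = genes, tes = tes, srna = srna,
    meth = meth, samples = samples,
    truth = list(dmps = truth_dmps,
                 dmgs = planted,
                 motif = list(
                   consensus = if (nrow(placements) > 0) {
                     cfg$motif_consensus[sort(unique(placements$motif))]
                   } else character(0),
                   placements = placements)),
    config = cfg
  ), class = "md_study")
}

#' @export
print.md_study <- function(x, ...) {
  cat("<md_study>", sum(Biostrings::width(x$genome)), "bp genome;",
      nrow(x$samples), "samples;",
      dplyr::n_distinct(x$meth$pos), "cytosine positions;",
      nrow(x$truth$dmps), "planted DMP records\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `tes.bed`, `srna.bed`, one
#' `<sample>.CX_report.txt` per sample, and `truth.json`.
#'
#' @param study `md_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(study$genome, file.path(dir, "genome.fa"))
  write_features(study$genes, file.path(dir, "genes.gff3"), format = "gff3")
  write_features(study$tes, file.path(dir, "tes.bed"), format = "bed")
  write_features(study$srna, file.path(dir, "srna.bed"), format = "bed")
  for (s in study$samples$sample_id) {
    write_cytosine_report(
      dplyr::filter(study$meth, .data$sample_id == s),
      file.path(dir, paste0(s, ".CX_report.txt"))
    )
  }
  jsonlite::write_json(
    list(dmps = study$truth$dmps, dmgs = study$truth$dmgs,
         motif_consensus = study$truth$motif$consensus,
         motif_placements = study$truth$motif$placements,
         samples = study$samples),
    file.path(dir, "truth.json"), dataframe = "columns"
  )
  invisible(dir)
}

#' Precision/recall of pipeline calls against planted truth
#'
#' @param calls Stage-dependent calls: for `"dmp"` a tibble with `chrom`,
#'   `pos`, `strand`; for `"dmg"` a character vector of gene IDs; for
#'   `"motif"` a position frequency matrix from [frequency_matrix()].
#' @param truth The `truth` element of an `md_study`.
#' @param stage `"dmp"`, `"dmg"`, or `"motif"`.
#' @return One-row tibble: `stage`, `n_calls`, `n_truth`, `tp`, `precision`
#'   (NA when there are no calls), `recall`. For `"motif"`, `tp` is the
#'   number of consensus positions whose modal base matches and `recall`
#'   the matched fraction.
#' @export
truth_metrics <- function(calls, truth, stage = c("dmp", "dmg", "motif")) {
  stage <- match.arg(stage)
  if (stage == "dmp") {
    truth_keys <- unique(site_key(truth$dmps$chrom, truth$dmps$pos,
                                  truth$dmps$strand))
    call_keys <- unique(site_key(calls$chrom, calls$pos, calls$strand))
    tp <- sum(call_keys %in% truth_keys)
    n_calls <- length(call_keys); n_truth <- length(truth_keys)
  } else if (stage == "dmg") {
    truth_keys <- unique(truth$dmgs$gene_id)
    call_keys <- unique(calls)
    tp <- sum(call_keys %in% truth_keys)
    n_calls <- length(call_keys); n_truth <- length(truth_keys)
  } else {
    # calls: one PFM, a list of PFMs, or md_motif_clusters; each planted
    # consensus is scored by its best-matching cluster's modal bases, and
    # the worst-recovered consensus is reported
    pfms <- if (inherits(calls, "md_motif_clusters")) {
      lapply(calls$msas, frequency_matrix)
    } else if (is.list(calls) && !is.matrix(calls)) {
      calls
    } else {
      list(calls)
    }
    modal <- lapply(pfms, function(p) {
      colnames(p)[max.col(p, ties.method = "first")]
    })
    per_consensus <- vapply(truth$motif$consensus, function(cs) {
      cc <- strsplit(cs, "")[[1]]
      max(vapply(modal, function(m) sum(m == cc), numeric(1)))
    }, numeric(1))
    width <- nchar(truth$motif$consensus[1])
    return(tibble::tibble(stage = stage, n_calls = length(pfms),
                          n_truth = length(per_consensus),
                          tp = as.integer(min(per_consensus)),
                          precision = NA_real_,
                          recall = min(per_consensus) / width))
  }
  tibble::tibble(
    stage = stage, n_calls = n_calls, n_truth = n_truth, tp = tp,
    precision = if (n_calls == 0) NA_real_ else tp / n_calls,
    recall = if (n_truth == 0) NA_real_ else tp / n_truth
  )
}
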