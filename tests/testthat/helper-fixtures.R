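# In-code fixtures shared across test files.

make_meth <- function(pos, meth, unmeth, sample_id = "s1", group = "WT",
                      chrom = "chr1", strand = "+", context = "CG",
                      trinucleotide = "CGA") {
  tibble::tibble(sample_id = sample_id, group = group, chrom = chrom,
                 pos = as.integer(pos), strand = strand, context = context,
                 trinucleotide = trinucleotide,
                 meth = as.integer(meth), unmeth = as.integer(unmeth))
}

make_features <- function(start, end, chrom = "chr1", kind = "gene",
                          strand = "+", prefix = kind) {
  tibble::tibble(
    feature_id = sprintf("%s_%02d", prefix, seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, kind = kind
  )
}

# a small but complete study used by pipeline smoke tests (cheap to run)
small_study <- function(seed = 101, ...) {
  generate_study(sim_config(
    genome_length = 60000, n_genes = 30, n_tes = 15, n_srna = 15,
    n_planted_genes = 6, dmps_per_gene = 8,
    motif_consensus = c("AGCTCTCGCATCGC", "CTGAAGCAGTGGTT"),
    seed = seed, ...
  ))
}

# null counts: shared per-site baseline, binomial sampling per replicate
simulate_null_samples <- function(n_sites, n_reps, coverage = 30,
                                  group = "WT", prefix = "ctl") {
  p <- stats::rbeta(n_sites, 2, 2)
  dplyr::bind_rows(lapply(seq_len(n_reps), function(r) {
    cov <- stats::rpois(n_sites, coverage) + 1L
    m <- stats::rbinom(n_sites, cov, p)
    make_meth(seq_len(n_sites), m, cov - m,
              sample_id = paste0(prefix, r), group = group)
  }))
}
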