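# toy contig engineered so windows can be sliced by hand:
# positions 1..30; a C at 10 (plus strand) and a G at 20 (C on minus strand)
toy_genome <- function() {
  s <- strsplit("AAAATTTTGCAGTCAGTCAGATTCCGGAAT", "")[[1]]
  stopifnot(s[10] == "C", s[20] == "G")
  setNames(paste(s, collapse = ""), "chr1")
}

toy_dmps <- function(pos, strand, samples = paste0("t", 1:3)) {
  tidyr::crossing(sample_id = samples, pos = as.integer(pos)) |>
    dplyr::mutate(group = "T", chrom = "chr1", strand = strand)
}

test_that("window extraction anchors the DMP cytosine at position 7 on both strands", {
  g <- toy_genome()
  # below the recurrence floor: nothing emitted
  few <- extract_windows(toy_dmps(10, "+", samples = c("t1", "t2")), g)
  expect_equal(nrow(few), 0)

  # plus strand: genome[4..17], C at window position 7
  w <- extract_windows(toy_dmps(10, "+"), g)
  expect_equal(w$seq, unname(substr(g, 4, 17)))
  expect_equal(substr(w$seq, 7, 7), "C")
  expect_equal(w$support, 3L)

  # minus strand (G on plus): reverse complement of genome[13..26]
  wm <- extract_windows(toy_dmps(20, "-"), g)
  expect_equal(wm$seq,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(g, 13, 26)))))
  expect_equal(substr(wm$seq, 7, 7), "C")

  # anchor that is not a cytosine is a validation error naming the site
  expect_error(extract_windows(toy_dmps(7, "+"), g), "chr1:7")
  # windows crossing the contig end are dropped with a warning
  expect_warning(out <- extract_windows(toy_dmps(26, "+"), g), "contig end")
  expect_equal(nrow(out), 0)
})

test_that("pairwise distances follow the raw and K80 closed forms", {
  expect_equal(pairwise_distance(c("ACGT", "ACGT"))[1, 2], 0)
  expect_equal(pairwise_distance(c("AAAA", "AAAT"))[1, 2], 0.25)
  # one transition in four sites: P = 0.25, Q = 0
  k80 <- -0.5 * log(1 - 2 * 0.25) - 0.25 * log(1)
  expect_equal(pairwise_distance(c("ACGT", "GCGT"), model = "k80")[1, 2],
               k80, tolerance = 1e-4)
  expect_equal(round(k80, 4), 0.3466)  # closed-form value
  # undefined K80 pairs get the large sentinel
  expect_warning(
    d <- pairwise_distance(c("ACACACACACACAC", "CACACACACACACA"),
                           model = "k80"),
    "sentinel")
  expect_equal(d[1, 2], 10)
})

test_that("upgma clustering recovers planted families and matches the oracle", {
  withr::local_seed(61)
  seeds <- c("AAAAAAAAAAAAAA", "GGGGGGGGGGGGGG", "TTTTTTTTTTTTTT")
  fam <- lapply(seeds, function(s) {
    vapply(1:20, function(i) {
      x <- strsplit(s, "")[[1]]
      flip <- runif(14) < 0.05
      x[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      paste(x, collapse = "")
    }, character(1))
  })
  seqs <- unlist(fam)
  cl <- upgma_clusters(pairwise_distance(seqs), k = 3, min_size = 10)
  truth <- rep(1:3, each = 20)
  expect_equal(nrow(cl), 60)
  tab <- table(cl$cluster_id, truth[cl$item])
  expect_equal(sum(apply(tab, 1, max)), 60)  # families recovered exactly

  # all-identical input collapses to one surviving cluster
  same <- rep("ACGTACCTACGTAC", 12)
  cl_same <- upgma_clusters(pairwise_distance(same), k = 5, min_size = 10)
  expect_equal(length(unique(cl_same$cluster_id)), 1)

  # 5-leaf hand-worked matrix: merge partitions equal the textbook oracle
  D <- matrix(0, 5, 5)
  D[upper.tri(D)] <- c(17, 21, 31, 23, 30, 34, 21, 28, 39, 43)
  D <- D + t(D)
  hc <- attr(upgma_clusters(D, k = 1, min_size = 1), "tree")
  oracle <- oracle_upgma_partitions(D)
  for (step in seq_along(oracle)) {
    k <- 5 - step
    if (k < 1) break
    expect_equal(canon_partition(stats::cutree(hc, k = k)),
                 canon_partition(oracle[[step]]))
  }
  expect_error(upgma_clusters(matrix(0, 1, 1)), ">= 2")
})

test_that("anchored alignment is the identity and external failures are reported", {
  seqs <- c("ACGTACCTACGTAC", "ACGTACCTACGTAA")
  expect_equal(align_cluster(seqs), seqs)
  expect_error(align_cluster(seqs, mode = "external",
                             aligner = "no-such-aligner-xyz"), "not found")
  expect_error(align_cluster(c("ACGT", "ACGTA")), "same length")
})

test_that("motif score follows the pairwise log2 match-count definition", {
  # perfect MSA of width 14: every pairwise score log2(14), information 0
  perfect <- motif_score(rep("ACGTACCTACGTAC", 5))
  expect_equal(perfect$score_s, log2(14))
  expect_equal(perfect$info_i, 0)

  # 2 rows of length 4 with 3 matches
  two <- motif_score(c("ACGT", "ACGA"))
  expect_equal(two$score_s, log2(3))
  expect_equal(two$info_i, 2 - log2(3))

  # 3 rows with pairwise matches (14, 7, 7): I = 2/3 exactly
  r1 <- "AAAAAAACCCCCCC"
  r2 <- r1                                  # 14 matches with r1
  r3 <- "AAAAAAAGGGGGGG"                    # 7 with r1, 7 with r2
  three <- motif_score(c(r1, r2, r3))
  expect_equal(unname(three$s_matrix[1, 2]), log2(14))
  expect_equal(unname(three$s_matrix[1, 3]), log2(7))
  expect_equal(three$info_i, 2 / 3)

  # zero-match pair propagates -Inf unless floored
  zm <- motif_score(c("AAAA", "CCCC"))
  expect_equal(zm$score_s, -Inf)
  expect_true(is.finite(motif_score(c("AAAA", "CCCC"),
                                    min_matches = 1)$score_s))
  expect_error(motif_score("ACGT"), ">= 2")
})

test_that("motif score agrees with the brute-force oracle and I >= 0", {
  withr::local_seed(71)
  for (rep in 1:25) {
    M <- sample(2:6, 1)
    N <- sample(4:14, 1)
    msa <- random_msa(M, N, gap_frac = if (rep %% 5 == 0) 0.1 else 0)
    got <- motif_score(msa)
    exp <- oracle_motif_score(msa)
    expect_equal(got$score_s, exp$score_s)
    expect_equal(got$info_i, exp$info_i)
    if (is.finite(got$info_i)) expect_gte(got$info_i, -1e-12)
  }
})

test_that("frequency matrices are column-normalized with gaps excluded", {
  f <- frequency_matrix(c("CA-", "CC-", "CGA"))
  expect_equal(unname(f[1, ]), c(0, 1, 0, 0))       # all-C column
  expect_equal(unname(f[2, ]), c(1, 1, 1, 0) / 3)
  expect_equal(unname(f[3, ]), c(1, 0, 0, 0))       # gaps out of denominator
  expect_equal(unname(rowSums(f)), rep(1, 3))
  u <- frequency_matrix(c("A", "C", "G", "T"))
  expect_equal(unname(u[1, ]), rep(0.25, 4))
  expect_error(frequency_matrix(c("A-", "C-")), "all-gap")
})

test_that("the motif cluster wrapper scores surviving clusters end to end", {
  withr::local_seed(81)
  seeds <- c("AGCTCTCGCATCGC", "CTGAAGCAGTGGTT")
  windows <- tibble::tibble(
    chrom = "chr1", anchor_pos = seq_len(30), strand = "+",
    seq = vapply(rep(seeds, each = 15), function(s) {
      x <- strsplit(s, "")[[1]]
      flip <- which(runif(14) < 0.1 & seq_len(14) != 7)
      x[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
      paste(x, collapse = "")
    }, character(1)),
    support = 3L
  )
  mc <- motif_clusters(windows, k = 2, min_size = 10)
  expect_equal(nrow(mc$clusters), 2)
  expect_true(all(mc$clusters$n_members >= 10))
  expect_true(all(mc$clusters$info_i >= 0))
  expect_equal(mc$clusters$info_i,
               log2(14) - mc$clusters$score_s)
})
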