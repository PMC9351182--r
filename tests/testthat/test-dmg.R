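make_dmps <- function(pos, sample_id = "t1", group = "T", chrom = "chr1") {
  tibble::tibble(sample_id = sample_id, group = group, chrom = chrom,
                 pos = as.integer(pos), strand = "+",
                 hd = 1, bayes_diff = 0.5)
}

test_that("per-gene DMP counting respects interval boundaries", {
  genes <- make_features(100, 200)
  dmps <- make_dmps(c(100, 200, 201))
  counts <- count_dmps_per_gene(dmps, genes)
  expect_equal(counts$n_dmps, 2L)

  # no DMPs: an explicit all-zero matrix over the sample universe
  samples <- tibble::tibble(sample_id = c("a", "b"), group = c("T", "T"))
  z <- count_dmps_per_gene(make_dmps(integer(0)), genes, samples = samples)
  expect_equal(nrow(z), 2)
  expect_true(all(z$n_dmps == 0))
})

test_that("per-gene counting matches a quadratic interval-membership oracle", {
  withr::local_seed(41)
  genes <- make_features(start = sample.int(9000, 50),
                         end = integer(50))
  genes$end <- genes$start + sample.int(400, 50)
  dmps <- dplyr::bind_rows(
    make_dmps(sample.int(10000, 500), sample_id = "t1"),
    make_dmps(sample.int(10000, 500), sample_id = "t2")
  )
  counts <- count_dmps_per_gene(dmps, genes)
  for (i in sample.int(nrow(counts), 40)) {
    g <- genes[genes$feature_id == counts$gene_id[i], ]
    d <- dmps[dmps$sample_id == counts$sample_id[i], ]
    expect_equal(counts$n_dmps[i],
                 sum(d$pos >= g$start & d$pos <= g$end))
  }
})

test_that("count and density filters exclude genes before testing", {
  genes <- make_features(c(1, 20001), c(2000, 70000))  # 2 kb and 50 kb
  samples <- tidyr::crossing(group = c("WT", "T"), rep = 1:3) |>
    dplyr::mutate(sample_id = paste0(group, rep))
  # gene 1: 6 treatment DMPs in total -> below the 7-DMP floor
  # gene 2: 14 treatment DMPs over 50 kb -> density 2.8/10kb, excluded
  dmps <- dplyr::bind_rows(
    make_dmps(seq(10, 60, by = 10), sample_id = "T1"),
    make_dmps(seq(20010, 20140, by = 10), sample_id = "T2")
  )
  res <- test_dmgs(count_dmps_per_gene(dmps, genes, samples = samples),
                   control = "WT")
  expect_equal(nrow(res), 0)
})

test_that("planted count differences are recovered with controlled false discoveries", {
  withr::local_seed(77)
  n_genes <- 200
  genes <- make_features(start = (0:(n_genes - 1)) * 3000 + 1,
                         end = (0:(n_genes - 1)) * 3000 + 2000)
  planted <- genes$feature_id[1:20]
  samples <- tibble::tibble(
    sample_id = c(paste0("WT", 1:3), paste0("T", 1:3)),
    group = rep(c("WT", "T"), each = 3)
  )
  # Poisson counts: rate 2 everywhere, rate 10 in planted genes (treatment).
  # BH controls the false-discovery proportion in expectation, so recall and
  # FDP are averaged over replicate simulations.
  metrics <- vapply(1:10, function(rep) {
    counts <- tidyr::crossing(
      tibble::tibble(gene_id = genes$feature_id, length_bp = 2000L),
      samples) |>
      dplyr::mutate(rate = ifelse(.data$gene_id %in% planted &
                                    .data$group == "T", 10, 2),
                    n_dmps = rpois(dplyr::n(), .data$rate)) |>
      dplyr::select(-"rate")
    res <- test_dmgs(counts, control = "WT", family = "poisson")
    called <- res$gene_id[res$is_dmg]
    c(recall = mean(planted %in% called),
      fdp = if (length(called) == 0) 0 else mean(!called %in% planted))
  }, numeric(2))
  expect_gte(mean(metrics["recall", ]), 0.9)
  expect_lte(mean(metrics["fdp", ]), 0.05 + 2 * stats::sd(metrics["fdp", ]) /
               sqrt(10))
})

test_that("under a global null the LRT p-values are calibrated", {
  withr::local_seed(13)
  n_genes <- 2000
  samples <- tibble::tibble(
    sample_id = c(paste0("WT", 1:3), paste0("T", 1:3)),
    group = rep(c("WT", "T"), each = 3)
  )
  counts <- tidyr::crossing(
    tibble::tibble(gene_id = sprintf("g%04d", 1:n_genes),
                   length_bp = 2000L), samples) |>
    dplyr::mutate(n_dmps = rpois(dplyr::n(), 8))
  res <- suppressWarnings(
    test_dmgs(counts, control = "WT", family = "poisson",
              min_dmps = 0, min_density = 0))
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
  # BH is monotone: adjusted order preserves raw order
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})

test_that("the DMG set is anti-monotone in every threshold", {
  withr::local_seed(59)
  samples <- tibble::tibble(
    sample_id = c(paste0("WT", 1:3), paste0("T", 1:3)),
    group = rep(c("WT", "T"), each = 3)
  )
  counts <- tidyr::crossing(
    tibble::tibble(gene_id = sprintf("g%03d", 1:60), length_bp = 2500L),
    samples) |>
    dplyr::mutate(n_dmps = rpois(dplyr::n(),
                                 ifelse(.data$group == "T", 6, 2)))
  base <- suppressWarnings(
    test_dmgs(counts, family = "poisson"))$gene_id
  base <- base[!is.na(base)]
  for (args in list(list(min_dmps = 10), list(min_density = 10),
                    list(lfc_min = 2), list(fdr = 0.001))) {
    stricter <- suppressWarnings(do.call(
      test_dmgs, c(list(counts, family = "poisson"), args)))
    expect_true(all(stricter$gene_id[stricter$is_dmg] %in% base))
  }
})

test_that("proximity fractions match an all-pairs distance oracle", {
  genes <- make_features(c(5000, 5000), c(6000, 6000))
  te_near <- make_features(7500, 7600, kind = "TE")
  te_far <- make_features(8100, 8200, kind = "TE")
  expect_equal(proximity_fraction(genes[1, ], te_near, 2000), 1)
  expect_equal(proximity_fraction(genes[1, ], te_far, 2000), 0)

  withr::local_seed(23)
  g <- make_features(sample.int(50000, 40), integer(40))
  g$end <- g$start + 500L
  f <- make_features(sample.int(50000, 30), integer(30), kind = "TE")
  f$end <- f$start + 200L
  got <- proximity_fraction(g, f, 2000)
  oracle <- mean(vapply(seq_len(nrow(g)), function(i) {
    any(vapply(seq_len(nrow(f)), function(j) {
      # distance between intervals, 0 if overlapping
      gap <- max(0, max(g$start[i], f$start[j]) - min(g$end[i], f$end[j]))
      gap <= 2000
    }, logical(1)))
  }, logical(1)))
  expect_equal(got, oracle)
})

test_that("set overlap structure enumerates venn cells and jaccard", {
  ident <- overlap_sets(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(sum(ident$venn$count), 5)
  expect_equal(ident$jaccard$jaccard, 1)

  disj <- overlap_sets(list(a = letters[1:5], b = letters[6:10]))
  expect_equal(disj$jaccard$intersection, 0)
  expect_equal(disj$jaccard$jaccard, 0)

  withr::local_seed(2)
  sets <- lapply(1:4, function(i) sample(1:1000, 300))
  names(sets) <- paste0("s", 1:4)
  ov <- overlap_sets(sets)
  expect_equal(sum(ov$venn$count), length(unique(unlist(sets))))
  # spot-check one venn cell against direct enumeration
  cell <- ov$venn[ov$venn$s1 & ov$venn$s2 & !ov$venn$s3 & !ov$venn$s4, ]
  direct <- length(setdiff(intersect(sets$s1, sets$s2),
                           union(sets$s3, sets$s4)))
  expect_equal(if (nrow(cell) == 0) 0 else cell$count, direct)
})
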