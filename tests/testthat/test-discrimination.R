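fake_dmps <- function(pos, sample_id, hd, group = "T", chrom = "chr1") {
  tibble::tibble(sample_id = sample_id, group = group, chrom = chrom,
                 pos = as.integer(pos), strand = "+", hd = hd,
                 bayes_diff = hd / 10)
}

test_that("gene matrix accumulates the chosen statistic per gene and sample", {
  genes <- make_features(c(100, 300), c(200, 400))
  samples <- tibble::tibble(sample_id = c("s1", "s2"), group = c("T", "T"))
  dmps <- fake_dmps(c(150, 160, 350), "s1", hd = c(2.0, 3.5, 7))
  gm <- gene_matrix(dmps, genes, samples = samples)
  expect_equal(gm$s1, c(5.5, 7))
  expect_equal(gm$s2, c(0, 0))  # sample without DMPs: zero column

  gm2 <- gene_matrix(dmps, genes, statistic = "sum_bayes_diff",
                     samples = samples)
  expect_equal(gm2$s1, c(0.55, 0.7))
  expect_error(gene_matrix(dmps, genes, statistic = "nope"))

  # brute-force accumulation oracle on random input
  withr::local_seed(8)
  g <- make_features((0:19) * 500 + 1, (0:19) * 500 + 400)
  d <- fake_dmps(sample.int(10000, 300, replace = TRUE),
                 sample(c("a", "b", "c"), 300, replace = TRUE),
                 hd = runif(300, 0, 5))
  gm3 <- gene_matrix(d, g, samples = tibble::tibble(
    sample_id = c("a", "b", "c"), group = "T"))
  for (i in sample.int(20, 8)) {
    for (s in c("a", "b", "c")) {
      expected <- sum(d$hd[d$sample_id == s & d$pos >= g$start[i] &
                             d$pos <= g$end[i]])
      expect_equal(gm3[[s]][gm3$gene_id == g$feature_id[i]], expected)
    }
  }
})

test_that("ward clustering recovers separated groups and matches the Lance-Williams oracle", {
  withr::local_seed(14)
  # two well-separated sample groups over 10 genes
  base <- matrix(rnorm(10 * 6, sd = 0.1), nrow = 10)
  base[, 4:6] <- base[, 4:6] + 20
  gm <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                       tibble::as_tibble(setNames(as.data.frame(base),
                                                  paste0("s", 1:6))))
  attr(gm, "groups") <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  wc <- ward_cluster(gm, k = 2)
  expect_equal(unname(wc$labels[1:3] == wc$labels[1]), rep(TRUE, 3))
  expect_false(wc$labels[1] == wc$labels[4])

  # duplicated sample merges at height zero
  gm_dup <- gm
  gm_dup$s2 <- gm_dup$s1
  expect_equal(min(ward_cluster(gm_dup)$hclust$height), 0)

  # 6-point configuration: partition sequence equals the Ward oracle
  x <- matrix(c(0, 0, 0.4, 0.1, 5, 5, 5.3, 4.8, 10, 0, 10.2, 0.3),
              ncol = 2, byrow = TRUE)
  gm6 <- tibble::tibble(gene_id = c("g1", "g2"),
                        tibble::as_tibble(setNames(as.data.frame(t(x)),
                                                   paste0("s", 1:6))))
  hc <- ward_cluster(gm6)$hclust
  oracle <- oracle_ward_partitions(x)
  for (step in seq_along(oracle$partitions)) {
    k <- 6 - step
    if (k < 1) break
    expect_equal(canon_partition(stats::cutree(hc, k = k)),
                 canon_partition(oracle$partitions[[step]]))
  }
  # ward.D2 heights are the square roots of the Ward (squared) merge costs
  expect_equal(hc$height, sqrt(oracle$heights), tolerance = 1e-8)

  expect_error(ward_cluster(gm[, 1:2]), ">= 2 samples")
  expect_error(ward_cluster(gm, k = 10), "exceeds")
})

test_that("pca-lda discriminates class-shifted samples with high LOO accuracy", {
  withr::local_seed(27)
  n_genes <- 50; reps <- 4
  shift <- matrix(0, n_genes, 3)
  shift[1:10, 2] <- 3; shift[11:20, 3] <- 3
  cols <- lapply(1:3, function(cl) {
    vapply(seq_len(reps), function(r) rnorm(n_genes) + shift[, cl],
           numeric(n_genes))
  })
  x <- do.call(cbind, cols)
  ids <- paste0("s", 1:(3 * reps))
  gm <- tibble::tibble(gene_id = sprintf("g%02d", 1:n_genes),
                       tibble::as_tibble(setNames(as.data.frame(x), ids)))
  groups <- setNames(rep(c("c1", "c2", "c3"), each = reps), ids)
  attr(gm, "groups") <- groups

  correct <- vapply(seq_along(ids), function(i) {
    train <- gm[, c("gene_id", ids[-i])]
    attr(train, "groups") <- groups[ids[-i]]
    fit <- pca_lda(train)
    test <- gm[, c("gene_id", ids[i])]
    predict(fit, test)$predicted == groups[[ids[i]]]
  }, logical(1))
  expect_gte(mean(correct), 0.9)

  fit_all <- pca_lda(gm)
  expect_true(all(fit_all$var_frac[seq_len(fit_all$K)] >= 0.01))
  expect_s3_class(tidy(fit_all), "tbl_df")
  expect_equal(glance(fit_all)$n_classes, 3)

  # a singleton class is refused by name
  bad_groups <- groups
  bad_groups[1] <- "lonely"
  attr(gm, "groups") <- bad_groups
  expect_error(pca_lda(gm), "lonely")
})

test_that("rank-1 data retains a single component", {
  withr::local_seed(4)
  u <- rnorm(30)
  x <- outer(u, c(1, 2, 3, 4, 5, 6)) + matrix(rnorm(180, sd = 1e-4), 30)
  gm <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                       tibble::as_tibble(setNames(as.data.frame(x),
                                                  paste0("s", 1:6))))
  attr(gm, "groups") <- setNames(rep(c("A", "B"), 3), paste0("s", 1:6))
  expect_equal(pca_lda(gm)$K, 1)
})

test_that("pc scores are loadings norms with conserved total", {
  withr::local_seed(33)
  x <- matrix(rnorm(40 * 8), 40)
  x[40, ] <- 7  # constant gene: zero loading after centering
  gm <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                       tibble::as_tibble(setNames(as.data.frame(x),
                                                  paste0("s", 1:8))))
  attr(gm, "groups") <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  fit <- pca_lda(gm)
  sc <- pc_scores(fit)
  expect_equal(sum(sc$pc_score^2), fit$K, tolerance = 1e-9)
  expect_lt(sc$pc_score[sc$gene_id == "g40"], 1e-9)

  # PCA reconstruction with all components reproduces the centered matrix
  full <- stats::prcomp(t(as.matrix(x)), center = TRUE)
  rec <- full$x %*% t(full$rotation)
  centered <- sweep(t(x), 2, full$center)
  expect_equal(rec, centered, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("correlation networks match the all-pairs oracle and spearman invariance", {
  mk <- function(x, ids = sprintf("g%02d", seq_len(nrow(x)))) {
    gm <- tibble::tibble(gene_id = ids,
                         tibble::as_tibble(setNames(as.data.frame(x),
                                                    paste0("s", seq_len(ncol(x))))))
    attr(gm, "groups") <- setNames(rep("T", ncol(x)), paste0("s", seq_len(ncol(x))))
    gm
  }
  withr::local_seed(19)
  dup <- matrix(rnorm(12), 2, 6, byrow = TRUE)
  dup[2, ] <- dup[1, ]
  net_dup <- correlation_network(mk(dup), tau = 0.9)
  expect_equal(nrow(net_dup$edges), 1)
  expect_equal(net_dup$edges$correlation, 1)

  x <- matrix(rnorm(20 * 8), 20)
  expect_equal(nrow(correlation_network(mk(x), tau = 1.01)$edges), 0)

  net <- correlation_network(mk(x), tau = 0.5, method = "spearman")
  cm <- stats::cor(t(x), method = "spearman")
  expected <- sum(abs(cm[upper.tri(cm)]) >= 0.5)
  expect_equal(nrow(net$edges), expected)
  expect_equal(net$connected_genes, sum(net$nodes$degree >= 1))

  # spearman edges are invariant to monotone transforms of sample values
  net_t <- correlation_network(mk(exp(x)), tau = 0.5, method = "spearman")
  expect_equal(net$edges$gene_a, net_t$edges$gene_a)
  expect_equal(net$edges$gene_b, net_t$edges$gene_b)

  # constant rows are excluded with a warning
  xc <- rbind(x, 1)
  expect_warning(correlation_network(mk(xc)), "constant")
  expect_error(correlation_network(mk(x[, 1:3])), ">= 4 samples")
})

test_that("fisher overlap test agrees with hypergeometric enumeration", {
  u <- sprintf("g%03d", 1:20)
  full <- set_overlap_fisher(u, u, u)
  expect_equal(full$overlap, 20)
  expect_equal(full$p_value, 1)

  # symmetric table [[5,5],[5,5]]
  a <- u[1:10]; b <- u[c(1:5, 11:15)]
  sym <- set_overlap_fisher(a, b, u)
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(sym$p_value, 1)

  # table [[10,2],[3,15]] vs exact enumeration
  u2 <- sprintf("x%03d", 1:30)
  a2 <- u2[1:12]; b2 <- u2[c(1:10, 13:15)]
  got <- set_overlap_fisher(a2, b2, u2)
  expect_equal(got$overlap, 10)
  expect_equal(got$p_value, oracle_fisher_p(10, 2, 3, 15), tolerance = 1e-10)

  expect_error(set_overlap_fisher(c(a2, "zzz"), b2, u2), "universe")
})
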