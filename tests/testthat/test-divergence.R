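test_that("pooling controls sums counts over the union of sites", {
  a <- make_meth(c(10, 20), c(3, 5), c(7, 5), sample_id = "c1")
  b <- make_meth(c(10, 30), c(2, 1), c(8, 9), sample_id = "c2")
  cen <- pool_reference(dplyr::bind_rows(a, b))
  expect_equal(cen$pos, c(10, 20, 30))
  expect_equal(cen$meth, c(5, 5, 1))     # (3,7)+(2,8) -> (5,15) at pos 10
  expect_equal(cen$unmeth, c(15, 5, 9))

  # one control: centroid identical to it
  solo <- pool_reference(a)
  expect_equal(solo$meth, a$meth)
  expect_equal(solo$unmeth, a$unmeth)
  expect_error(pool_reference(a[0, ]), "control")
})

test_that("hellinger divergence matches its closed form and properties", {
  expect_equal(hellinger_divergence(5, 5, 50, 50), 0)
  expect_equal(hellinger_divergence(5, 5, 50, 50, weighted = FALSE), 0)
  expect_equal(hellinger_divergence(1, 0, 0, 1, weighted = FALSE), 1)
  # 2 * (10*10/20) * ((1-0)^2 + (0-1)^2) = 20
  expect_equal(hellinger_divergence(10, 0, 0, 10), 20)
  expect_error(hellinger_divergence(0, 0, 1, 1), "zero coverage")

  withr::local_seed(3)
  m1 <- rpois(200, 10); u1 <- rpois(200, 10) + 1
  m2 <- rpois(200, 4); u2 <- rpois(200, 12) + 1
  # symmetry, bounds
  expect_equal(hellinger_divergence(m1, u1, m2, u2),
               hellinger_divergence(m2, u2, m1, u1))
  hu <- hellinger_divergence(m1, u1, m2, u2, weighted = FALSE)
  expect_true(all(hu >= 0 & hu <= 1))
  # weighted form is linear in the coverage factor at fixed proportions
  h1 <- hellinger_divergence(4, 6, 9, 1)
  h2 <- hellinger_divergence(8, 12, 18, 2)  # doubled counts, same p's
  w1 <- 2 * 10 * 10 / 20
  w2 <- 2 * 20 * 20 / 40
  expect_equal(h2 / h1, w2 / w1)
})

test_that("bayesian level is the posterior mean and converges to m/(m+u)", {
  expect_equal(bayes_level(0, 0), 0.5)
  expect_equal(bayes_level(9, 1), 10 / 12)
  expect_error(bayes_level(1, 1, prior = c(-1, 1)), "positive")
  # asymptotics with fixed ratio
  expect_equal(bayes_level(9e6, 1e6), 0.9, tolerance = 1e-5)
  # moment matching recovers Beta hyperparameters approximately
  withr::local_seed(7)
  p <- rbeta(5000, 4, 6)
  cov <- rep(400L, 5000)
  m <- rbinom(5000, cov, p)
  ab <- moment_match_beta(m, cov - m)
  expect_equal(ab[1] / sum(ab), 0.4, tolerance = 0.05)
})

test_that("weibull-quantile cutoff recovers a known null quantile", {
  withr::local_seed(21)
  null <- rweibull(10000, shape = 2, scale = 1)
  cm <- fit_null_cutoff(null, method = "quantile", alpha = 0.05)
  # true 95th percentile: scale * (-log(0.05))^(1/shape) = 1.73082
  expect_equal(cm$cutoff, sqrt(-log(0.05)), tolerance = 0.05 * 1.7308)
  expect_s3_class(glance(cm), "tbl_df")
  expect_equal(tidy(cm)$term, c("shape", "scale", "cutoff"))

  # near-degenerate null: cutoff stays at the boundary of the fitted scale
  jitter <- 1 + rnorm(200, sd = 1e-3)
  cj <- fit_null_cutoff(jitter, method = "quantile", alpha = 0.05)
  expect_gt(cj$cutoff, 0.99)

  expect_error(fit_null_cutoff(rep(0, 100)), "degenerate")
  expect_error(fit_null_cutoff(rweibull(10, 2, 1)), ">= 50")
})

test_that("youden cutoff separates well-separated null and signal", {
  withr::local_seed(5)
  null <- runif(200, 0, 0.1)
  signal <- runif(200, 0.9, 1)
  cm <- fit_null_cutoff(null, method = "youden", treatment_hd = signal)
  expect_gt(cm$cutoff, 0.1)
  expect_lt(cm$cutoff, 0.9)
  expect_equal(cm$youden_j, 1)
  expect_error(fit_null_cutoff(null, method = "youden"), "treatment_hd")
})

test_that("dmp calling applies both the level gate and the divergence cutoff", {
  cen <- make_meth(c(1, 2, 3), c(10, 2, 70), c(10, 18, 30),
                   sample_id = "cen")[, -(1:2)]
  cutoff <- structure(list(method = "quantile", cutoff = 1, alpha = 0.05),
                      class = "md_cutoff")

  # sample identical to centroid: no DMPs
  ident <- make_meth(c(1, 2, 3), c(10, 2, 70), c(10, 18, 30))
  expect_equal(nrow(call_dmps(ident, cen, cutoff)), 0)

  # strong hyper site passes; HD from the formula confirms it clears cutoff
  hyper <- make_meth(1, 18, 2)  # p 0.9 vs 0.5
  hd_val <- hellinger_divergence(18, 2, 10, 10)
  expect_gt(hd_val, cutoff$cutoff)
  res <- call_dmps(hyper, cen, cutoff)
  expect_equal(nrow(res), 1)
  expect_equal(res$direction, "hyper")

  # large divergence but |tv| <= 0.2 is gated out
  big_cov <- make_meth(3, 850, 150)   # p 0.85 vs 0.70, tv = 0.15
  expect_gt(hellinger_divergence(850, 150, 70, 30), 5)
  expect_equal(nrow(call_dmps(big_cov, cen, cutoff, tv_min = 0.20)), 0)

  expect_error(call_dmps(make_meth(99, 5, 5), cen, cutoff), "share no sites")
})

test_that("the DMP set shrinks monotonically in cutoff and tv_min", {
  withr::local_seed(31)
  ctl <- simulate_null_samples(800, 3)
  cen <- pool_reference(ctl)
  trt <- simulate_null_samples(800, 1, prefix = "t", group = "T")
  counts <- vapply(c(0.5, 2, 5, 10), function(co) {
    cm <- structure(list(method = "quantile", cutoff = co, alpha = 0.05),
                    class = "md_cutoff")
    nrow(call_dmps(trt, cen, cm, tv_min = 0.1))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  cm <- structure(list(method = "quantile", cutoff = 1, alpha = 0.05),
                  class = "md_cutoff")
  counts_tv <- vapply(c(0, 0.1, 0.2, 0.4), function(tv) {
    nrow(call_dmps(trt, cen, cm, tv_min = tv))
  }, numeric(1))
  expect_true(all(diff(counts_tv) <= 0))
})

test_that("a control against its own centroid yields ~alpha of sites at the fitted cutoff", {
  withr::local_seed(99)
  n <- 10000
  ctl <- simulate_null_samples(n, 3)
  cen <- pool_reference(ctl)
  divs <- lapply(unique(ctl$sample_id), function(s) {
    methylation_divergence(dplyr::filter(ctl, sample_id == s), cen)
  })
  null_hd <- unlist(lapply(divs, function(d) d$hd))
  cm <- fit_null_cutoff(null_hd, method = "quantile", alpha = 0.05)
  # type-I control: fraction of sites at or above the 95% cutoff, with the
  # level gate disabled so the divergence calibration is isolated
  frac <- nrow(call_dmps(dplyr::filter(ctl, sample_id == "ctl1"), cen, cm,
                         tv_min = 0)) / n
  expect_lt(frac, 0.07)
  expect_gt(frac, 0.03)
})
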