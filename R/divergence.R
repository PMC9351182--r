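#' Pool control replicates into a reference centroid
#'
#' The reference for all divergence computations is the pooled wild-type
#' (control) methylome: per-site methylated and unmethylated counts summed
#' element-wise across control replicates. A site appears in the centroid if
#' it is covered in at least one control replicate.
#'
#' @param controls Tidy methylome tibble holding one or more control samples
#'   (rows from [read_cytosine_report()] or [simulate_methylome_study()]).
#' @return A tibble with columns `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, `meth`, `unmeth` and an attached `n_replicates`
#'   attribute.
#' @export
pool_reference <- function(controls) {
  if (is.null(controls) || nrow(controls) == 0) {
    stop_bad_arg("pool_reference(): need at least one control sample")
  }
  n_rep <- if ("sample_id" %in% names(controls)) {
    dplyr::n_distinct(controls$sample_id)
  } else 1L
  out <- controls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(
      context = .data$context[1],
      trinucleotide = .data$trinucleotide[1],
      meth = sum(.data$meth),
      unmeth = sum(.data$unmeth),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
  attr(out, "n_replicates") <- n_rep
  out
}

#' Hellinger divergence between two methylation count pairs
#'
#' For per-cytosine methylation the two "distributions" are the Bernoulli
#' (methylated, unmethylated) proportions on each side. Two forms are
#' available:
#'
#' * **weighted** (default): \eqn{HD = 2 \frac{n_1 n_2}{n_1 + n_2}
#'   [(\sqrt{p_1}-\sqrt{p_2})^2 + (\sqrt{1-p_1}-\sqrt{1-p_2})^2]} where
#'   \eqn{n = m + u} is the coverage on each side. Divergence grows with the
#'   evidence (harmonic-mean coverage), so a level difference supported by
#'   deep coverage scores higher than the same difference at shallow coverage.
#' * **plain**: the bounded Hellinger distance
#'   \eqn{\frac{1}{\sqrt 2}\sqrt{(\sqrt{p_1}-\sqrt{p_2})^2 +
#'   (\sqrt{1-p_1}-\sqrt{1-p_2})^2} \in [0, 1]}.
#'
#' Both are symmetric and zero iff \eqn{p_1 = p_2}. All arguments are
#' vectorized.
#'
#' @param m1,u1 Methylated/unmethylated counts on side 1.
#' @param m2,u2 Counts on side 2.
#' @param weighted Use the coverage-weighted form (default) or the plain
#'   bounded Hellinger distance.
#' @return Non-negative numeric vector.
#' @export
hellinger_divergence <- function(m1, u1, m2, u2, weighted = TRUE) {
  n1 <- m1 + u1
  n2 <- m2 + u2
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop_bad_arg("hellinger_divergence(): zero coverage on one side")
  }
  p1 <- m1 / n1
  p2 <- m2 / n2
  core <- (sqrt(p1) - sqrt(p2))^2 + (sqrt(1 - p1) - sqrt(1 - p2))^2
  if (weighted) {
    2 * (n1 * n2) / (n1 + n2) * core
  } else {
    sqrt(core) / sqrt(2)
  }
}

#' Bayesian (posterior-mean) methylation level
#'
#' Beta-binomial shrinkage estimate of the methylation level:
#' \eqn{(m + a) / (m + u + a + b)} under a Beta(a, b) prior. With the default
#' uniform prior this is the Laplace-smoothed level; hyperparameters can also
#' be moment-matched from all sites of a sample via [moment_match_beta()].
#'
#' @param m,u Methylated / unmethylated counts (vectorized).
#' @param prior Length-2 positive numeric `c(a, b)` Beta hyperparameters.
#' @return Levels in \[0, 1\].
#' @export
bayes_level <- function(m, u, prior = c(1, 1)) {
  if (length(prior) != 2 || any(!is.finite(prior)) || any(prior <= 0)) {
    stop_bad_arg("bayes_level(): prior must be two positive hyperparameters")
  }
  (m + prior[1]) / (m + u + prior[1] + prior[2])
}

#' Moment-matched Beta hyperparameters for a sample's methylation levels
#'
#' Matches the mean and variance of the observed per-site methylation
#' proportions to a Beta distribution. Falls back to the uniform prior
#' `c(1, 1)` when matching fails (e.g. variance incompatible with a Beta).
#'
#' @param m,u Count vectors over the sites of one sample.
#' @return `c(a, b)`.
#' @export
moment_match_beta <- function(m, u) {
  n <- m + u
  keep <- n > 0
  if (!any(keep)) return(c(1, 1))
  p <- m[keep] / n[keep]
  mu <- mean(p)
  v <- stats::var(p)
  if (!is.finite(v) || v <= 0 || mu <= 0 || mu >= 1 || v >= mu * (1 - mu)) {
    return(c(1, 1))
  }
  k <- mu * (1 - mu) / v - 1
  c(mu * k, (1 - mu) * k)
}

#' Per-site divergence of a sample against the reference centroid
#'
#' Joins a sample with the pooled reference on (chrom, pos, strand) — the
#' site universe is the intersection, since divergence is undefined at zero
#' coverage — and computes, per site: methylation levels `p_trt` and `p_ref`,
#' their difference `tv` (total-variation-style level difference), the
#' Hellinger divergence `hd`, and the Bayesian level difference `bayes_diff`.
#'
#' @param sample One sample's methylome tibble.
#' @param centroid Reference centroid from [pool_reference()].
#' @param hd `"weighted"` or `"plain"` Hellinger form.
#' @param prior Beta hyperparameters for `bayes_diff`; `NULL` (default)
#'   moment-matches per side.
#' @return Tibble of divergence records (one row per shared site).
#' @export
methylation_divergence <- function(sample, centroid,
                                   hd = c("weighted", "plain"),
                                   prior = NULL) {
  hd <- match.arg(hd)
  shared <- dplyr::inner_join(
    sample, centroid,
    by = c("chrom", "pos", "strand"),
    suffix = c("", "_ref")
  )
  if (nrow(shared) == 0) {
    stop_bad_arg("methylation_divergence(): sample and centroid share no sites")
  }
  prior_trt <- prior %||% moment_match_beta(shared$meth, shared$unmeth)
  prior_ref <- prior %||% moment_match_beta(shared$meth_ref, shared$unmeth_ref)
  out <- shared |>
    dplyr::mutate(
      p_trt = .data$meth / (.data$meth + .data$unmeth),
      p_ref = .data$meth_ref / (.data$meth_ref + .data$unmeth_ref),
      tv = .data$p_trt - .data$p_ref,
      hd = hellinger_divergence(.data$meth, .data$unmeth,
                                .data$meth_ref, .data$unmeth_ref,
                                weighted = (hd == "weighted")),
      bayes_diff = bayes_level(.data$meth, .data$unmeth, prior_trt) -
        bayes_level(.data$meth_ref, .data$unmeth_ref, prior_ref)
    )
  cols <- c("chrom", "pos", "strand", "context", "trinucleotide",
            "meth", "unmeth", "meth_ref", "unmeth_ref",
            "p_trt", "p_ref", "tv", "hd", "bayes_diff")
  if ("sample_id" %in% names(out)) cols <- c("sample_id", "group", cols)
  dplyr::select(out, dplyr::all_of(cols))
}

#' Estimate the optimal Hellinger-divergence cutoff from the control null
#'
#' Separates treatment-associated methylation signal from the within-control
#' fluctuation measured by calling each control replicate against the pooled
#' centroid. Two signal-detection readings are implemented:
#'
#' * `"quantile"`: a Weibull null is fitted by maximum likelihood to the
#'   positive control-derived divergences and the cutoff is its
#'   \eqn{1-\alpha} quantile.
#' * `"youden"`: given treatment divergences as well, the cutoff maximizes
#'   Youden's J = sensitivity + specificity − 1 with control-derived values
#'   as negatives (an optimal-cutpoint estimate in the ROC sense).
#' * `"fdr"`: the empirical-FDR cutpoint — the smallest threshold at which
#'   the expected number of null exceedances (the control-derived null tail,
#'   rescaled to the number of treatment comparisons) is at most `alpha`
#'   times the observed treatment exceedances. When the signal is a small
#'   contamination of a null-dominated mixture, Youden's balanced criterion
#'   is unstable (the two empirical distributions differ only in a thin
#'   tail); the FDR cutpoint targets the purity of the selected set
#'   directly and degrades gracefully.
#'
#' @param null_hd Numeric vector of control-vs-centroid divergences (>= 50).
#' @param method `"quantile"`, `"youden"`, or `"fdr"`.
#' @param alpha Tail probability (quantile method) or target false-discovery
#'   fraction (fdr method); default 0.05.
#' @param treatment_hd Treatment divergences, required for `"youden"` and
#'   `"fdr"`.
#' @return An object of class `md_cutoff` with elements `method`, `cutoff`,
#'   `alpha`, and (quantile method) the fitted Weibull `shape` and `scale`.
#' @export
fit_null_cutoff <- function(null_hd, method = c("quantile", "youden", "fdr"),
                            alpha = 0.05, treatment_hd = NULL) {
  method <- match.arg(method)
  null_hd <- null_hd[is.finite(null_hd)]
  if (length(null_hd) < 50) {
    stop_bad_arg("fit_null_cutoff(): need >= 50 null divergence values, got %d",
                 length(null_hd))
  }
  if (all(null_hd == 0)) {
    stop_bad_arg("fit_null_cutoff(): degenerate null (all zeros)")
  }
  if (method == "quantile") {
    pos <- null_hd[null_hd > 0]
    fit <- fitdistrplus::fitdist(pos, "weibull")
    shape <- unname(fit$estimate["shape"])
    scale <- unname(fit$estimate["scale"])
    cutoff <- stats::qweibull(1 - alpha, shape = shape, scale = scale)
    out <- list(method = "quantile", alpha = alpha, cutoff = cutoff,
                null_family = "weibull", shape = shape, scale = scale,
                n_null = length(pos))
  } else if (method == "fdr") {
    if (is.null(treatment_hd) || length(treatment_hd) == 0) {
      stop_bad_arg("fit_null_cutoff(): fdr method needs treatment_hd")
    }
    treatment_hd <- treatment_hd[is.finite(treatment_hd)]
    st <- sort(treatment_hd)
    sn <- sort(null_hd)
    ratio <- length(treatment_hd) / length(null_hd)
    # candidate thresholds at the observed treatment values: exceedances
    # and expected null exceedances by binary search on the sorted samples
    n_trt_geq <- length(st) - seq_along(st) + 1
    n_null_geq <- length(sn) - findInterval(st - 1e-12, sn)
    efdr <- pmin(1, (n_null_geq * ratio) / n_trt_geq)
    ok <- which(efdr <= alpha)
    if (length(ok) == 0) {
      cutoff <- sn[length(sn)] + abs(sn[length(sn)]) * 1e-6 + 1e-12
      efdr_at <- 0
    } else {
      cutoff <- st[min(ok)]
      efdr_at <- efdr[min(ok)]
    }
    out <- list(method = "fdr", alpha = alpha, cutoff = cutoff,
                efdr = efdr_at, n_null = length(null_hd),
                n_treatment = length(treatment_hd))
  } else {
    if (is.null(treatment_hd) || length(treatment_hd) == 0) {
      stop_bad_arg("fit_null_cutoff(): youden method needs treatment_hd")
    }
    treatment_hd <- treatment_hd[is.finite(treatment_hd)]
    cand <- sort(unique(c(null_hd, treatment_hd)))
    # candidate thresholds sit strictly between observed values, so empirical
    # CDF evaluation reduces to findInterval on the sorted samples
    thr <- c(cand[1] / 2, (cand[-length(cand)] + cand[-1]) / 2,
             cand[length(cand)] + abs(cand[length(cand)]) * 1e-6 + 1e-12)
    sn <- sort(null_hd)
    st <- sort(treatment_hd)
    spec <- findInterval(thr, sn) / length(sn)   # P(null < t)
    sens <- 1 - findInterval(thr, st) / length(st)  # P(trt >= t)
    j <- sens + spec - 1
    cutoff <- thr[which.max(j)]
    out <- list(method = "youden", alpha = alpha, cutoff = cutoff,
                youden_j = max(j), n_null = length(null_hd),
                n_treatment = length(treatment_hd))
  }
  structure(out, class = "md_cutoff")
}

#' @export
print.md_cutoff <- function(x, ...) {
  cat("<md_cutoff> method =", x$method, " cutoff =", signif(x$cutoff, 5), "\n")
  if (x$method == "quantile") {
    cat("  Weibull null: shape =", signif(x$shape, 4),
        " scale =", signif(x$scale, 4), " alpha =", x$alpha, "\n")
  } else {
    cat("  Youden J =", signif(x$youden_j, 4), "\n")
  }
  invisible(x)
}

#' Call differentially methylated positions (DMPs)
#'
#' A site is a DMP iff its absolute methylation level difference exceeds
#' `tv_min` (default 20%) **and** its Hellinger divergence reaches the fitted
#' cutoff. Direction is `"hyper"` when the level difference is positive,
#' `"hypo"` otherwise.
#'
#' @param sample One sample's methylome tibble.
#' @param centroid Pooled reference from [pool_reference()].
#' @param cutoff_model `md_cutoff` from [fit_null_cutoff()].
#' @param tv_min Minimum absolute level difference (default 0.20).
#' @param hd,prior Passed to [methylation_divergence()].
#' @return Tibble of DMPs (divergence record columns plus `direction`).
#' @export
call_dmps <- function(sample, centroid, cutoff_model, tv_min = 0.20,
                      hd = c("weighted", "plain"), prior = NULL) {
  stopifnot(inherits(cutoff_model, "md_cutoff"))
  div <- methylation_divergence(sample, centroid, hd = hd, prior = prior)
  div |>
    dplyr::filter(abs(.data$tv) > tv_min, .data$hd >= cutoff_model$cutoff) |>
    dplyr::mutate(direction = as.character(ifelse(.data$tv > 0, "hyper", "hypo")))
}
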