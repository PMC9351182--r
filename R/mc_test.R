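#' Position-by-base count matrix of candidate windows
#'
#' The N x 4 matrix of base counts over the entire set of motif-candidate
#' windows: entry (i, b) is the number of windows carrying base b at
#' position i. This matrix is the input of the Dirichlet base-composition
#' estimate underlying the Monte-Carlo randomness test.
#'
#' @param windows Window tibble from [extract_windows()] or character vector
#'   of equal-length ACGT sequences.
#' @return N x 4 integer matrix, columns A, C, G, T.
#' @export
count_matrix <- function(windows) {
  seqs <- if (is.data.frame(windows)) windows$seq else windows
  mat <- seqs_to_matrix(seqs)
  bad <- !mat %in% DNA_BASES
  if (any(bad)) {
    stop_bad_arg("count_matrix(): non-ACGT character '%s'", mat[bad][1])
  }
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, DNA_BASES))
  storage.mode(counts) <- "integer"
  rownames(counts) <- seq_len(nrow(counts))
  counts
}

#' Estimate a Dirichlet base-composition model from a count matrix
#'
#' Treats each row (alignment position) of the count matrix as a draw from a
#' Dirichlet-multinomial with a shared parameter vector
#' \eqn{\alpha = (\alpha_A, \alpha_C, \alpha_G, \alpha_T)} and estimates
#' \eqn{\alpha} either by moment matching (Mosimann's estimator: mean
#' proportions give the composition, the mean variance ratio gives the
#' precision \eqn{\alpha_0}) or by the standard fixed-point
#' maximum-likelihood iteration on the digamma score equations (tolerance
#' 1e-8, at most 1000 iterations, initialized from the moment estimate).
#'
#' @param counts N x 4 non-negative integer matrix (rows = positions).
#' @param method `"moment"` (default) or `"fixed-point"`.
#' @return Object of class `md_dirichlet`: `alpha` (named, A/C/G/T),
#'   `method`, and for the fixed-point method `iterations` and `converged`.
#' @export
estimate_dirichlet <- function(counts, method = c("moment", "fixed-point")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) {
    stop_bad_arg("estimate_dirichlet(): need >= 2 rows of counts")
  }
  if (any(counts < 0)) stop_bad_arg("estimate_dirichlet(): negative counts")
  n_row <- rowSums(counts)
  if (any(n_row == 0)) stop_bad_arg("estimate_dirichlet(): zero-sum row")
  props <- counts / n_row
  if (nrow(unique(round(props, 12))) == 1) {
    stop_bad_arg(paste("estimate_dirichlet(): all rows share one composition;",
                       "dispersion is unidentifiable - supply a fixed alpha"))
  }
  alpha <- moment_alpha(counts)
  iterations <- 0L
  converged <- NA
  if (method == "fixed-point") {
    fp <- dirichlet_fixed_point(counts, alpha_init = alpha)
    alpha <- fp$alpha
    iterations <- fp$iterations
    converged <- fp$converged
  }
  structure(list(alpha = setNames(alpha, DNA_BASES), method = method,
                 iterations = iterations, converged = converged,
                 n_positions = nrow(counts), depth = mean(n_row)),
            class = "md_dirichlet")
}

# Mosimann moment estimator for Dirichlet-multinomial rows.
# For row depth n: Var(p_hat_b) = m_b (1 - m_b) (n + a0) / (n (1 + a0)),
# solved for the precision a0 using the variance ratio averaged over bases.
moment_alpha <- function(counts) {
  n_row <- rowSums(counts)
  n <- mean(n_row)
  props <- counts / n_row
  m <- colMeans(props)
  v <- apply(props, 2, stats::var)
  usable <- m > 0 & m < 1 & v > 0
  if (!any(usable)) {
    stop_bad_arg("estimate_dirichlet(): cannot moment-match (no usable base)")
  }
  r <- mean((v / (m * (1 - m)))[usable])
  a0 <- n * (1 - r) / (r * n - 1)
  if (!is.finite(a0) || a0 <= 0) {
    stop_bad_arg(paste("estimate_dirichlet(): moment matching failed",
                       "(dispersion outside the Dirichlet-multinomial range)"))
  }
  pmax(a0 * m, 1e-8)
}

# Minka's fixed-point MLE update for the Dirichlet-multinomial.
dirichlet_fixed_point <- function(counts, alpha_init, tol = 1e-8,
                                  max_iter = 1000L) {
  alpha <- alpha_init
  n_row <- rowSums(counts)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a0 <- sum(alpha)
    denom <- sum(digamma(n_row + a0) - digamma(a0))
    num <- colSums(digamma(sweep(counts, 2, alpha, "+")) -
                     matrix(digamma(alpha), nrow(counts), length(alpha),
                            byrow = TRUE))
    new_alpha <- alpha * num / denom
    new_alpha <- pmax(new_alpha, 1e-10)
    if (max(abs(new_alpha - alpha)) < tol) {
      alpha <- new_alpha
      converged <- TRUE
      break
    }
    alpha <- new_alpha
  }
  list(alpha = alpha, iterations = it, converged = converged)
}

#' @export
print.md_dirichlet <- function(x, ...) {
  cat("<md_dirichlet> method =", x$method, "\n  alpha =",
      paste(sprintf("%s=%.4g", names(x$alpha), x$alpha), collapse = " "), "\n")
  invisible(x)
}

#' Posterior base probabilities under the Dirichlet prior
#'
#' \eqn{\hat p_i = (n_i + \alpha_i) / (|n| + |\alpha|)}: observed counts
#' smoothed by the estimated pseudo-counts. Always a probability vector.
#'
#' @param n_vec Length-4 non-negative count vector (A, C, G, T order).
#' @param alpha Length-4 positive Dirichlet parameters or `md_dirichlet`.
#' @return Length-4 probability vector summing to 1.
#' @export
posterior_probs <- function(n_vec, alpha) {
  if (inherits(alpha, "md_dirichlet")) alpha <- alpha$alpha
  if (any(alpha <= 0)) stop_bad_arg("posterior_probs(): alpha must be > 0")
  (n_vec + alpha) / (sum(n_vec) + sum(alpha))
}

#' Simulate a random MSA under the Dirichlet base-composition model
#'
#' For each of the `n_cols` alignment columns independently, a base
#' probability vector is drawn from the Dirichlet(alpha) distribution (via
#' normalized gamma variates) and `n_rows` bases are then drawn i.i.d. from
#' it. Column-wise draws make the null a *composition-randomness* null: base
#' composition fluctuates by position, but no cross-row conservation is
#' imposed. Deterministic given `seed`.
#'
#' @param n_rows,n_cols MSA dimensions (M >= 2 rows, N >= 1 columns).
#' @param model `md_dirichlet` or a length-4 positive alpha vector.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return Character vector of `n_rows` sequences of length `n_cols`.
#' @export
simulate_msa <- function(n_rows, n_cols, model, seed = NULL) {
  if (inherits(model, "md_dirichlet")) model <- model$alpha
  if (length(model) != 4 || any(!is.finite(model)) || any(model <= 0)) {
    stop_bad_arg("simulate_msa(): alpha must be four positive numbers")
  }
  if (n_rows < 2 || n_cols < 1) {
    stop_bad_arg("simulate_msa(): need n_rows >= 2 and n_cols >= 1")
  }
  with_local_seed(seed, {
    mat <- matrix("", n_rows, n_cols)
    for (j in seq_len(n_cols)) {
      g <- stats::rgamma(4, shape = model)
      if (sum(g) == 0) g <- rep(1, 4)
      mat[, j] <- sample(DNA_BASES, n_rows, replace = TRUE, prob = g / sum(g))
    }
    apply(mat, 1, paste0, collapse = "")
  })
}

#' Monte-Carlo p-value for an observed motif score
#'
#' Simulates `n_sims` random MSAs of the observed shape under the Dirichlet
#' model, scores each with [motif_score()], and estimates
#' \eqn{p = \frac{1}{N_s + 1} \sum_{i=0}^{N_s} 1[S_i \ge S_0]} — the sum
#' includes the observed alignment itself (the i = 0 term), so
#' \eqn{p \ge 1/(N_s + 1)} always. Simulated \eqn{-\infty} scores satisfy
#' the inequality only when \eqn{S_0 = -\infty}.
#'
#' @param s_observed Observed motif score \eqn{S_0}.
#' @param n_rows,n_cols Shape of the observed MSA.
#' @param model `md_dirichlet` or length-4 alpha vector.
#' @param n_sims Number of simulated MSAs (default 1000).
#' @param seed Optional seed for reproducibility.
#' @return One-row tibble: `s_observed`, `n_sims`, `n_geq` (count of scores
#'   >= S0, including the observed), `p_value`.
#' @export
mc_pvalue <- function(s_observed, n_rows, n_cols, model, n_sims = 1000,
                      seed = NULL) {
  if (n_sims < 1) stop_bad_arg("mc_pvalue(): n_sims must be >= 1")
  sims <- with_local_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      motif_score(simulate_msa(n_rows, n_cols, model))$score_s
    }, numeric(1))
  })
  n_geq <- 1L + sum(sims >= s_observed)
  tibble::tibble(s_observed = s_observed, n_sims = as.integer(n_sims),
                 n_geq = n_geq, p_value = n_geq / (n_sims + 1))
}

#' Monte-Carlo randomness test for every surviving motif cluster
#'
#' Estimates (or accepts) the global Dirichlet model from the entire set of
#' candidate windows, then computes the Monte-Carlo p-value of each
#' cluster's motif score at the cluster's own MSA shape. Per-cluster
#' simulation seeds are derived deterministically from `seed`.
#'
#' @param clusters `md_motif_clusters` from [motif_clusters()].
#' @param model `md_dirichlet`, alpha vector, or `NULL` to estimate from all
#'   cluster members' windows.
#' @param n_sims Simulations per cluster (default 1000).
#' @param seed Integer seed.
#' @param method Dirichlet estimation method when `model` is `NULL`.
#' @return The cluster summary tibble with `p_value`, `n_geq`, `n_sims`
#'   columns appended; the fitted model is attached as attribute `model`.
#' @export
test_motif_clusters <- function(clusters, model = NULL, n_sims = 1000,
                                seed = 1L, method = "moment") {
  stopifnot(inherits(clusters, "md_motif_clusters"))
  if (is.null(model)) {
    model <- estimate_dirichlet(count_matrix(clusters$members$seq),
                                method = method)
  }
  res <- purrr::map_dfr(seq_len(nrow(clusters$clusters)), function(i) {
    row <- clusters$clusters[i, ]
    msa <- clusters$msas[[as.character(row$cluster_id)]]
    mc <- mc_pvalue(row$score_s, n_rows = length(msa),
                    n_cols = nchar(msa[1]), model = model, n_sims = n_sims,
                    seed = derive_seed(seed, i))
    dplyr::bind_cols(row, mc[, c("n_geq", "p_value")])
  })
  res$n_sims <- as.integer(n_sims)
  attr(res, "model") <- model
  res
}
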