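#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_null_cutoff Tidy the fitted null/cutoff model: one row per
#'   parameter.
#' @param x,object An `md_cutoff`.
#' @param ... Unused.
#' @method tidy md_cutoff
#' @export
tidy.md_cutoff <- function(x, ...) {
  if (x$method == "quantile") {
    tibble::tibble(term = c("shape", "scale", "cutoff"),
                   estimate = c(x$shape, x$scale, x$cutoff))
  } else {
    tibble::tibble(term = c("cutoff", "youden_j"),
                   estimate = c(x$cutoff, x$youden_j))
  }
}

#' @describeIn fit_null_cutoff One-row model summary.
#' @method glance md_cutoff
#' @export
glance.md_cutoff <- function(x, ...) {
  tibble::tibble(method = x$method, cutoff = x$cutoff, alpha = x$alpha,
                 n_null = x$n_null)
}

#' @describeIn pca_lda Per-sample discriminant coordinates.
#' @param x,object An `md_pca_lda`.
#' @param ... Unused.
#' @method tidy md_pca_lda
#' @export
tidy.md_pca_lda <- function(x, ...) x$discriminants

#' @describeIn pca_lda One-row summary: retained components and variance.
#' @method glance md_pca_lda
#' @export
glance.md_pca_lda <- function(x, ...) {
  tibble::tibble(
    K = x$K, k_lda = x$k_lda,
    retained_variance = sum(x$var_frac[seq_len(x$K)]),
    n_samples = nrow(x$scores),
    n_classes = length(unique(x$scores$group)),
    training_accuracy = mean(x$assigned == x$scores$group)
  )
}

#' @describeIn correlation_network Edge list as a tibble.
#' @param x,object An `md_network`.
#' @param ... Unused.
#' @method tidy md_network
#' @export
tidy.md_network <- function(x, ...) x$edges

#' @describeIn correlation_network One-row network summary.
#' @method glance md_network
#' @export
glance.md_network <- function(x, ...) {
  tibble::tibble(tau = x$tau, method = x$method,
                 n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 connected_genes = x$connected_genes)
}

#' @describeIn select_hubs Per-node cluster assignment and hub flag.
#' @param x,object An `md_hubs`.
#' @param ... Unused.
#' @method tidy md_hubs
#' @export
tidy.md_hubs <- function(x, ...) x$nodes

#' @describeIn select_hubs One-row hub-selection summary.
#' @method glance md_hubs
#' @export
glance.md_hubs <- function(x, ...) {
  tibble::tibble(k = x$k, n_nodes = nrow(x$nodes), n_hubs = length(x$hubs),
                 degenerate = x$degenerate)
}

#' @describeIn estimate_dirichlet One row per base with its alpha estimate.
#' @param x,object An `md_dirichlet`.
#' @param ... Unused.
#' @method tidy md_dirichlet
#' @export
tidy.md_dirichlet <- function(x, ...) {
  tibble::tibble(base = names(x$alpha), alpha = unname(x$alpha))
}

#' @describeIn estimate_dirichlet One-row estimation summary.
#' @method glance md_dirichlet
#' @export
glance.md_dirichlet <- function(x, ...) {
  tibble::tibble(method = x$method, precision = sum(x$alpha),
                 iterations = x$iterations, converged = x$converged,
                 n_positions = x$n_positions, depth = x$depth)
}
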