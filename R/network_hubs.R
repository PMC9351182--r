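#' Node centrality attributes of an undirected network
#'
#' Computes six standard node attributes — betweenness centrality, closeness
#' centrality, average shortest-path length, local clustering coefficient,
#' degree, and eccentricity — on the simple undirected graph induced by an
#' edge list. Duplicate edges and self-loops are dropped with a warning.
#' Path-based attributes (betweenness, closeness, average path length,
#' eccentricity) are computed within each connected component and normalized
#' by component size; for singleton components they are 0, and the local
#' clustering coefficient of nodes with fewer than two neighbours is 0.
#'
#' @param edges Two-column data frame / tibble of node IDs (extra columns
#'   ignored), or an [igraph::graph] object.
#' @return Tibble: `node_id`, `betweenness`, `closeness`,
#'   `avg_shortest_path_length`, `clustering_coefficient`, `degree`,
#'   `eccentricity`, in node order.
#' @export
node_attributes <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- edges
  } else {
    edges <- as.data.frame(edges)
    if (nrow(edges) == 0) stop_bad_arg("node_attributes(): empty graph")
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  }
  if (igraph::vcount(g) == 0) stop_bad_arg("node_attributes(): empty graph")
  gs <- igraph::simplify(g)
  if (igraph::ecount(gs) < igraph::ecount(g)) {
    warn(sprintf("node_attributes(): dropped %d duplicate/self-loop edge(s)",
                 igraph::ecount(g) - igraph::ecount(gs)))
  }
  g <- gs
  comp <- igraph::components(g)
  res <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    n <- igraph::vcount(sub)
    if (n == 1) {
      res[[ci]] <- tibble::tibble(
        node_id = igraph::V(sub)$name,
        betweenness = 0, closeness = 0, avg_shortest_path_length = 0,
        clustering_coefficient = 0, degree = 0L, eccentricity = 0
      )
      next
    }
    d <- igraph::distances(sub)
    cc <- suppressWarnings(
      igraph::transitivity(sub, type = "local", isolates = "zero"))
    res[[ci]] <- tibble::tibble(
      node_id = igraph::V(sub)$name,
      betweenness = unname(igraph::betweenness(sub, normalized = n > 2)),
      closeness = unname((n - 1) / rowSums(d)),
      avg_shortest_path_length = unname(rowSums(d) / (n - 1)),
      clustering_coefficient = unname(ifelse(is.nan(cc), 0, cc)),
      degree = unname(igraph::degree(sub)),
      eccentricity = unname(apply(d, 1, max))
    )
  }
  out <- dplyr::bind_rows(res)
  out[match(igraph::V(g)$name, out$node_id), ]
}

# deterministic k-means++ seeding: farthest-point-weighted sampling under a
# private RNG; ties broken by lowest row index via sample's cumulative rule
kmeanspp_centers <- function(x, k, seed) {
  with_local_seed(seed, {
    n <- nrow(x)
    centers <- integer(k)
    centers[1] <- sample.int(n, 1)
    if (k > 1) {
      for (j in 2:k) {
        d2 <- apply(x, 1, function(r) {
          min(colSums((t(x[centers[seq_len(j - 1)], , drop = FALSE]) - r)^2))
        })
        if (all(d2 == 0)) {
          centers[j:k] <- rep(centers[1], k - j + 1)
          break
        }
        centers[j] <- sample.int(n, 1, prob = d2 / sum(d2))
      }
    }
    centers
  })
}

#' Select network hub genes by k-means on centrality attributes
#'
#' Standardizes the six node attributes (z-scores; the two distance-like
#' attributes, average shortest-path length and eccentricity, are negated so
#' that larger always means more central), clusters the nodes with k-means
#' (Euclidean distance, deterministic k-means++ seeding, `iterations`
#' iterations), and selects as hubs the members of the cluster with the
#' highest mean standardized, orientation-corrected centrality.
#'
#' If every node has identical attributes the clustering is degenerate: a
#' warning is raised and all nodes are reported as hubs in one cluster.
#'
#' @param attrs Attribute tibble from [node_attributes()].
#' @param k Number of clusters (default 3).
#' @param iterations Maximum k-means iterations (default 300).
#' @param seed Seed for the deterministic k-means++ initialization.
#' @return Object of class `md_hubs`: `nodes` (tibble `node_id`, `cluster`,
#'   `centrality_index`, `is_hub`), `cluster_summary` (per-cluster mean
#'   centrality, size, `is_hub_cluster`), `hubs` (character vector), `k`.
#' @export
select_hubs <- function(attrs, k = 3, iterations = 300, seed = 1L) {
  attr_cols <- c("betweenness", "closeness", "avg_shortest_path_length",
                 "clustering_coefficient", "degree", "eccentricity")
  x <- as.matrix(attrs[, attr_cols])
  if (nrow(x) < k) {
    stop_bad_arg("select_hubs(): k = %d exceeds %d nodes", k, nrow(x))
  }
  z <- apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  # orient distance-like attributes so larger = more central
  z[, "avg_shortest_path_length"] <- -z[, "avg_shortest_path_length"]
  z[, "eccentricity"] <- -z[, "eccentricity"]
  centrality_index <- rowMeans(z)
  if (nrow(unique(z)) == 1) {
    warn("select_hubs(): all nodes have identical attributes; degenerate clustering, every node reported as hub")
    nodes <- tibble::tibble(node_id = attrs$node_id, cluster = 1L,
                            centrality_index = centrality_index,
                            is_hub = TRUE)
    out <- list(nodes = nodes,
                cluster_summary = tibble::tibble(
                  cluster = 1L, size = nrow(nodes),
                  mean_centrality = mean(centrality_index),
                  is_hub_cluster = TRUE),
                hubs = nodes$node_id, k = 1L, degenerate = TRUE)
    class(out) <- "md_hubs"
    return(out)
  }
  init <- kmeanspp_centers(z, k, seed)
  cz <- unique(z[init, , drop = FALSE])  # guard against coincident seeds
  km <- stats::kmeans(z, centers = cz, iter.max = iterations)
  summary <- tibble::tibble(cluster = seq_len(max(km$cluster)),
                            size = as.integer(table(km$cluster))) |>
    dplyr::mutate(mean_centrality = vapply(.data$cluster, function(cl) {
      mean(centrality_index[km$cluster == cl])
    }, numeric(1)))
  hub_cluster <- summary$cluster[which.max(summary$mean_centrality)]
  summary$is_hub_cluster <- summary$cluster == hub_cluster
  nodes <- tibble::tibble(node_id = attrs$node_id,
                          cluster = as.integer(km$cluster),
                          centrality_index = centrality_index,
                          is_hub = km$cluster == hub_cluster)
  out <- list(nodes = nodes,
              cluster_summary = dplyr::arrange(
                summary, dplyr::desc(.data$mean_centrality)),
              hubs = nodes$node_id[nodes$is_hub], k = k,
              degenerate = FALSE)
  class(out) <- "md_hubs"
  out
}

#' @export
print.md_hubs <- function(x, ...) {
  cat("<md_hubs>", length(x$hubs), "hub(s) from", nrow(x$nodes),
      "nodes in", x$k, "clusters\n")
  invisible(x)
}
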