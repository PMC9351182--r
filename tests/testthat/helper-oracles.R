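# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take the slow, definition-level route.

# Ward minimum-variance agglomeration via the Lance-Williams update on
# squared Euclidean distances. Returns the sequence of partitions (one per
# merge) and the merge heights (Ward distances, on the squared scale).
oracle_ward_partitions <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dcur <- d2
  diag(dcur) <- Inf
  partitions <- list()
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 1) break
    idx <- which(dcur == min(dcur), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- min(idx[1, ]); j <- max(idx[1, ])
    heights <- c(heights, dcur[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- vapply(seq_len(k), function(h) {
      if (h == i || h == j) return(Inf)
      nh <- sizes[h]
      ((ni + nh) * dcur[i, h] + (nj + nh) * dcur[j, h] - nh * dcur[i, j]) /
        (ni + nj + nh)
    }, numeric(1))
    active[[i]] <- sort(c(active[[i]], active[[j]]))
    sizes[i] <- ni + nj
    dcur[i, ] <- new_d; dcur[, i] <- new_d
    active <- active[-j]; sizes <- sizes[-j]
    dcur <- dcur[-j, -j, drop = FALSE]
    diag(dcur) <- Inf
    membership <- integer(n)
    for (c in seq_along(active)) membership[active[[c]]] <- c
    partitions[[length(partitions) + 1]] <- membership
  }
  list(partitions = partitions, heights = heights)
}

# UPGMA (average linkage, size-weighted means) returning partitions.
oracle_upgma_partitions <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dcur <- d
  diag(dcur) <- Inf
  partitions <- list()
  repeat {
    k <- length(active)
    if (k == 1) break
    idx <- which(dcur == min(dcur), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- min(idx[1, ]); j <- max(idx[1, ])
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- vapply(seq_len(k), function(h) {
      if (h == i || h == j) return(Inf)
      (ni * dcur[i, h] + nj * dcur[j, h]) / (ni + nj)
    }, numeric(1))
    active[[i]] <- sort(c(active[[i]], active[[j]]))
    sizes[i] <- ni + nj
    dcur[i, ] <- new_d; dcur[, i] <- new_d
    active <- active[-j]; sizes <- sizes[-j]
    dcur <- dcur[-j, -j, drop = FALSE]
    diag(dcur) <- Inf
    membership <- integer(n)
    for (c in seq_along(active)) membership[active[[c]]] <- c
    partitions[[length(partitions) + 1]] <- membership
  }
  partitions
}

# canonical form of a partition vector, for label-free comparison
canon_partition <- function(m) as.integer(factor(m, levels = unique(m)))

# All-pairs BFS node attributes on an undirected simple graph given as an
# adjacency list; includes Brandes-free betweenness by explicit path
# counting over a distance-ordered DP.
oracle_node_attrs <- function(adj) {
  n <- length(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)  # number of shortest paths
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!is.finite(dist[s, w])) {
            dist[s, w] <- dist[s, v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == dist[s, v] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  betw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(dist[s, t])) next
        if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          betw[v] <- betw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  comp_of <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp_of[s] == 0) {
      cid <- cid + 1
      comp_of[is.finite(dist[s, ])] <- cid
    }
  }
  res <- data.frame(node = seq_len(n), betweenness = NA_real_,
                    closeness = NA_real_, avg_spl = NA_real_,
                    clustering = NA_real_, degree = NA_real_,
                    eccentricity = NA_real_)
  for (v in seq_len(n)) {
    comp <- which(comp_of == comp_of[v])
    nc <- length(comp)
    others <- setdiff(comp, v)
    res$degree[v] <- length(adj[[v]])
    if (nc == 1) {
      res$betweenness[v] <- 0; res$closeness[v] <- 0
      res$avg_spl[v] <- 0; res$eccentricity[v] <- 0
      res$clustering[v] <- 0
      next
    }
    res$betweenness[v] <- if (nc > 2) {
      betw[v] / ((nc - 1) * (nc - 2) / 2)
    } else betw[v]
    res$closeness[v] <- (nc - 1) / sum(dist[v, others])
    res$avg_spl[v] <- mean(dist[v, others])
    res$eccentricity[v] <- max(dist[v, others])
    nb <- adj[[v]]
    if (length(nb) < 2) {
      res$clustering[v] <- 0
    } else {
      links <- 0
      for (a in seq_along(nb)) {
        for (b in seq_along(nb)) {
          if (a < b && nb[b] %in% adj[[nb[a]]]) links <- links + 1
        }
      }
      res$clustering[v] <- links / choose(length(nb), 2)
    }
  }
  res
}

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (R's rule: sum probabilities <= observed,
# with the 1e-7 relative tolerance fisher.test uses)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # col 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# definition-level motif score: double loop over pairs and positions
oracle_motif_score <- function(msa) {
  rows <- strsplit(msa, "")
  M <- length(rows); N <- length(rows[[1]])
  scores <- c()
  for (j in seq_len(M - 1)) {
    for (k in (j + 1):M) {
      matches <- 0
      for (i in seq_len(N)) {
        bj <- rows[[j]][i]; bk <- rows[[k]][i]
        if (bj == bk && bj %in% c("A", "C", "G", "T")) matches <- matches + 1
      }
      scores <- c(scores, log2(matches))
    }
  }
  S <- mean(scores)
  list(score_s = S, info_i = log2(N) - S)
}

# Dirichlet-multinomial sampler for parameter-recovery tests
r_dirichlet_multinom <- function(n_rows, depth, alpha) {
  t(vapply(seq_len(n_rows), function(i) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    as.integer(stats::rmultinom(1, depth, g / sum(g)))
  }, integer(length(alpha))))
}

random_msa <- function(M, N, gap_frac = 0) {
  chars <- c("A", "C", "G", "T")
  if (gap_frac > 0) chars <- c(chars, "-")
  probs <- c(rep((1 - gap_frac) / 4, 4), if (gap_frac > 0) gap_frac)
  vapply(seq_len(M), function(i) {
    paste0(sample(chars, N, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}
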