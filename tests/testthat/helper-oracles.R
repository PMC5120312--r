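# Independent oracles used to cross-check the package's statistics. Each is
# deliberately written from the textbook definition, not by reusing package
# internals.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j) over sorted p-values.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  v <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(v)))
  pmin(1, q)[order(o)]
}

# Exact two-sided Mann-Whitney p by enumeration of all equally likely group
# assignments of the pooled data (doubled tail, capped at 1).
mw_enumerate_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  n <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_all <- apply(utils::combn(m + n, m), 2L, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  u_obs <- u_of(a, b)
  if (u_obs > m * n / 2) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

# Two-sided hypergeometric p by explicit mass summation from choose().
hyper_brute_p <- function(k, q, K, N) {
  kk <- max(0L, q + K - N):min(q, K)
  mass <- choose(K, kk) * choose(N - K, q - kk) / choose(N, q)
  min(1, 2 * min(sum(mass[kk <= k]), sum(mass[kk >= k])))
}

# Minimal independent Markov clustering: dense expand/inflate loop without
# pruning, clusters read as connected components of the limit matrix's
# nonzero pattern.
reference_mcl_membership <- function(adj, inflation = 2) {
  diag(adj) <- 1
  m <- sweep(adj, 2L, colSums(adj), "/")
  for (it in 1:300) {
    m2 <- (m %*% m)^inflation
    m2 <- sweep(m2, 2L, colSums(m2), "/")
    if (max(abs(m2 - m)) < 1e-12) {
      m <- m2
      break
    }
    m <- m2
  }
  m[m < 1e-8] <- 0
  g <- igraph::graph_from_adjacency_matrix(
    ((m + t(m)) > 0) * 1, mode = "undirected"
  )
  igraph::components(g)$membership
}

# Midranks and Pearson-on-ranks from first principles.
hand_midranks <- function(v) {
  r <- numeric(length(v))
  sv <- sort(v)
  for (u in unique(v)) {
    r[v == u] <- mean(which(sv == u))
  }
  r
}

hand_spearman <- function(x, y) {
  rx <- hand_midranks(x)
  ry <- hand_midranks(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}

# Build a mirvalve-style graph object from an explicit edge list.
edge_graph <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$node_a, edges$node_b)))
  structure(
    list(nodes = nodes, edges = edges, threshold = 0, mode = "positive"),
    class = "mirvalve_graph"
  )
}

# 12-node graph of three 4-cliques joined by single bridges.
planted_clique_graph <- function() {
  cliques <- list(1:4, 5:8, 9:12)
  ed <- do.call(rbind, lapply(cliques, function(v) t(utils::combn(v, 2L))))
  ed <- rbind(ed, c(4L, 5L), c(8L, 9L))
  edges <- tibble::tibble(
    node_a = sprintf("n%02d", ed[, 1L]),
    node_b = sprintf("n%02d", ed[, 2L]),
    weight = 1
  )
  list(
    graph = edge_graph(edges, nodes = sprintf("n%02d", 1:12)),
    truth = rep(1:3, each = 4L),
    adjacency = {
      a <- matrix(0, 12, 12, dimnames = list(sprintf("n%02d", 1:12),
                                             sprintf("n%02d", 1:12)))
      a[ed] <- 1
      a + t(a)
    }
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Paired-sample subset used by the integration stage (first 10 per group).
paired_subset <- function(expr, n_each = 10L) {
  samp <- c(sprintf("case_%02d", seq_len(n_each)),
            sprintf("ctrl_%02d", seq_len(n_each)))
  expr[, c("feature_id", samp)]
}

pair_key <- function(mirna, gene) paste(mirna, gene, sep = "\r")
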