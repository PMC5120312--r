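#' Thresholded Pearson co-expression graph
#'
#' Builds the weighted undirected graph whose nodes are the requested
#' features (typically the differentially expressed miRNAs) and whose edges
#' connect pairs with Pearson correlation above the threshold. The default
#' mode keeps only positive correlations (`r > threshold`); `"absolute"`
#' keeps `|r| > threshold`. Edge weights are stored as the signed r.
#' Constant features are dropped with a warning.
#'
#' @param x expression tibble.
#' @param features character vector of feature IDs to include; default all.
#' @param threshold correlation threshold (default 0.5).
#' @param mode `"positive"` or `"absolute"`.
#' @return An object of class `mirvalve_graph`: list with `nodes`
#'   (character), `edges` (tibble node_a, node_b, weight), `threshold`,
#'   `mode`.
#' @export
correlation_graph <- function(x, features = NULL, threshold = 0.5,
                              mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  m <- expr_to_matrix(x)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing) > 0L) {
      abort(paste0("features not in expression table: ",
                   paste(head(missing, 5L), collapse = ", ")))
    }
    m <- m[features, , drop = FALSE]
  }
  if (ncol(m) < 3L) abort("need at least 3 samples for correlation.")
  if (abs(threshold) > 1) abort("`threshold` must lie in [-1, 1].")
  m <- m[order(rownames(m)), , drop = FALSE]
  m <- drop_constant_features(m, "correlation graph construction")
  nodes <- rownames(m)
  r <- stats::cor(t(m))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  w <- r[idx]
  pass <- if (mode == "positive") w > threshold else abs(w) > threshold
  edges <- tibble::tibble(
    node_a = nodes[idx[pass, 1L]],
    node_b = nodes[idx[pass, 2L]],
    weight = w[pass]
  )
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold, mode = mode),
    class = "mirvalve_graph"
  )
}

#' @export
print.mirvalve_graph <- function(x, ...) {
  cat(sprintf("<mirvalve_graph> %d nodes, %d edges (%s r > %g)\n",
              length(x$nodes), nrow(x$edges), x$mode, x$threshold))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  g
}

#' Per-node degree of a correlation graph
#'
#' @param graph a `mirvalve_graph`.
#' @return Tibble (node, degree) sorted by decreasing degree then node ID;
#'   isolated nodes are included with degree 0.
#' @export
degree_table <- function(graph) {
  stopifnot(inherits(graph, "mirvalve_graph"))
  deg <- table(factor(c(graph$edges$node_a, graph$edges$node_b),
                      levels = graph$nodes))
  tibble::tibble(node = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(degree), node)
}

# column-normalize a non-negative matrix; zero columns are left untouched
mcl_normalize <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2L, cs, "/")
}

#' Markov Clustering (MCL) of a weighted graph
#'
#' From-scratch implementation of the Markov Cluster algorithm: the
#' self-loop-augmented adjacency matrix of edge-weight magnitudes is column
#' normalized into a random-walk transition matrix and then alternately
#' expanded (matrix power) and inflated (entrywise power followed by column
#' renormalization), with small entries pruned, until the matrix change
#' falls below `tol`. Clusters are read off the attractor rows (rows
#' retaining mass on the diagonal): attractors that still exchange mass form
#' one cluster, and every node is assigned to the attractor from which it
#' receives the most incoming mass, ties resolved toward the smallest
#' cluster ID. Inflation controls granularity; 2.0 is the conventional
#' default.
#'
#' @param graph a `mirvalve_graph` (or any list with `nodes` and an `edges`
#'   tibble of node_a, node_b, weight).
#' @param inflation entrywise inflation power, > 1.
#' @param expansion matrix-power expansion, integer >= 2.
#' @param prune_below entries below this magnitude are zeroed each
#'   iteration (the column maximum is always retained).
#' @param max_iter,tol iteration controls; non-convergence returns a result
#'   with `converged = FALSE` and a warning.
#' @return A tibble of class `mirvalve_mcl` (node, cluster) with attributes
#'   `converged`, `iterations`, `n_clusters`, `params`, and the final
#'   transition matrix in `attr(, "final_matrix")`. `tidy()` returns the
#'   assignment; `glance()` a one-row summary.
#' @export
mcl <- function(graph, inflation = 2, expansion = 2L, prune_below = 1e-5,
                max_iter = 100L, tol = 1e-6) {
  stopifnot(is.list(graph), !is.null(graph$nodes))
  if (length(graph$nodes) == 0L) abort("graph has no nodes.")
  if (inflation <= 1) abort("`inflation` must be > 1.")
  expansion <- check_count(expansion, "expansion", 2L)
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges) > 0L) {
    ia <- match(graph$edges$node_a, nodes)
    ib <- match(graph$edges$node_b, nodes)
    w <- abs(graph$edges$weight)
    a[cbind(ia, ib)] <- w
    a[cbind(ib, ia)] <- w
  }
  diag(a) <- 1  # self loops stabilize the walk
  m <- mcl_normalize(a)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- m
    # expansion: matrix power
    e <- m
    for (k in seq_len(expansion - 1L)) e <- e %*% m
    # inflation: entrywise power, then renormalize
    m <- mcl_normalize(e^inflation)
    # prune small entries but never empty a column
    keep_max <- cbind(max.col(t(m)), seq_len(n))
    small <- m < prune_below
    small[keep_max] <- FALSE
    m[small] <- 0
    m <- mcl_normalize(m)
    if (max(abs(m - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge in %d iterations.", max_iter))
  }

  attractors <- which(diag(m) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # attractors exchanging mass belong to one attractor system
  sub <- (m[attractors, attractors, drop = FALSE] > 0) |
    t(m[attractors, attractors, drop = FALSE] > 0)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sub * 1, mode = "undirected")
  )$membership
  # relabel attractor systems 1..K by first node in sorted order
  sys_of_attractor <- match(comp, unique(comp[order(attractors)]))

  assignment <- integer(n)
  for (j in seq_len(n)) {
    mass <- m[attractors, j]
    if (max(mass) <= 0) {
      # unreached node (only possible without convergence): own singleton
      assignment[j] <- NA_integer_
      next
    }
    best <- which(mass == max(mass))
    assignment[j] <- min(sys_of_attractor[best])
  }
  if (anyNA(assignment)) {
    extra <- max(sys_of_attractor)
    for (j in which(is.na(assignment))) {
      extra <- extra + 1L
      assignment[j] <- extra
    }
  }
  # final relabel by order of first appearance over sorted nodes
  assignment <- match(assignment, unique(assignment))

  out <- tibble::tibble(node = nodes, cluster = assignment)
  structure(out,
    class = c("mirvalve_mcl", class(out)),
    converged = converged,
    iterations = iter,
    n_clusters = length(unique(assignment)),
    params = list(inflation = inflation, expansion = expansion,
                  prune_below = prune_below, max_iter = max_iter, tol = tol),
    final_matrix = m
  )
}

#' @export
tidy.mirvalve_mcl <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mirvalve_mcl <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_nodes = nrow(x),
    n_clusters = attr(x, "n_clusters"),
    converged = attr(x, "converged"),
    iterations = attr(x, "iterations"),
    inflation = p$inflation,
    expansion = p$expansion
  )
}
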