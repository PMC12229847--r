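#' Build an undirected interaction network restricted to a gene list
#'
#' Induces the subgraph of a canonical edge list on \code{restrict_to}
#' (when given), removes isolated nodes (degree zero) with a report, and
#' labels connected components.
#'
#' @param edges Canonical edge data frame (see [read_edges()]).
#' @param restrict_to Optional gene list defining the induced subgraph.
#' @return List of class \code{"metab_network"}: \code{graph} (igraph),
#'   \code{nodes}, \code{degree}, \code{components} (named integer ids,
#'   0-based), \code{isolated} (nodes removed), \code{n_edges}.
#' @export
build_network <- function(edges, restrict_to = NULL) {
  stopifnot(is.data.frame(edges), nrow(edges) > 0L)
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  isolated <- character(0)
  if (!is.null(restrict_to)) {
    keep <- intersect(igraph::V(g)$name, restrict_to)
    isolated <- setdiff(restrict_to, keep)  # genes with no edge at all
    g <- igraph::induced_subgraph(g, keep)
  }
  deg <- igraph::degree(g)
  iso_now <- names(deg)[deg == 0]
  isolated <- c(isolated, iso_now)
  if (length(iso_now) > 0L)
    g <- igraph::delete_vertices(g, iso_now)
  if (igraph::vcount(g) == 0L || igraph::ecount(g) == 0L)
    stop("empty network after restriction")
  comp <- igraph::components(g)
  structure(list(graph = g, nodes = igraph::V(g)$name,
                 degree = igraph::degree(g),
                 components = stats::setNames(comp$membership - 1L,
                                              igraph::V(g)$name),
                 isolated = isolated,
                 n_edges = igraph::ecount(g)),
            class = "metab_network")
}

#' Random-walk energy scores on an interaction network
#'
#' Every node starts with one unit of energy (total energy = number of
#' nodes, so a score of 2 means twice the network-average energy). At each
#' iteration a node keeps a \code{laziness} fraction of its energy and sends
#' the rest split equally among its neighbours; iteration continues until
#' the L1 change falls below \code{tol}. The converged energy per node is
#' its random-walk (RW) score. On each connected component the limit is the
#' degree-proportional stationary distribution,
#' \eqn{(\text{component energy}) \cdot \deg(v) / \sum_u \deg(u)}; the lazy
#' step guarantees convergence on bipartite components without changing that
#' limit.
#'
#' @param net A [build_network()] result.
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum iterations.
#' @param laziness Fraction of energy retained in place per iteration, in
#'   \eqn{[0, 1)}.
#' @param trace If \code{TRUE}, record per-iteration energy totals and the
#'   score trajectory sums (used to audit energy conservation).
#' @return List of class \code{"walk_result"}: \code{rw_score} (named),
#'   \code{iterations}, \code{residual}, \code{components},
#'   and, when traced, \code{energy_trace}.
#' @export
random_walk_scores <- function(net, tol = 1e-10, max_iter = 100000L,
                               laziness = 0.5, trace = FALSE) {
  stopifnot(inherits(net, "metab_network"))
  if (laziness < 0 || laziness >= 1) stop("laziness must be in [0, 1)")
  A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  deg <- rowSums(A)
  if (any(deg == 0)) stop("network contains isolated nodes; rebuild it first")
  n <- nrow(A)
  # column u of P sends e(u)/deg(u) to each neighbour of u
  P <- A / rep(deg, each = n)  # P[v, u] = A[v, u] / deg(u)
  e <- rep(1, n)
  energy_trace <- if (trace) numeric(0) else NULL
  it <- 0L
  repeat {
    it <- it + 1L
    e_new <- laziness * e + (1 - laziness) * as.vector(P %*% e)
    resid <- sum(abs(e_new - e))
    e <- e_new
    if (trace) energy_trace <- c(energy_trace, sum(e))
    if (resid < tol) break
    if (it >= max_iter)
      stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
                   max_iter, resid))
  }
  names(e) <- net$nodes
  structure(list(rw_score = e, iterations = it, residual = resid,
                 components = net$components, degree = net$degree,
                 energy_trace = energy_trace),
            class = "walk_result")
}

#' Closed-form stationary RW scores
#'
#' The analytic limit of [random_walk_scores()]: on each connected
#' component, \eqn{(\text{component size}) \cdot \deg(v) / \sum \deg(u)}
#' (each node starts with energy 1, so the component energy equals its
#' size). Exposed for auditing the iterative walk.
#'
#' @param net A [build_network()] result.
#' @return Named numeric vector of stationary scores.
#' @export
stationary_walk_scores <- function(net) {
  deg <- net$degree
  comp <- net$components
  out <- numeric(length(deg))
  for (cid in unique(comp)) {
    idx <- comp == cid
    out[idx] <- sum(idx) * deg[idx] / sum(deg[idx])
  }
  names(out) <- names(deg)
  out
}

#' Select network hubs by RW score
#'
#' Nodes whose RW score is at least \code{threshold} (inclusive), i.e. nodes
#' retaining at least \code{threshold} times the network-average energy,
#' sorted by score descending.
#'
#' @param result A [random_walk_scores()] result.
#' @param threshold Inclusive score cutoff (default 2: twice the average).
#' @return Character vector of hub genes, highest score first.
#' @export
select_hubs <- function(result, threshold = 2.0) {
  stopifnot(inherits(result, "walk_result"))
  s <- result$rw_score[result$rw_score >= threshold]
  names(sort(s, decreasing = TRUE))
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("Random-walk scores on %d nodes (%d components)\n",
              length(x$rw_score), length(unique(x$components))))
  cat(sprintf("  converged in %d iterations (L1 residual %.3g)\n",
              x$iterations, x$residual))
  top <- utils::head(sort(x$rw_score, decreasing = TRUE), 5L)
  cat("  top scores:", paste(sprintf("%s=%.3g", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}
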