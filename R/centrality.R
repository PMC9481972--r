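# Centralities absent from igraph, implemented on the weighted adjacency.
# Weights act as strengths/conductances ("heavier = closer"), matching the
# edge-weight convention of the four network scenarios.

weightedAdjacency <- function(g, weights) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  if (!is.null(weights)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    A[] <- 0
    A[el] <- weights
    A[el[, c(2, 1), drop = FALSE]] <- weights
  }
  A
}

#' Katz centrality
#'
#' Counts attenuated walks ending at each node:
#' \eqn{x = (I - \alpha A)^{-1} \beta 1}, where A is the (weighted) adjacency
#' matrix. The attenuation defaults to \code{0.9 / lambda_max(A)}, which
#' guarantees convergence of the underlying walk series for every graph and
#' weighting scenario.
#'
#' @param g an igraph object.
#' @param weights edge weights (strengths); NULL for unweighted.
#' @param alpha attenuation; must be smaller than \code{1/lambda_max(A)}.
#' @param beta additive constant per node.
#' @param attenuationFactor used when \code{alpha} is NULL:
#'   \code{alpha = attenuationFactor / lambda_max(A)}.
#' @param lambdaMax optional precomputed leading eigenvalue of A.
#' @return named numeric vector of centralities.
#' @export
katzCentrality <- function(g, weights = NULL, alpha = NULL, beta = 1,
                           attenuationFactor = 0.9, lambdaMax = NULL) {
  A <- weightedAdjacency(g, weights)
  n <- nrow(A)
  lmax <- lambdaMax %||%
    max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (is.null(alpha)) alpha <- attenuationFactor / lmax
  if (alpha >= 1 / lmax)
    stopInput("Katz attenuation %.4g >= 1/lambda_max = %.4g", alpha, 1 / lmax)
  x <- solve(diag(n) - alpha * A, rep(beta, n))
  stats::setNames(as.numeric(x), igraph::V(g)$name)
}

# grounded generalized inverse of the weighted Laplacian (node 1 grounded);
# valid for effective-resistance and current computations since all the
# involved right-hand sides are orthogonal to the all-ones vector
groundedLaplacianInverse <- function(A) {
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  G <- matrix(0, n, n)
  G[-1, -1] <- solve(L[-1, -1, drop = FALSE])
  G
}

#' Current-flow closeness (information centrality)
#'
#' Treats edge weights as electrical conductances and scores each node by the
#' reciprocal of its mean effective resistance to all other nodes:
#' \eqn{CFC(v) = (n-1) / \sum_t R(v,t)}. Nodes reachable through many short,
#' heavy paths have low resistance to the rest of the tissue and hence high
#' centrality.
#'
#' @inheritParams katzCentrality
#' @return named numeric vector.
#' @export
currentFlowCloseness <- function(g, weights = NULL) {
  if (!igraph::is_connected(g)) stopInput("current-flow closeness needs a connected graph")
  A <- weightedAdjacency(g, weights)
  n <- nrow(A)
  G <- groundedLaplacianInverse(A)
  dG <- diag(G)
  sumR <- n * dG + sum(dG) - 2 * rowSums(G)
  stats::setNames((n - 1) / sumR, igraph::V(g)$name)
}

#' Current-flow (random-walk) betweenness
#'
#' For every source-target pair a unit current flows through the resistor
#' network defined by the edge conductances; a node's score is the summed
#' current throughput over all pairs not involving the node itself:
#' \eqn{CFB(v) = \sum_{s<t} \frac{1}{2}\sum_{e \ni v} |I_e(s,t)|} for
#' \eqn{v \notin \{s,t\}}. Computed via the grounded Laplacian inverse with a
#' per-edge sorting reduction, so the cost stays at O(m n log n) after one
#' linear solve.
#'
#' @inheritParams katzCentrality
#' @return named numeric vector.
#' @export
currentFlowBetweenness <- function(g, weights = NULL) {
  if (!igraph::is_connected(g)) stopInput("current-flow betweenness needs a connected graph")
  A <- weightedAdjacency(g, weights)
  n <- nrow(A)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(el)) else weights
  G <- groundedLaplacianInverse(A)
  coef <- 2 * seq_len(n) - 1 - n
  acc <- numeric(n)
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    d <- G[u, ] - G[v, ]
    sE <- w[e] * sum(coef * sort(d))  # = sum_{s<t} |I_e(s,t)|
    acc[u] <- acc[u] + abs(sE)
    acc[v] <- acc[v] + abs(sE)
  }
  # pairs with v in {s,t} contribute exactly 1/2 each (all current leaves the
  # source / enters the target), so subtract (n-1)/2
  stats::setNames(acc / 2 - (n - 1) / 2, igraph::V(g)$name)
}
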