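#' Node strengths of a weighted directed network
#'
#' With `weights[i, j]` the directed weight from j to i, the in-strength of
#' node i is its row sum (total inflow), the out-strength of node j its
#' column sum (total outflow), and the total strength their sum.
#'
#' @param mat a `pdc_connectivity` (or square non-negative matrix with zero
#'   diagonal).
#' @return data.frame with columns `label`, `in_strength`, `out_strength`,
#'   `strength`.
#' @export
strengths <- function(mat) {
  W <- .conn_weights(mat)
  data.frame(label = rownames(W),
             in_strength = rowSums(W),
             out_strength = colSums(W),
             strength = rowSums(W) + colSums(W),
             row.names = NULL)
}

.conn_weights <- function(mat) {
  W <- if (inherits(mat, "pdc_connectivity")) mat$weights else as.matrix(mat)
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(W))) {
    dimnames(W) <- list(sprintf("n%02d", seq_len(nrow(W))),
                        sprintf("n%02d", seq_len(nrow(W))))
  }
  W
}

#' Directed weighted clustering coefficient
#'
#' Fagiolo's directed-weighted generalization: with P the weight matrix,
#' S = P^(1/3) + (P')^(1/3) element-wise, a the binarized adjacency
#' (a_ij = 1 iff w_ij > 0), and k_i the total (in + out) binary degree,
#' \deqn{C_i = \frac{1}{2} \frac{[S^3]_{ii}}{k_i (k_i - 1) - 2 \sum_j a_{ij} a_{ji}}}
#' The numerator counts weighted directed triangles through i (all eight
#' orientation patterns); the denominator counts the triples that could
#' close, discounting reciprocal pairs, which cannot form a triangle with a
#' third node by themselves.  Nodes with a zero denominator contribute
#' C_i = 0; C is the mean of C_i.
#'
#' @param mat connectivity matrix as in [strengths()]; weights must lie in
#'   [0, 1] for the cube-root normalization to keep C in [0, 1].
#' @return list with `per_node` (named numeric C_i) and `global` (mean C).
#' @export
clustering <- function(mat) {
  W <- .conn_weights(mat)
  if (any(W > 1)) stop("weights must lie in [0, 1]")
  S <- W^(1 / 3) + t(W)^(1 / 3)
  num <- diag(S %*% S %*% S)
  a <- (W > 0) * 1
  k <- rowSums(a) + colSums(a)
  recip <- diag(a %*% a)
  den <- k * (k - 1) - 2 * recip
  Ci <- ifelse(den > 0, 0.5 * num / den, 0)
  names(Ci) <- rownames(W)
  list(per_node = Ci, global = mean(Ci))
}

#' Directed shortest-path distance matrix
#'
#' Each directed edge j -> i with weight `weights[i, j] > 0` has length
#' 1 / weight (strong edges are short); absent edges have infinite length.
#' Entry (s, t) of the returned matrix is the minimal total length over
#' directed paths from node s to node t; the diagonal is 0 and unreachable
#' pairs are `Inf`.
#'
#' @param mat connectivity matrix as in [strengths()].
#' @return K x K numeric distance matrix.
#' @export
shortest_path_lengths <- function(mat) {
  W <- .conn_weights(mat)
  K <- nrow(W)
  # length of the edge s -> t is 1 / W[t, s]
  len <- t(W)
  len[len > 0] <- 1 / len[len > 0]
  g <- igraph::graph_from_adjacency_matrix(len, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, mode = "out",
                         weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- dimnames(W)
  D
}

#' Characteristic path length
#'
#' Mean of the directed shortest-path distances over all ordered node pairs
#' (i != j).  If any pair is unreachable the mean is `Inf`; the result then
#' carries a `disconnected` attribute set to `TRUE` (global efficiency is
#' the robust alternative on disconnected graphs).
#'
#' @param distances matrix from [shortest_path_lengths()].
#' @return scalar L (possibly `Inf`).
#' @export
char_path_length <- function(distances) {
  off <- distances[row(distances) != col(distances)]
  L <- mean(off)
  attr(L, "disconnected") <- any(!is.finite(off))
  L
}

#' Global efficiency
#'
#' Mean of the reciprocal shortest-path distances over ordered pairs, with
#' 1/Inf = 0, so it remains finite and meaningful on disconnected graphs.
#'
#' @param distances matrix from [shortest_path_lengths()].
#' @return scalar Ge in [0, Inf).
#' @export
global_efficiency <- function(distances) {
  off <- distances[row(distances) != col(distances)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Local efficiency per node
#'
#' For each node i, the global-efficiency-style harmonic mean computed on
#' the subgraph induced by i's neighbours -- every node with any in- or
#' out-edge to/from i -- excluding i itself.  Nodes with fewer than two
#' neighbours get 0.
#'
#' @param mat connectivity matrix as in [strengths()].
#' @return named numeric vector Le_i.
#' @export
local_efficiency <- function(mat) {
  W <- .conn_weights(mat)
  K <- nrow(W)
  Le <- stats::setNames(numeric(K), rownames(W))
  for (i in seq_len(K)) {
    nb <- which((W[i, ] > 0 | W[, i] > 0) & seq_len(K) != i)
    if (length(nb) < 2L) next
    sub <- W[nb, nb, drop = FALSE]
    Le[i] <- global_efficiency(shortest_path_lengths(sub))
  }
  Le
}

#' All network metrics of a connectivity matrix
#'
#' Convenience wrapper computing the global metrics (clustering coefficient
#' C, characteristic path length L, global efficiency Ge) and the per-node
#' table (in-/out-/total strength, local efficiency, binary total degree).
#'
#' @param mat a `pdc_connectivity`.
#' @return list with `C`, `L`, `Ge`, `disconnected` flag, and `per_node`
#'   data.frame.
#' @export
network_metrics <- function(mat) {
  W <- .conn_weights(mat)
  cl <- clustering(W)
  D <- shortest_path_lengths(W)
  L <- char_path_length(D)
  st <- strengths(W)
  a <- (W > 0) * 1
  per_node <- data.frame(
    st,
    local_efficiency = unname(local_efficiency(W)),
    clustering = unname(cl$per_node),
    degree = unname(rowSums(a) + colSums(a)),
    row.names = NULL
  )
  list(C = cl$global, L = as.numeric(L), Ge = global_efficiency(D),
       disconnected = isTRUE(attr(L, "disconnected")), per_node = per_node)
}
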