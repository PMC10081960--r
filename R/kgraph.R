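#' Gaussian kNN graph over spiral readout points
#'
#' Builds the adjacency matrix of the k-space graph whose vertices are the
#' `Q` readout points of one spiral interleaf:
#' `A[i, j] = exp(-||v_i - v_j||^2 / dbar^2)`, where `dbar` is the mean
#' Euclidean distance over all unordered pairs of distinct points. Each row
#' is then truncated to its `K` largest entries (the diagonal `A[i, i] = 1`
#' is the row maximum and always survives); ties are broken in favour of
#' the smaller column index. Row-wise truncation generally yields an
#' asymmetric matrix; it is kept asymmetric unless `symmetrize = TRUE`
#' (which averages with the transpose pattern by keeping the union of
#' retained entries).
#'
#' Because the construction depends only on pairwise distances, the graph
#' is invariant under rigid rotation of the trajectory: one graph serves
#' all golden-angle frames.
#'
#' @param coords Q x 2 matrix of k-space coordinates (cycles/FOV).
#' @param K number of retained neighbours per row (including self).
#' @param symmetrize keep the union of (i,j)/(j,i) retained entries,
#'   making the truncated adjacency symmetric.
#' @return object of class `kspace_graph`: `coords`, `mean_pair_dist`,
#'   `K`, `adjacency` (sparse Q x Q), `propagation` (sparse Q x Q, see
#'   [propagation_matrix()]).
#' @export
#' @examples
#' g <- build_adjacency(make_spiral(64, 48, 0.5)$coords, K = 5)
#' Matrix::diag(g$adjacency)[1:3]  # all 1
build_adjacency <- function(coords, K, symmetrize = FALSE) {
  coords <- as.matrix(coords)
  Q <- nrow(coords)
  check_that(ncol(coords) == 2, "coords must be a Q x 2 matrix")
  check_that(K >= 1, "K must be >= 1")
  check_that(K <= Q, "K must be <= Q")
  K <- as.integer(K)
  d <- as.matrix(stats::dist(coords))
  dbar <- mean(d[upper.tri(d)])
  A <- exp(-(d / dbar)^2)
  keep <- matrix(FALSE, Q, Q)
  for (i in seq_len(Q)) {
    ## ties broken by smaller column index: order() is stable on the
    ## secondary key seq_len(Q)
    keep[i, order(-A[i, ], seq_len(Q))[seq_len(K)]] <- TRUE
  }
  if (symmetrize) keep <- keep | t(keep)
  At <- A
  At[!keep] <- 0
  adjacency <- methods::as(methods::as(Matrix::Matrix(At, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")
  g <- structure(list(coords = coords, mean_pair_dist = dbar, K = K,
                      adjacency = adjacency, propagation = NULL),
                 class = "kspace_graph")
  g$propagation <- propagation_matrix(g)
  g
}

#' Normalised propagation matrix of the graph convolution
#'
#' Returns `Dhat^{-1/2} Ahat Dhat^{-1/2}` with `Ahat = A + I` applied to
#' the kNN-truncated adjacency (so the diagonal is boosted to 2) and
#' `Dhat[i, i] = sum_j Ahat[i, j]`. The symmetric normalisation
#' `Dhat^{-1/2} Ahat Dhat^{-1/2}` is the standard graph-convolution
#' propagation rule; with `K = 1` the truncated adjacency is the identity
#' and the propagation matrix reduces exactly to the identity.
#'
#' @param graph a `kspace_graph` from [build_adjacency()].
#' @return sparse Q x Q propagation matrix.
#' @export
propagation_matrix <- function(graph) {
  check_that(inherits(graph, "kspace_graph"), "graph must be a kspace_graph")
  A <- graph$adjacency
  Q <- nrow(A)
  Ahat <- A + Matrix::Diagonal(Q)
  deg <- Matrix::rowSums(Ahat)
  if (any(deg <= 0)) stop("internal error: zero row degree despite self-loop")
  s <- 1 / sqrt(deg)
  Matrix::Diagonal(Q, s) %*% Ahat %*% Matrix::Diagonal(Q, s)
}
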