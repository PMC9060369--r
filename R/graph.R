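#' Fuzzy k-nearest-neighbour graph
#'
#' Builds the weighted neighbourhood graph underlying the manifold
#' embedding: for each cell, directed weights to its `k` nearest
#' neighbours `w_i(x_i, x_j) = exp(-(d(x_i, x_j) - rho_i) / sigma_i)`,
#' where `rho_i` is the distance to the nearest neighbour (guaranteeing
#' local connectivity: the nearest neighbour always has weight 1) and
#' `sigma_i` is calibrated per cell so that the total neighbour weight
#' mass equals `log2(k)` (the smooth-kNN calibration).  The directed
#' weights are symmetrised by the probabilistic t-conorm
#' `A_ij = w_ij + w_ji - w_ij * w_ji`.
#'
#' @param data Marker data frame (or numeric matrix) of the cells to
#'   embed.
#' @param k Number of nearest neighbours (default 20).
#' @param markers Optional marker columns.
#' @return A `fuzzy_graph` object: `idx`/`dist` (n x k kNN matrices),
#'   `rho`, `sigma`, `weights` (n x k directed weights), and `edges`, a
#'   tibble of the symmetrised adjacency (`from`, `to`, `weight`,
#'   `adjacency`) with one row per directed kNN edge.
#' @export
fuzzy_knn_graph <- function(data, k = 20, markers = NULL) {
  X <- if (is.matrix(data)) data else
    marker_matrix(data, markers, exclude = c("label", "population"))
  n <- nrow(X)
  if (k >= n) abort(sprintf("k (%d) must be smaller than the number of cells (%d)", k, n))
  nn <- FNN::get.knn(X, k = k)
  idx <- nn$nn.index
  dist <- nn$nn.dist
  rho <- dist[, 1]
  sigma <- vapply(seq_len(n), function(i) {
    smooth_knn_sigma(dist[i, ], rho[i], target = log2(k))
  }, numeric(1))
  weights <- exp(-pmax(dist - rho, 0) / sigma)

  # symmetrised adjacency over the union of directed edges
  from <- rep(seq_len(n), k)
  to <- as.vector(idx)
  w_ij <- as.vector(weights)
  W <- Matrix::sparseMatrix(i = from, j = to, x = w_ij, dims = c(n, n))
  w_ji <- W[cbind(to, from)]
  adjacency <- w_ij + w_ji - w_ij * w_ji

  structure(list(
    k = k, idx = idx, dist = dist, rho = rho, sigma = sigma,
    weights = weights,
    edges = tibble::tibble(from = from, to = to, weight = w_ij,
                           mutual_weight = w_ji, adjacency = adjacency),
    cell_id = if (is.matrix(data)) sprintf("cell_%d", seq_len(n)) else cell_ids(data)
  ), class = "fuzzy_graph")
}

# Binary search for sigma so that sum_j exp(-(d_j - rho)/sigma) = target.
smooth_knn_sigma <- function(d, rho, target, n_iter = 64, tol = 1e-5) {
  lo <- 0
  hi <- Inf
  mid <- 1
  for (it in seq_len(n_iter)) {
    val <- sum(exp(-pmax(d - rho, 0) / mid))
    if (abs(val - target) < tol) break
    if (val > target) {
      hi <- mid
      mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  max(mid, 1e-12)
}

#' @export
print.fuzzy_graph <- function(x, ...) {
  cat(sprintf("<fuzzy_graph> %d cells, k = %d, %d directed edges\n",
              nrow(x$idx), x$k, nrow(x$edges)))
  invisible(x)
}

#' Symmetrised t-conorm combination of two directed weights
#'
#' The elementwise rule used to symmetrise the fuzzy graph:
#' `a = w_ij + w_ji - w_ij * w_ji`.
#' @param w_ij,w_ji Directed edge weights in [0, 1].
#' @return The symmetrised weight.
#' @export
symmetrize_weights <- function(w_ij, w_ji) {
  w_ij + w_ji - w_ij * w_ji
}

#' Low-dimensional manifold embedding of the unknown pool
#'
#' Embeds cells into 2 or 3 dimensions by minimising the fuzzy-graph
#' cross-entropy between high- and low-dimensional edge weights with
#' stochastic gradient descent (UMAP; the optimiser is provided by the
#' uwot package, fed this package's kNN graph).  Reproducible under a
#' fixed seed in single-threaded mode.
#'
#' @param data Marker data frame or numeric matrix of cells to embed.
#' @param n_components Output dimensionality, 2 (default) or 3.
#' @param k Neighbourhood size (default 20).
#' @param n_epochs SGD epochs (default 200).
#' @param min_dist UMAP minimum embedded distance (default 0.1).
#' @param markers Optional marker columns.
#' @param seed Integer seed.
#' @return A `gate_embedding` tibble: `cell_id` plus coordinate columns
#'   `umap_1..umap_d`, with the `fuzzy_graph` and seed as attributes.
#' @export
embed_cells <- function(data, n_components = 2, k = 20, n_epochs = 200,
                        min_dist = 0.1, markers = NULL, seed = 1) {
  if (!n_components %in% c(2L, 3L)) abort("n_components must be 2 or 3")
  graph <- fuzzy_knn_graph(data, k = k, markers = markers)
  n <- nrow(graph$idx)
  nn <- list(idx = cbind(seq_len(n), graph$idx),
             dist = cbind(rep(0, n), graph$dist))
  coords <- with_seed(seed, {
    uwot::umap(X = NULL, nn_method = nn, n_components = n_components,
               n_epochs = n_epochs, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  })
  if (any(!is.finite(coords))) abort("embedding produced non-finite coordinates")
  colnames(coords) <- paste0("umap_", seq_len(n_components))
  out <- dplyr::bind_cols(tibble::tibble(cell_id = graph$cell_id),
                          tibble::as_tibble(as.data.frame(coords)))
  class(out) <- c("gate_embedding", class(out))
  attr(out, "graph") <- graph
  attr(out, "seed") <- seed
  out
}

#' Coordinates of an embedding as a matrix
#' @param embedding A `gate_embedding` (or any data frame with `umap_*`
#'   columns).
#' @return Numeric matrix of embedded coordinates.
#' @export
embedding_coords <- function(embedding) {
  cols <- grep("^umap_", names(embedding), value = TRUE)
  if (length(cols) == 0L) cols <- setdiff(names(embedding), "cell_id")
  as.matrix(embedding[cols])
}

#' Cross-entropy between high- and low-dimensional edge weights
#'
#' Evaluates, over the edges of the fuzzy graph, the fuzzy-set
#' cross-entropy `sum w log(w/w') + (1-w) log((1-w)/(1-w'))` between the
#' high-dimensional adjacency weights and the embedded weights
#' `w' = 1 / (1 + a d^(2b))` (the smooth embedded-similarity kernel).
#'
#' @param embedding A `gate_embedding` whose attached graph supplies the
#'   high-dimensional weights.
#' @param a,b Embedded-kernel shape parameters (defaults match
#'   `min_dist = 0.1`).
#' @return The cross-entropy (scalar, >= 0 up to clipping).
#' @export
embedding_cross_entropy <- function(embedding, a = 1.577, b = 0.8951) {
  graph <- attr(embedding, "graph")
  if (is.null(graph)) abort("embedding has no attached fuzzy_graph")
  Y <- embedding_coords(embedding)
  e <- graph$edges
  d2 <- rowSums((Y[e$from, , drop = FALSE] - Y[e$to, , drop = FALSE])^2)
  w_low <- 1 / (1 + a * d2^b)
  w <- pmin(pmax(e$adjacency, 1e-12), 1 - 1e-12)
  w_low <- pmin(pmax(w_low, 1e-12), 1 - 1e-12)
  sum(w * log(w / w_low) + (1 - w) * log((1 - w) / (1 - w_low)))
}
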