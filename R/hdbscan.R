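# Hierarchical density clustering of the embedded unknown pool:
# mutual-reachability distances, the single-linkage hierarchy they induce
# (equivalent to the minimum-spanning-tree construction), condensation of
# the dendrogram by minimum cluster size, and excess-of-mass stability
# selection of flat clusters.

#' Mutual reachability distances
#'
#' `d_mreach(a, b) = max(core(a), core(b), d(a, b))`, where `core(x)` is
#' the distance from `x` to its k-th nearest neighbour.  The result is
#' symmetric, at least the base distance, and zero on the diagonal by
#' convention.
#'
#' @param distances A square distance matrix or `dist` object.
#' @param core Optional vector of per-point core distances; computed from
#'   `distances` as the k-th smallest off-diagonal entry per row when `k`
#'   is given instead.
#' @param k Neighbour count for the core distance (ignored when `core` is
#'   supplied).
#' @return A symmetric matrix of mutual reachability distances.
#' @export
mutual_reachability <- function(distances, core = NULL, k = NULL) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (is.null(core)) {
    if (is.null(k)) abort("supply either `core` distances or `k`")
    if (k >= n) abort("k must be smaller than the number of points")
    core <- apply(D, 1, function(row) sort(row[-which.min(row)])[k])
    # row[-which.min] drops one zero (self); sorted k-th entry is the k-NN
  }
  if (length(core) != n) abort("core length must match the distance matrix")
  M <- pmax(D, outer(core, core, pmax))
  diag(M) <- 0
  M
}

# Condensed cluster tree from a single-linkage hclust object.
# Returns rows (parent, child, child_type, lambda, size): point rows are
# cells leaving a condensed cluster at density lambda = 1/distance;
# cluster rows are true splits into two children of size >= mcs.
condense_hclust <- function(hc, min_cluster_size) {
  merge <- hc$merge
  height <- pmax(hc$height, 1e-10)
  n <- nrow(merge) + 1L
  sizes <- integer(nrow(merge))
  for (t in seq_len(nrow(merge))) {
    sizes[t] <- sum(ifelse(merge[t, ] < 0, 1L, sizes[pmax(merge[t, ], 1L)]))
  }
  leaves_of <- function(node) {                 # leaf point ids under a merge node
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (nd < 0) out <- c(out, -nd) else stack <- c(stack, merge[nd, ])
    }
    out
  }
  node_size <- function(nd) if (nd < 0) 1L else sizes[nd]

  rows <- list()
  next_cluster <- 1L
  birth <- c(root = 0)
  names(birth) <- NULL
  birth_lambda <- numeric(0)
  birth_lambda[1] <- 0
  parent_of <- integer(0)
  parent_of[1] <- NA_integer_
  stack <- list(list(node = nrow(merge), cluster = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    node <- fr$node
    cl <- fr$cluster
    ch <- merge[node, ]
    s <- c(node_size(ch[1]), node_size(ch[2]))
    lambda <- 1 / height[node]
    big <- s >= min_cluster_size
    if (all(big)) {
      for (j in 1:2) {
        next_cluster <- next_cluster + 1L
        birth_lambda[next_cluster] <- lambda
        parent_of[next_cluster] <- cl
        rows[[length(rows) + 1L]] <- list(parent = cl, child = next_cluster,
                                          child_type = "cluster",
                                          lambda = lambda, size = s[j])
        if (ch[j] < 0) {
          # a leaf can be a big child only when min_cluster_size == 1
          rows[[length(rows) + 1L]] <- list(parent = next_cluster, child = -ch[j],
                                            child_type = "point",
                                            lambda = lambda, size = 1L)
        } else {
          stack[[length(stack) + 1L]] <- list(node = ch[j], cluster = next_cluster)
        }
      }
    } else {
      for (j in 1:2) {
        if (big[j]) {
          stack[[length(stack) + 1L]] <- list(node = ch[j], cluster = cl)
        } else {
          pts <- if (ch[j] < 0) -ch[j] else leaves_of(ch[j])
          for (p in pts) {
            rows[[length(rows) + 1L]] <- list(parent = cl, child = p,
                                              child_type = "point",
                                              lambda = lambda, size = 1L)
          }
        }
      }
    }
  }
  tree <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  list(tree = tree, birth_lambda = birth_lambda, parent_of = parent_of,
       n_clusters = next_cluster)
}

# Excess-of-mass selection over the condensed tree.
# Returns the selected cluster ids and the per-cluster stability.
select_clusters_eom <- function(condensed, allow_single_cluster = FALSE) {
  tree <- condensed$tree
  ncl <- condensed$n_clusters
  stability <- numeric(ncl)
  for (cl in seq_len(ncl)) {
    rows <- tree[tree$parent == cl, ]
    stability[cl] <- sum((rows$lambda - condensed$birth_lambda[cl]) * rows$size)
  }
  children <- lapply(seq_len(ncl), function(cl) {
    tree$child[tree$parent == cl & tree$child_type == "cluster"]
  })
  selected <- logical(ncl)
  subtree_stab <- stability
  deselect_descendants <- function(cl) {
    for (ch in children[[cl]]) {
      selected[ch] <<- FALSE
      deselect_descendants(ch)
    }
  }
  for (cl in rev(seq_len(ncl))) {
    if (cl == 1L && !allow_single_cluster) next
    kids <- children[[cl]]
    if (length(kids) == 0L) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- stability[cl]
    } else {
      s_kids <- sum(subtree_stab[kids])
      if (stability[cl] >= s_kids) {
        selected[cl] <- TRUE
        subtree_stab[cl] <- stability[cl]
        deselect_descendants(cl)
      } else {
        subtree_stab[cl] <- s_kids
      }
    }
  }
  if (allow_single_cluster && selected[1L] && any(selected[-1L])) {
    selected[1L] <- FALSE
  }
  list(selected = which(selected), stability = stability)
}

#' Extract novel populations by condensed-tree stability clustering
#'
#' Clusters the embedded unknown pool: Euclidean distances in the
#' embedding are lifted to mutual reachability distances
#' ([mutual_reachability()]), the single-linkage hierarchy is condensed by
#' `min_cluster_size`, and flat clusters are selected by excess-of-mass
#' stability.  Cells in no stable cluster are labeled noise.
#'
#' @param embedding A `gate_embedding` (or data frame of coordinates).
#' @param min_cluster_size Minimum cluster size (minPts); default
#'   `max(15, 0.5%` of cells`)`.
#' @param min_samples Neighbour count for the core distance; defaults to
#'   `min_cluster_size`.
#' @param allow_single_cluster Permit the hierarchy root itself to be
#'   selected when no true split survives condensation.
#' @return A `gate_clustering` tibble (`cell_id`, `cluster` integer id or
#'   `NA` for noise), with attributes `clusters` (size and stability per
#'   extracted cluster), `condensed_tree`, and `min_cluster_size`.
#' @export
cluster_embedding <- function(embedding, min_cluster_size = NULL,
                              min_samples = NULL,
                              allow_single_cluster = FALSE) {
  X <- embedding_coords(embedding)
  n <- nrow(X)
  ids <- if ("cell_id" %in% names(embedding)) as.character(embedding$cell_id)
         else sprintf("cell_%d", seq_len(n))
  if (is.null(min_cluster_size)) min_cluster_size <- max(15L, ceiling(0.005 * n))
  min_cluster_size <- as.integer(min_cluster_size)
  if (n < min_cluster_size || n < 2L) {
    warn(sprintf("fewer cells (%d) than min_cluster_size (%d): all noise",
                 n, min_cluster_size))
    out <- tibble::tibble(cell_id = ids, cluster = NA_integer_)
    class(out) <- c("gate_clustering", class(out))
    attr(out, "clusters") <- tibble::tibble(cluster = integer(), size = integer(),
                                            stability = numeric())
    attr(out, "min_cluster_size") <- min_cluster_size
    return(out)
  }
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- min(as.integer(min_samples), n - 1L)

  core <- FNN::get.knn(X, k = min_samples)$nn.dist[, min_samples]
  d <- stats::dist(X)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  dm <- pmax(as.vector(d), pmax(core[i], core[j]))
  attributes(dm) <- attributes(d)
  hc <- stats::hclust(dm, method = "single")

  condensed <- condense_hclust(hc, min_cluster_size)
  sel <- select_clusters_eom(condensed, allow_single_cluster)

  labels <- rep(NA_integer_, n)
  if (length(sel$selected)) {
    sel_set <- sel$selected
    pt_rows <- condensed$tree[condensed$tree$child_type == "point", ]
    # nearest selected ancestor (including the direct parent cluster)
    anc_label <- function(cl) {
      while (!is.na(cl)) {
        if (cl %in% sel_set) return(cl)
        cl <- condensed$parent_of[cl]
      }
      NA_integer_
    }
    parent_map <- vapply(sort(unique(pt_rows$parent)), anc_label, integer(1))
    names(parent_map) <- sort(unique(pt_rows$parent))
    lab <- parent_map[as.character(pt_rows$parent)]
    labels[pt_rows$child] <- lab
    # renumber to consecutive ids in order of extraction
    labels <- match(labels, sel_set)
  }
  out <- tibble::tibble(cell_id = ids, cluster = labels)
  class(out) <- c("gate_clustering", class(out))
  sizes <- table(factor(labels, levels = seq_along(sel$selected)))
  attr(out, "clusters") <- tibble::tibble(
    cluster = seq_along(sel$selected),
    size = as.integer(sizes),
    stability = sel$stability[sel$selected]
  )
  attr(out, "condensed_tree") <- condensed$tree
  attr(out, "min_cluster_size") <- min_cluster_size
  out
}

#' @export
print.gate_clustering <- function(x, ...) {
  info <- attr(x, "clusters")
  cat(sprintf("<gate_clustering> %d cells: %d cluster(s), %d noise\n",
              nrow(x), nrow(info), sum(is.na(x$cluster))))
  if (nrow(info)) print(tibble::as_tibble(info))
  invisible(x)
}

#' Name novel clusters and merge them into an assignment fragment
#'
#' Orders extracted clusters by decreasing size and names them
#' `new_1, new_2, ...`, skipping any name already present among the
#' canonical populations.  Noise cells keep `label = "unknown"` with
#' `source = "noise"`.
#'
#' @param clustering A `gate_clustering` from [cluster_embedding()].
#' @param existing_names Character vector of names already in use.
#' @return A tibble (`cell_id`, `label`, `source`).
#' @export
name_novel_clusters <- function(clustering, existing_names = character()) {
  info <- attr(clustering, "clusters")
  if (is.null(info) || nrow(info) == 0L) {
    return(tibble::tibble(cell_id = as.character(clustering$cell_id),
                          label = "unknown", source = "noise")[seq_len(nrow(clustering)), ])
  }
  ord <- info$cluster[order(-info$size)]
  fresh <- character(length(ord))
  idx <- 1L
  for (r in seq_along(ord)) {
    repeat {
      cand <- sprintf("new_%d", idx)
      idx <- idx + 1L
      if (!cand %in% existing_names) break
    }
    fresh[r] <- cand
  }
  name_of <- stats::setNames(fresh, ord)
  lab <- ifelse(is.na(clustering$cluster), "unknown",
                name_of[as.character(clustering$cluster)])
  src <- ifelse(is.na(clustering$cluster), "noise", "novel_cluster")
  tibble::tibble(cell_id = as.character(clustering$cell_id),
                 label = unname(lab), source = src)
}
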