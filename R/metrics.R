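#' Contingency table of true classes by predicted clusters
#'
#' Exact integer cross-tabulation N_ij underlying every external index.
#' Cells with unassigned (`NA`) truth are excluded by default.
#'
#' @param truth True labels (vector or factor; `NA` = unassigned).
#' @param pred Predicted labels/cluster ids, same length.
#' @param drop_unassigned Drop cells with `NA` truth (default `TRUE`).
#' @return A `gate_contingency` object: the counts matrix with per-class
#'   TP/FP/FN/TN in attribute `binary`.
#' @export
contingency_table <- function(truth, pred, drop_unassigned = TRUE) {
  if (length(truth) != length(pred)) {
    abort(sprintf("length mismatch: %d true vs %d predicted labels",
                  length(truth), length(pred)))
  }
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (drop_unassigned) {
    keep <- !is.na(truth)
    truth <- truth[keep]
    pred <- pred[keep]
  }
  if (length(truth) == 0L) abort("empty input: no labeled cells")
  if (anyNA(pred)) abort("predicted labels contain NA")
  tab <- table(truth = truth, pred = pred)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  n <- sum(counts)
  binary <- tibble::tibble(
    class = rownames(counts),
    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_, tn = NA_integer_
  )
  shared <- intersect(rownames(counts), colnames(counts))
  for (r in seq_len(nrow(binary))) {
    cls <- binary$class[r]
    tp <- if (cls %in% shared) counts[cls, cls] else 0L
    row_sum <- sum(counts[cls, ])
    col_sum <- if (cls %in% colnames(counts)) sum(counts[, cls]) else 0L
    binary$tp[r] <- tp
    binary$fp[r] <- col_sum - tp
    binary$fn[r] <- row_sum - tp
    binary$tn[r] <- n - row_sum - col_sum + tp
  }
  structure(counts, class = c("gate_contingency", "matrix"), binary = binary)
}

as_contingency <- function(truth, pred = NULL) {
  if (inherits(truth, "gate_contingency")) return(truth)
  contingency_table(truth, pred)
}

#' Weighted multi-class F-score
#'
#' Per-class F_i = 2 * precision_i * recall_i / (precision_i + recall_i),
#' combined as the class-prevalence-weighted average F = sum (C_i / N) F_i.
#' When the predicted labels are arbitrary cluster ids (not a subset of the
#' true class names), each cluster is first mapped to its
#' maximum-overlap true class (many-to-one).
#'
#' @param truth True labels or a `gate_contingency`.
#' @param pred Predicted labels (ignored when `truth` is a contingency).
#' @return A list: `f` (weighted score), `by_class` tibble with per-class
#'   precision, recall and F_i.
#' @export
f_score <- function(truth, pred = NULL) {
  ct <- as_contingency(truth, pred)
  counts <- unclass(ct)
  classes <- rownames(counts)
  clusters <- colnames(counts)
  if (all(clusters %in% classes)) {
    mapping <- stats::setNames(clusters, clusters)
  } else {
    mapping <- stats::setNames(classes[apply(counts, 2, which.max)], clusters)
  }
  n <- sum(counts)
  by_class <- lapply(classes, function(cls) {
    mapped_cols <- clusters[mapping == cls]
    tp <- sum(counts[cls, mapped_cols])
    pred_pos <- sum(counts[, mapped_cols])
    true_pos <- sum(counts[cls, ])
    precision <- if (pred_pos > 0) tp / pred_pos else 0
    recall <- if (true_pos > 0) tp / true_pos else 0
    f_i <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    tibble::tibble(class = cls, n_cells = true_pos, precision = precision,
                   recall = recall, f = f_i)
  })
  by_class <- dplyr::bind_rows(by_class)
  list(f = sum(by_class$n_cells / n * by_class$f), by_class = by_class)
}

choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two partitions,
#' computed from the contingency-table pair counts; 1 for identical
#' partitions (up to relabeling), near 0 for random ones.
#'
#' @inheritParams f_score
#' @return A single number in [-1, 1].
#' @export
adjusted_rand_index <- function(truth, pred = NULL) {
  ct <- as_contingency(truth, pred)
  counts <- unclass(ct)
  n <- sum(counts)
  if (n < 2) abort("ARI requires at least 2 cells")
  sum_ij <- sum(choose2(counts))
  sum_i <- sum(choose2(rowSums(counts)))
  sum_j <- sum(choose2(colSums(counts)))
  expected <- sum_i * sum_j / choose2(n)
  max_index <- (sum_i + sum_j) / 2
  if (abs(max_index - expected) < 1e-12) {
    # degenerate: both partitions all-singletons or single-cluster
    return(if (sum_ij == max_index) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall: over all cell pairs,
#' TP = pairs together in both partitions, FP = together only in the
#' prediction, FN = together only in the truth.
#'
#' @inheritParams f_score
#' @return A single number in [0, 1]; 0 when no pair is shared.
#' @export
fowlkes_mallows_index <- function(truth, pred = NULL) {
  ct <- as_contingency(truth, pred)
  counts <- unclass(ct)
  if (sum(counts) < 2) abort("FMI requires at least 2 cells")
  tp <- sum(choose2(counts))
  tp_fp <- sum(choose2(colSums(counts)))
  tp_fn <- sum(choose2(rowSums(counts)))
  if (tp == 0 || tp_fp == 0 || tp_fn == 0) return(0)
  sqrt(tp / tp_fp) * sqrt(tp / tp_fn)
}

entropy_counts <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' V-measure, homogeneity and completeness
#'
#' Conditional-entropy-based external index: homogeneity
#' `1 - H(C|K)/H(C)` penalises clusters mixing classes, completeness
#' `1 - H(K|C)/H(K)` penalises classes split across clusters, and the
#' V-measure is their harmonic mean.  A zero relevant entropy yields 1 by
#' convention.
#'
#' @inheritParams f_score
#' @return A list with `v_measure`, `homogeneity`, `completeness`.
#' @export
v_measure <- function(truth, pred = NULL) {
  ct <- as_contingency(truth, pred)
  counts <- unclass(ct)
  n <- sum(counts)
  h_c <- entropy_counts(rowSums(counts))
  h_k <- entropy_counts(colSums(counts))
  h_c_given_k <- sum(vapply(seq_len(ncol(counts)), function(j) {
    entropy_counts(counts[, j]) * sum(counts[, j]) / n
  }, numeric(1)))
  h_k_given_c <- sum(vapply(seq_len(nrow(counts)), function(i) {
    entropy_counts(counts[i, ]) * sum(counts[i, ]) / n
  }, numeric(1)))
  homogeneity <- if (h_c == 0) 1 else 1 - h_c_given_k / h_c
  completeness <- if (h_k == 0) 1 else 1 - h_k_given_c / h_k
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  list(v_measure = v, homogeneity = homogeneity, completeness = completeness)
}

#' Neighborhood proportion error of an embedding
#'
#' For every cell, the fraction of its `k` nearest neighbours sharing its
#' subtype is computed in the original marker space and in the embedding.
#' Per subtype, the two empirical distributions of that fraction (over the
#' support 0, 1/k, ..., 1) are compared by total variation distance; the
#' NPE is the cell-weighted average of these distances.  An embedding that
#' perfectly preserves neighbourhood composition has NPE 0; smaller is
#' better.
#'
#' @param original Marker data frame or matrix (original space).
#' @param embedding Embedding coordinates (`gate_embedding`, data frame or
#'   matrix) for the same cells.
#' @param labels Subtype per cell (vector or column name in `original`).
#' @param k Neighbourhood size (default 20).
#' @param markers Optional marker columns of `original`.
#' @return The NPE (scalar >= 0).  Subtypes with fewer than 2 cells are
#'   skipped with a warning.
#' @export
npe <- function(original, embedding, labels, k = 20, markers = NULL) {
  X <- if (is.matrix(original)) original else
    marker_matrix(original, markers, exclude = c("label", "population"))
  Y <- if (is.matrix(embedding)) embedding else embedding_coords(embedding)
  if (nrow(X) != nrow(Y)) abort("original and embedding cover different cell counts")
  lab <- if (is.data.frame(original)) resolve_labels(original, labels) else
    as_label_vector(labels)
  if (anyNA(lab)) abort("labels must be available for all scored cells")
  n <- nrow(X)
  if (k >= n) abort("k must be smaller than the number of cells")

  frac_same <- function(M) {
    nn <- FNN::get.knn(M, k = k)$nn.index
    same <- matrix(as.character(lab)[nn], n, k) == as.character(lab)
    rowSums(same) / k
  }
  p_orig <- frac_same(X)
  q_emb <- frac_same(Y)

  support <- 0:k
  total <- 0
  scored <- 0L
  for (s in levels(droplevels(lab))) {
    ix <- which(lab == s)
    if (length(ix) < 2L) {
      warn(sprintf("subtype '%s' has fewer than 2 cells; skipped", s))
      next
    }
    P <- tabulate(round(p_orig[ix] * k) + 1L, nbins = k + 1L) / length(ix)
    Q <- tabulate(round(q_emb[ix] * k) + 1L, nbins = k + 1L) / length(ix)
    delta <- 0.5 * sum(abs(P - Q))
    total <- total + delta * length(ix)
    scored <- scored + length(ix)
  }
  if (scored == 0L) abort("no subtype with at least 2 cells")
  total / scored
}

#' Residual variance between original and embedded distances
#'
#' `1 - R^2` where `R` is the Pearson correlation between corresponding
#' entries of the original-space and embedded-space distance vectors; 0
#' when the embedding preserves distances up to a positive affine map, 1
#' when they are uncorrelated.
#'
#' @param original_distances,embedded_distances Matching `dist` objects,
#'   matrices, or numeric vectors of pairwise distances.
#' @return A single number <= 1.
#' @export
residual_variance <- function(original_distances, embedded_distances) {
  dv <- function(d) {
    if (inherits(d, "dist")) return(as.vector(d))
    if (is.matrix(d)) return(d[lower.tri(d)])
    as.numeric(d)
  }
  x <- dv(original_distances)
  y <- dv(embedded_distances)
  if (length(x) != length(y)) abort("distance vectors differ in length")
  if (sd(x) == 0 || sd(y) == 0) return(1)   # no correlation is definable
  1 - cor(x, y)^2
}

#' Area under the ROC curve
#'
#' Trapezoidal area of the true-positive rate against the false-positive
#' rate over all score thresholds; equal to the probability that a
#' positive cell outscores a negative one, with ties counting one half
#' (midpoint convention).
#'
#' @param scores Numeric per-cell scores (higher = more positive).
#' @param truth Logical (or 2-level) vector of true class membership.
#' @return The ROC curve area in [0, 1].
#' @export
roc_curve_area <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) abort("scores and truth differ in length")
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    abort("ROC area undefined: one of the classes is absent")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' All external indices at once
#'
#' Convenience wrapper computing the full external-evaluation panel for a
#' predicted labeling against the truth.
#'
#' @inheritParams f_score
#' @return A one-row tibble: `f_score`, `ari`, `fmi`, `v_measure`,
#'   `homogeneity`, `completeness`, `n`.
#' @export
evaluate_labels <- function(truth, pred = NULL) {
  ct <- as_contingency(truth, pred)
  v <- v_measure(ct)
  tibble::tibble(
    f_score = f_score(ct)$f,
    ari = adjusted_rand_index(ct),
    fmi = fowlkes_mallows_index(ct),
    v_measure = v$v_measure,
    homogeneity = v$homogeneity,
    completeness = v$completeness,
    n = sum(unclass(ct))
  )
}
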