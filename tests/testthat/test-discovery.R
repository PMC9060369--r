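blob_tbl <- function(centers, n_per, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
            centers[i, ], `+`)
    }))
  })
  out <- tibble::as_tibble(as.data.frame(pts))
  names(out) <- paste0("umap_", seq_len(ncol(pts)))
  out
}

test_that("fuzzy graph weights follow the local-connectivity kernel", {
  # directed weight to the nearest neighbour is exp(0) = 1, and the
  # per-point weight mass is calibrated to log2(k)
  tab <- blob_tbl(matrix(c(0, 0), 1), 60, sd = 1, seed = 2)
  g <- fuzzy_knn_graph(tab, k = 10)
  expect_equal(unname(g$weights[, 1]), rep(1, 60))
  expect_true(all(abs(rowSums(g$weights) - log2(10)) < 0.05))
  expect_true(all(g$edges$adjacency >= 0 & g$edges$adjacency <= 1))

  # symmetrisation rule on hand values
  expect_equal(symmetrize_weights(1, 0), 1)
  expect_equal(symmetrize_weights(0.5, 0.5), 0.75)
  expect_equal(symmetrize_weights(0, 0), 0)

  # the symmetrised adjacency is an exactly symmetric function of the pair
  key <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
  split_a <- split(g$edges$adjacency, key)
  expect_true(all(vapply(split_a, function(v) max(v) - min(v) < 1e-12, logical(1))))

  expect_error(fuzzy_knn_graph(tab, k = 60), "smaller")
})

test_that("mutual reachability reproduces the max rule and its properties", {
  D <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(mutual_reachability(D, core = c(1, 2))[1, 2], 5)
  expect_equal(mutual_reachability(D, core = c(1, 2))[1, 1], 0)

  D2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(mutual_reachability(D2, core = c(4, 2))[1, 2], 4)

  withr::with_seed(3, X <- matrix(rnorm(40), 20, 2))
  D3 <- as.matrix(dist(X))
  M <- mutual_reachability(D3, k = 4)
  expect_equal(M, t(M))
  expect_true(all(M >= D3 - 1e-12))
  expect_true(all(diag(M) == 0))

  # core distance computed internally equals the k-th neighbour distance
  core4 <- apply(D3, 1, function(r) sort(r[r > 0])[4])
  M2 <- mutual_reachability(D3, core = core4)
  expect_equal(M, M2)
})

test_that("embedding separates far blobs, preserves duplicates, and is deterministic", {
  centers <- matrix(c(0, 0, 30, 0), 2, byrow = TRUE)
  tab <- blob_tbl(centers, 250, sd = 1, seed = 4)
  names(tab) <- c("m1", "m2")
  e1 <- embed_cells(tab, k = 15, n_epochs = 300, seed = 9)
  e2 <- embed_cells(tab, k = 15, n_epochs = 300, seed = 9)
  expect_identical(embedding_coords(e1), embedding_coords(e2))

  Y <- embedding_coords(e1)
  intra <- (mean(dist(Y[1:250, ])) + mean(dist(Y[251:500, ]))) / 2
  inter <- mean(as.matrix(dist(Y))[1:250, 251:500])
  expect_gt(inter / intra, 3)

  # duplicated points land within numerical jitter of each other
  dup <- dplyr::bind_rows(tab, tab[1:3, ])
  ed <- embed_cells(dup, k = 15, n_epochs = 100, seed = 9)
  Yd <- embedding_coords(ed)
  spread <- median(dist(Yd[seq(1, 500, by = 5), ]))
  for (i in 1:3) {
    expect_lt(sqrt(sum((Yd[i, ] - Yd[500 + i, ])^2)), 0.1 * spread)
  }

  # cross-entropy of the fitted embedding is finite and improves on a
  # random layout
  ce_fit <- embedding_cross_entropy(e1)
  shuffled <- e1
  withr::with_seed(1, {
    perm <- sample.int(nrow(tab))
  })
  shuffled$umap_1 <- shuffled$umap_1[perm]
  shuffled$umap_2 <- shuffled$umap_2[perm]
  attr(shuffled, "graph") <- attr(e1, "graph")
  expect_lt(ce_fit, embedding_cross_entropy(shuffled))
})

test_that("planted blobs are recovered exactly and noise is rejected", {
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, byrow = TRUE)
  b3 <- blob_tbl(centers, 120, sd = 1, seed = 5)
  cl <- cluster_embedding(b3, min_cluster_size = 15)
  info <- attr(cl, "clusters")
  expect_equal(nrow(info), 3)
  truth <- rep(1:3, each = 120)
  got <- ifelse(is.na(cl$cluster), 0L, cl$cluster)
  expect_gt(matched_agreement(truth, got), 0.95)

  # a single tight blob is one cluster when a lone cluster is permitted
  blob <- blob_tbl(matrix(c(0, 0), 1), 100, sd = 0.5, seed = 6)
  c1 <- cluster_embedding(blob, min_cluster_size = 10,
                          allow_single_cluster = TRUE)
  expect_equal(nrow(attr(c1, "clusters")), 1)
  expect_gte(mean(!is.na(c1$cluster)), 0.95)

  # uniform points in high dimension have no density mode
  withr::with_seed(7, {
    u <- tibble::as_tibble(as.data.frame(matrix(runif(1000), 100, 10)))
  })
  names(u) <- paste0("umap_", 1:10)
  cu <- cluster_embedding(u, min_cluster_size = 50)
  expect_gt(mean(is.na(cu$cluster)), 0.5)

  # fewer cells than min_cluster_size: all noise with a warning
  expect_warning(cs <- cluster_embedding(blob[1:5, ], min_cluster_size = 10),
                 "min_cluster_size")
  expect_true(all(is.na(cs$cluster)))
})

test_that("novel clusters are named by decreasing size without collisions", {
  cl <- tibble::tibble(cell_id = sprintf("c%d", 1:8),
                       cluster = c(1L, 1L, 2L, 2L, 2L, NA, 1L, 2L))
  attr(cl, "clusters") <- tibble::tibble(cluster = 1:2, size = c(3L, 4L),
                                         stability = c(1, 2))
  class(cl) <- c("gate_clustering", class(cl))
  frag <- name_novel_clusters(cl, existing_names = c("popA", "popB"))
  expect_equal(frag$label[cl$cluster == 2L & !is.na(cl$cluster)][1], "new_1")
  expect_equal(frag$label[cl$cluster == 1L & !is.na(cl$cluster)][1], "new_2")
  expect_equal(frag$label[6], "unknown")
  expect_equal(frag$source[6], "noise")

  # collision with an existing name advances the numbering
  frag2 <- name_novel_clusters(cl, existing_names = c("new_1"))
  expect_setequal(setdiff(unique(frag2$label), "unknown"), c("new_2", "new_3"))

  # zero clusters -> all unknown/noise fragment
  cl0 <- tibble::tibble(cell_id = c("a", "b"), cluster = c(NA_integer_, NA_integer_))
  attr(cl0, "clusters") <- tibble::tibble(cluster = integer(), size = integer(),
                                          stability = numeric())
  class(cl0) <- c("gate_clustering", class(cl0))
  frag0 <- name_novel_clusters(cl0)
  expect_equal(frag0$label, c("unknown", "unknown"))
})
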