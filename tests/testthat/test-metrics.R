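test_that("contingency tables cross-tabulate exactly with binary counts", {
  ct <- contingency_table(c("A", "A", "B"), c(1, 1, 2))
  expect_equal(unclass(ct)["A", "1"], 2L)
  expect_equal(unclass(ct)["B", "2"], 1L)
  expect_equal(sum(unclass(ct)), 3L)

  b <- attr(contingency_table(c("A", "A", "B", "B"), c("A", "A", "A", "B")),
            "binary")
  expect_equal(b$tp, c(2L, 1L))
  expect_equal(b$fp, c(1L, 0L))
  expect_equal(b$fn, c(0L, 1L))
  expect_equal(b$tp + b$fp + b$fn + b$tn, c(4L, 4L))

  expect_error(contingency_table(c("A", "B"), c(1, 2, 3)), "length mismatch")
  expect_error(contingency_table(character(0), character(0)), "empty")
  # unassigned truth is excluded
  ct2 <- contingency_table(c("A", NA, "B"), c(1, 1, 2))
  expect_equal(sum(unclass(ct2)), 2L)
})

test_that("weighted F-score matches hand-computed and oracle values", {
  expect_equal(f_score(c("A", "A", "B"), c("A", "A", "B"))$f, 1)

  # hand-computed: P_A = 2/3, R_A = 1, F_A = 0.8; P_B = 1, R_B = 1/2,
  # F_B = 2/3; weights 1/2 each
  res <- f_score(c("A", "A", "B", "B"), c("A", "A", "A", "B"))
  expect_equal(res$f, 0.5 * 0.8 + 0.5 * (2 / 3))
  expect_equal(res$by_class$precision, c(2 / 3, 1))
  expect_equal(res$by_class$recall, c(1, 1 / 2))

  # zero overlap for a class
  res0 <- f_score(c("A", "A", "B"), c("B", "B", "A"))
  expect_equal(res0$by_class$f[res0$by_class$class == "A"], 0)

  withr::with_seed(21, {
    for (i in 1:20) {
      truth <- sample(c("A", "B", "C"), 30, replace = TRUE)
      pred <- truth
      pred[sample(30, 8)] <- sample(unique(truth), 8, replace = TRUE)
      expect_equal(f_score(truth, pred)$f, oracle_f_score(truth, pred))
    }
  })
})

test_that("ARI and FMI agree with brute-force pair counting", {
  expect_equal(adjusted_rand_index(c("A", "A", "B", "B"), c("x", "x", "y", "y")), 1)
  expect_equal(fowlkes_mallows_index(c("A", "A", "B"), c("A", "A", "B")), 1)

  # truth pairs vs all-singleton prediction, brute-forced over all 6 pairs
  u <- c("A", "A", "B", "B")
  expect_equal(adjusted_rand_index(u, 1:4), oracle_ari(u, 1:4))
  expect_equal(fowlkes_mallows_index(u, 1:4), 0)   # no pair survives

  # the all-in-one prediction: FMI = sqrt(2/6 * 2/2)
  expect_equal(fowlkes_mallows_index(u, rep(1, 4)), sqrt(1 / 3))
  expect_equal(fowlkes_mallows_index(u, rep(1, 4)), oracle_fmi(u, rep(1, 4)))

  withr::with_seed(31, {
    for (i in 1:25) {
      truth <- sample(1:3, 25, replace = TRUE)
      pred <- sample(1:4, 25, replace = TRUE)
      expect_equal(adjusted_rand_index(truth, pred), oracle_ari(truth, pred))
      expect_equal(fowlkes_mallows_index(truth, pred), oracle_fmi(truth, pred))
    }
  })
})

test_that("external indices are invariant to relabeling predicted clusters", {
  withr::with_seed(41, {
    truth <- sample(c("A", "B", "C"), 40, replace = TRUE)
    pred <- sample(1:4, 40, replace = TRUE)
  })
  relabeled <- c(9, 7, 5, 3)[pred]
  expect_equal(adjusted_rand_index(truth, pred),
               adjusted_rand_index(truth, relabeled))
  expect_equal(fowlkes_mallows_index(truth, pred),
               fowlkes_mallows_index(truth, relabeled))
  expect_equal(v_measure(truth, pred)$v_measure,
               v_measure(truth, relabeled)$v_measure)
  expect_equal(f_score(truth, pred)$f, f_score(truth, relabeled)$f)
})

test_that("V-measure matches entropy conventions and the MI oracle", {
  expect_equal(v_measure(c("A", "A", "B"), c(1, 1, 2))$v_measure, 1)

  # one predicted cluster against two balanced classes
  v <- v_measure(c("A", "A", "B", "B"), rep(1, 4))
  expect_equal(v$homogeneity, 0)
  expect_equal(v$completeness, 1)
  expect_equal(v$v_measure, 0)

  withr::with_seed(51, {
    for (i in 1:20) {
      truth <- sample(c("A", "B"), 20, replace = TRUE)
      pred <- sample(1:3, 20, replace = TRUE)
      expect_equal(v_measure(truth, pred)$v_measure,
                   oracle_v_measure(truth, pred), tolerance = 1e-12)
    }
  })
})

test_that("corrupting a perfect prediction degrades the pair indices", {
  withr::with_seed(61, {
    truth <- sample(c("A", "B", "C", "D"), 200, replace = TRUE)
    flips <- c(0, 20, 60, 120)
    scores <- vapply(flips, function(k) {
      pred <- truth
      ix <- sample(200, k)
      pred[ix] <- sample(c("A", "B", "C", "D"), k, replace = TRUE)
      c(adjusted_rand_index(truth, pred), fowlkes_mallows_index(truth, pred),
        f_score(truth, pred)$f)
    }, numeric(3))
  })
  for (r in 1:3) expect_true(all(diff(scores[r, ]) <= 1e-9))
})

test_that("NPE is zero for a copied embedding and maximal for swapped neighbourhoods", {
  withr::with_seed(71, X <- matrix(rnorm(60 * 4), 60, 4))
  lab <- rep(c("A", "B", "C"), each = 20)
  expect_equal(npe(X, X, lab, k = 5), 0)

  # k = 1 toy where the embedding rewires every nearest neighbour across
  # subtypes: both per-subtype fraction distributions move from point mass
  # at 1 to point mass at 0, so each total variation distance is 1
  orig <- matrix(c(0, 1, 10, 11), ncol = 1)
  emb <- matrix(c(0, 10.5, 10, 11), ncol = 1)
  expect_equal(npe(orig, emb, c("A", "A", "B", "B"), k = 1), 1)

  # a faithful embedding beats a shuffled one on separated blobs
  withr::with_seed(72, {
    blobs <- rbind(matrix(rnorm(100, 0, 1), 50, 2),
                   matrix(rnorm(100, 8, 1), 50, 2))
    lab2 <- rep(c("A", "B"), each = 50)
    shuffled <- blobs[sample(100), ]
  })
  expect_lt(npe(blobs, blobs + rnorm(200, 0, 0.01), lab2, k = 10),
            npe(blobs, shuffled, lab2, k = 10))

  expect_warning(npe(X, X, c(rep("A", 59), "zz"), k = 5), "fewer than 2")
})

test_that("residual variance matches closed forms", {
  d <- runif(20, 1, 5)
  expect_equal(residual_variance(d, 3 * d + 1), 0)

  # 3-point toy: r = 1/sqrt(4/3), RV = 1 - 3/4
  expect_equal(residual_variance(c(1, 2, 3), c(1, 2, 2)), 0.25)

  # zero-variance vector: no correlation definable
  expect_equal(residual_variance(d, rep(2, 20)), 1)
})

test_that("ROC area equals the rank statistic with midpoint ties", {
  expect_equal(roc_curve_area(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_curve_area(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  s4 <- c(0.9, 0.4, 0.6, 0.1)
  t4 <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_curve_area(s4, t4), oracle_auc(s4, t4))

  withr::with_seed(81, {
    for (i in 1:10) {
      sc <- round(runif(40), 2)    # rounded scores force ties
      tr <- runif(40) > 0.4
      if (!any(tr) || all(tr)) next
      expect_equal(roc_curve_area(sc, tr), oracle_auc(sc, tr))
      expect_equal(roc_curve_area(sc, tr),
                   as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                                  direction = "<"))))
    }
  })
  expect_error(roc_curve_area(1:3, c(TRUE, TRUE, TRUE)), "absent")
})

test_that("the combined report collects every index", {
  rep <- evaluate_labels(c("A", "A", "B", "B"), c("A", "A", "A", "B"))
  expect_equal(names(rep), c("f_score", "ari", "fmi", "v_measure",
                             "homogeneity", "completeness", "n"))
  expect_true(all(rep[c("f_score", "fmi", "v_measure")] <= 1))
  expect_equal(rep$n, 4L)
})
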