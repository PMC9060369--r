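make_two_pop <- function(n_per = 200, mean2 = 10, seed = 1) {
  withr::with_seed(seed, {
    tab <- tibble::tibble(
      cell_id = sprintf("c%d", seq_len(2 * n_per)),
      m1 = c(rnorm(n_per, 0, 1), rnorm(n_per, mean2, 1)),
      label = rep(c("A", "B"), each = n_per)
    )
    attr(tab, "transformed") <- TRUE
    tab
  })
}

test_that("softmax rows are normalised and match closed forms", {
  s <- deepgate:::softmax_rows(matrix(c(0, 0, log(2), 0), 2, byrow = TRUE))
  expect_equal(s[1, ], c(0.5, 0.5))
  expect_equal(s[2, ], c(2 / 3, 1 / 3))
  z <- matrix(rnorm(50), 10, 5)
  expect_equal(rowSums(deepgate:::softmax_rows(z)), rep(1, 10))
})

test_that("analytic gradients match numerical gradients on a tiny toy", {
  withr::with_seed(7, {
    X <- matrix(rnorm(6), 3, 2)
    y <- c(1L, 2L, 1L)
    params <- deepgate:::nn_init(2, 4, 2)
  })
  lambda <- 0.1
  act <- "softplus"    # smooth activation for finite differences
  ana <- deepgate:::nn_gradients(params, X, y, lambda, act)
  h <- 1e-5
  for (l in seq_along(params$W)) {
    for (target in c("W", "b")) {
      p <- params[[target]][[l]]
      num <- if (is.matrix(p)) array(0, dim = dim(p)) else numeric(length(p))
      for (i in seq_along(p)) {
        up <- params; up[[target]][[l]][i] <- p[i] + h
        dn <- params; dn[[target]][[l]][i] <- p[i] - h
        num[i] <- (deepgate:::nn_loss(up, X, y, lambda, act) -
                     deepgate:::nn_loss(dn, X, y, lambda, act)) / (2 * h)
      }
      a <- if (target == "W") ana$W[[l]] else ana$b[[l]]
      rel <- sqrt(sum((num - a)^2)) / (sqrt(sum(num^2)) + sqrt(sum(a^2)) + 1e-12)
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("linearly separable populations are learned perfectly", {
  tab <- make_two_pop()
  cfg <- classifier_config(hidden_sizes = c(16, 8), epochs = 30,
                           validation_fraction = 0, seed = 2)
  fit <- train_classifier(tab, "label", cfg)
  pred <- predict(fit, tab)
  expect_equal(mean(as.character(pred) == tab$label), 1)

  # logistic-regression oracle agrees on every cell (separation warnings
  # are expected on perfectly separable data)
  glm_fit <- suppressWarnings(
    stats::glm(I(label == "B") ~ m1, data = tab, family = binomial()))
  glm_pred <- ifelse(stats::predict(glm_fit, type = "response") > 0.5, "B", "A")
  expect_equal(as.character(pred), unname(glm_pred))

  # training loss settles: non-increasing on average over the final 10%
  tail_loss <- tail(fit$history$loss, max(3, nrow(fit$history) %/% 10))
  expect_lte(mean(diff(tail_loss)), 1e-3)
})

test_that("posterior rows are probabilities summing to one", {
  tab <- make_two_pop(50)
  fit <- train_classifier(tab, "label",
                          classifier_config(hidden_sizes = 8, epochs = 10,
                                            validation_fraction = 0, seed = 1))
  post <- predict_posteriors(fit, tab)
  probs <- as.matrix(post[c("A", "B")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(rowSums(probs), rep(1, nrow(tab)), tolerance = 1e-6)
})

test_that("an overwhelming L2 penalty flattens posteriors toward uniform", {
  tab <- make_two_pop(100)
  # enough optimiser steps for the penalty-dominated fixed point near 0
  cfg <- classifier_config(hidden_sizes = 8, lambda_l2 = 1e6, epochs = 100,
                           learning_rate = 0.05, batch_size = 16,
                           validation_fraction = 0, seed = 1)
  fit <- train_classifier(tab, "label", cfg)
  free <- train_classifier(tab, "label",
                           classifier_config(hidden_sizes = 8, epochs = 100,
                                             learning_rate = 0.05,
                                             batch_size = 16,
                                             validation_fraction = 0, seed = 1))
  expect_lt(max(abs(unlist(fit$weights))), 0.1 * max(abs(unlist(free$weights))))
  post <- predict_posteriors(fit, tab)
  expect_true(all(abs(as.matrix(post[c("A", "B")]) - 0.5) < 0.1))
})

test_that("training is deterministic under a fixed seed", {
  tab <- make_two_pop(60)
  cfg <- classifier_config(hidden_sizes = 8, epochs = 8,
                           validation_fraction = 0, seed = 11)
  f1 <- train_classifier(tab, "label", cfg)
  f2 <- train_classifier(tab, "label", cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$weights, f2$weights)
})

test_that("degenerate training inputs are rejected", {
  tab <- make_two_pop(50)
  one <- tab
  one$label <- "A"
  expect_error(train_classifier(one, "label"), "at least 2")

  few <- tab
  few$label[few$label == "B"] <- NA
  few$label[1:3] <- "B"
  expect_error(train_classifier(few, "label"), "fewer than 5")

  raw <- tab
  attr(raw, "transformed") <- FALSE
  expect_error(train_classifier(raw, "label"), "raw scale")

  fit <- train_classifier(tab, "label",
                          classifier_config(hidden_sizes = 8, epochs = 5,
                                            validation_fraction = 0, seed = 1))
  other <- tibble::tibble(cell_id = "x", wrong_marker = 1)
  expect_error(predict_posteriors(fit, other), "mismatch")
})

test_that("model summaries expose layer shapes and fit statistics", {
  tab <- make_two_pop(50)
  fit <- train_classifier(tab, "label",
                          classifier_config(hidden_sizes = c(8, 4), epochs = 5,
                                            validation_fraction = 0, seed = 1))
  td <- tidy(fit)
  expect_equal(td$n_in, c(1, 8, 4))
  expect_equal(td$n_out, c(8, 4, 2))
  gl <- glance(fit)
  expect_equal(gl$n_populations, 2)
  expect_equal(gl$epochs_run, 5)
})

test_that("cross-validated ROC areas behave at the extremes", {
  tab <- make_two_pop(100)
  cfg <- classifier_config(hidden_sizes = 8, epochs = 40, batch_size = 32,
                           validation_fraction = 0, seed = 3)
  cv <- crossvalidated_roc(tab, "label", cfg, folds = 4, seed = 5)
  expect_equal(nrow(cv), 8)   # 2 populations x 4 folds
  expect_true(all(cv$roc_auc > 0.999))
  expect_equal(attr(cv, "mean_auc"), 1, tolerance = 1e-3)

  shuffled <- tab
  shuffled$label <- withr::with_seed(8, sample(shuffled$label))
  cv2 <- crossvalidated_roc(shuffled, "label", cfg, folds = 4, seed = 5)
  expect_lt(abs(attr(cv2, "mean_auc") - 0.5), 0.1)

  expect_error(crossvalidated_roc(tab, "label", cfg, folds = 1), ">= 2")
})
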