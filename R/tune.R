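#' Particle-swarm hyperparameter search
#'
#' Tunes the classifier's depth, L2 penalty and dropout rate with a
#' canonical global-best particle swarm (inertia + cognitive + social
#' velocity update), maximising the validation macro-average one-vs-rest
#' ROC curve area.  The gated cells are split half/half (stratified) into
#' a training and a validation set; every candidate configuration is
#' trained on the first half and scored on the second.
#'
#' Positions are clipped to the search box; integer dimensions (number of
#' hidden layers) are rounded before evaluation.  `lambda_l2` is searched
#' on the log10 scale.  Ties keep the earlier-evaluated configuration.
#'
#' @param data Marker data frame (transformed scale).
#' @param labels Gated labels (column name or vector, `NA` = unassigned).
#' @param search_space Named list of ranges:
#'   `n_layers = c(min, max)` (integers, counted from the widest layer of
#'   `base_config$hidden_sizes`), `lambda_l2 = c(min, max)` (> 0), and
#'   `dropout_rate = c(min, max)`.
#' @param swarm_size Number of particles.
#' @param iterations Velocity/position updates after the initial sweep.
#' @param base_config Template [classifier_config()] supplying every field
#'   not searched over.
#' @param inertia,cognitive,social Swarm coefficients; defaults 0.72,
#'   1.49, 1.49 (standard constriction values).
#' @param markers Optional marker column names.
#' @param seed Integer seed; the search is deterministic.
#' @return The best [classifier_config()] found, with attributes
#'   `roc_auc` (its validation score) and `evaluations` (a tibble of every
#'   configuration evaluated).
#' @export
tune_classifier <- function(data, labels,
                            search_space = list(n_layers = c(1, 3),
                                                lambda_l2 = c(1e-6, 1e-2),
                                                dropout_rate = c(0, 0.5)),
                            swarm_size = 8, iterations = 5,
                            base_config = classifier_config(),
                            inertia = 0.72, cognitive = 1.49, social = 1.49,
                            markers = NULL, seed = 1) {
  dims <- c("n_layers", "lambda_l2", "dropout_rate")
  if (!all(dims %in% names(search_space))) {
    abort("search_space must provide n_layers, lambda_l2 and dropout_rate ranges")
  }
  lo <- c(search_space$n_layers[1], log10(max(search_space$lambda_l2[1], 1e-12)),
          search_space$dropout_rate[1])
  hi <- c(search_space$n_layers[2], log10(max(search_space$lambda_l2[2], 1e-12)),
          search_space$dropout_rate[2])
  if (any(hi < lo)) abort("empty search space: a range has max < min")

  y <- resolve_labels(data, labels)
  keep <- which(!is.na(y))
  if (length(keep) < 10) abort("too few labeled cells to tune on")

  with_seed(seed, {
    # half/half stratified split of the gated cells
    y_lab <- droplevels(y[keep])
    val <- unlist(lapply(split(seq_along(keep), y_lab), function(ix) {
      sample(ix, floor(length(ix) / 2))
    }), use.names = FALSE)
    tr <- keep[-val]
    te <- keep[val]
    lab_tr <- replace(as.character(y), setdiff(seq_along(y), tr), NA)

    as_config <- function(pos) {
      nl <- as.integer(round(pos[1]))
      cfg <- base_config
      cfg$hidden_sizes <- head(base_config$hidden_sizes, max(nl, 1L))
      cfg$lambda_l2 <- 10^pos[2]
      cfg$dropout_rate <- min(max(pos[3], 0), 0.99)
      cfg
    }
    evaluate <- function(pos) {
      cfg <- as_config(pos)
      fit <- train_classifier(data, lab_tr, config = cfg, markers = markers)
      post <- predict_posteriors(fit, data[te, , drop = FALSE])
      truth <- as.character(y[te])
      aucs <- vapply(fit$populations, function(pop) {
        pos_cls <- truth == pop
        if (!any(pos_cls) || all(pos_cls)) return(NA_real_)
        roc_curve_area(post[[pop]], pos_cls)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }

    d <- length(lo)
    span <- hi - lo
    if (all(span == 0)) {            # degenerate single-point space
      f <- evaluate(lo)
      best <- as_config(lo)
      attr(best, "roc_auc") <- f
      attr(best, "evaluations") <- tibble::tibble(
        n_layers = as.integer(round(lo[1])), lambda_l2 = 10^lo[2],
        dropout_rate = lo[3], roc_auc = f)
      return(best)
    }
    X <- t(replicate(swarm_size, lo + runif(d) * span))
    X[1, ] <- (lo + hi) / 2
    V <- matrix(0, swarm_size, d)
    evals <- list()
    pbest <- X
    pbest_f <- rep(-Inf, swarm_size)
    gbest <- X[1, ]
    gbest_f <- -Inf

    score_all <- function(X) {
      for (i in seq_len(nrow(X))) {
        f <- evaluate(X[i, ])
        evals[[length(evals) + 1L]] <<- tibble::tibble(
          n_layers = as.integer(round(X[i, 1])), lambda_l2 = 10^X[i, 2],
          dropout_rate = X[i, 3], roc_auc = f)
        if (f > pbest_f[i]) {
          pbest_f[i] <<- f
          pbest[i, ] <<- X[i, ]
        }
        if (f > gbest_f) {          # strict: ties keep the earlier config
          gbest_f <<- f
          gbest <<- X[i, ]
        }
      }
    }

    score_all(X)
    if (!(all(hi == lo))) {
      for (it in seq_len(iterations)) {
        r1 <- matrix(runif(swarm_size * d), swarm_size, d)
        r2 <- matrix(runif(swarm_size * d), swarm_size, d)
        V <- inertia * V + cognitive * r1 * (pbest - X) +
          social * r2 * sweep(X, 2, gbest, function(x, g) g - x)
        X <- X + V
        X <- pmin(pmax(X, matrix(lo, swarm_size, d, byrow = TRUE)),
                  matrix(hi, swarm_size, d, byrow = TRUE))
        score_all(X)
      }
    }

    best <- as_config(gbest)
    attr(best, "roc_auc") <- gbest_f
    attr(best, "evaluations") <- dplyr::bind_rows(evals)
    best
  })
}
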