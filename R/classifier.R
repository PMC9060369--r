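#' Classifier configuration
#'
#' Collects the hyperparameters of the canonical-population softmax
#' classifier: a feedforward network with (by default) three hidden layers
#' of 128, 64 and 32 units, trained by mini-batch ADAM on the mean
#' cross-entropy plus an L2 weight penalty.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths (>= 1 layer).
#' @param activation Hidden activation, `"relu"` (default) or `"softplus"`.
#' @param lambda_l2 L2 regularisation strength (lambda), >= 0.
#' @param learning_rate ADAM learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param dropout_rate Hidden-layer dropout rate in [0, 1).
#' @param validation_fraction Share of labeled cells held out for early
#'   stopping (0 disables).
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden_sizes = c(128, 64, 32),
                              activation = c("relu", "softplus"),
                              lambda_l2 = 1e-4, learning_rate = 0.001,
                              batch_size = 256, epochs = 300,
                              dropout_rate = 0, validation_fraction = 0.1,
                              patience = 10, seed = 1) {
  activation <- match.arg(activation)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L)) {
    abort("at least one hidden layer with positive width is required")
  }
  if (lambda_l2 < 0) abort("lambda_l2 must be non-negative")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  check_positive_scalar(learning_rate, "learning_rate")
  check_positive_scalar(batch_size, "batch_size")
  check_positive_scalar(epochs, "epochs")
  structure(list(hidden_sizes = hidden_sizes, activation = activation,
                 lambda_l2 = lambda_l2, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 dropout_rate = dropout_rate,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Train the canonical-population softmax classifier
#'
#' Fits the feedforward softmax network on arcsinh-transformed marker
#' expression for the gated (labeled) cells.  Unassigned cells (`NA`
#' labels) are excluded from training.  Optimisation is mini-batch ADAM on
#' mean cross-entropy + `lambda_l2 * sum(W^2)`, with optional early
#' stopping on a stratified validation split.  Deterministic under a fixed
#' seed and single-threaded BLAS.
#'
#' @param data Marker data frame (cells x markers, transformed scale).
#' @param labels Column name in `data` or a vector: gated population per
#'   cell, `NA` for unassigned.
#' @param config A [classifier_config()].
#' @param markers Optional marker column names.
#' @param verbose Print per-epoch losses.
#' @return A `gate_classifier` object with weights, training history and
#'   the population order used for posterior columns; supports
#'   [predict_posteriors()], `predict()`, `tidy()` and `glance()`.
#' @export
train_classifier <- function(data, labels, config = classifier_config(),
                             markers = NULL, verbose = FALSE) {
  if (isFALSE(is_transformed(data))) {
    abort("data is on the raw scale; apply asinh_transform() first")
  }
  y_all <- resolve_labels(data, labels)
  X_all <- marker_matrix(data, markers, exclude = c("label", "population"))
  keep <- !is.na(y_all)
  if (!any(keep)) abort("no labeled cells to train on")
  y <- droplevels(y_all[keep])
  if (nlevels(y) < 2L) abort("training requires at least 2 labeled populations")
  small <- table(y) < 5L
  if (any(small)) {
    abort(paste0("population(s) with fewer than 5 labeled cells: ",
                 paste(names(small)[small], collapse = ", ")))
  }
  X <- X_all[keep, , drop = FALSE]
  populations <- levels(y)
  yi <- as.integer(y)

  center <- colMeans(X)
  scale_ <- apply(X, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)

  cfg <- config
  n <- nrow(Xs)
  with_seed(cfg$seed, {
    # stratified validation split for early stopping
    val_idx <- integer()
    if (cfg$validation_fraction > 0 && cfg$patience > 0) {
      val_idx <- unlist(lapply(split(seq_len(n), yi), function(ix) {
        nv <- floor(length(ix) * cfg$validation_fraction)
        if (nv >= 1 && length(ix) - nv >= 1) sample(ix, nv) else integer()
      }), use.names = FALSE)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    params <- nn_init(ncol(Xs), cfg$hidden_sizes, length(populations))
    state <- adam_init(params)
    history <- vector("list", cfg$epochs)
    best <- list(val = Inf, params = params, epoch = 0L)
    wait <- 0L
    epochs_run <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      starts <- seq(1, length(ord), by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        ix <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, length(ord))]
        Xb <- Xs[ix, , drop = FALSE]
        yb <- yi[ix]
        fw <- nn_forward(params, Xb, cfg$activation, cfg$dropout_rate, training = TRUE)
        p <- fw$probs[cbind(seq_along(yb), yb)]
        loss <- -mean(log(pmax(p, 1e-300))) +
          cfg$lambda_l2 * sum(vapply(params$W, function(w) sum(w^2), numeric(1)))
        if (!is.finite(loss)) {
          abort(sprintf("non-finite training loss at epoch %d", epoch))
        }
        batch_losses[bi] <- loss
        grads <- nn_gradients(params, Xb, yb, cfg$lambda_l2, cfg$activation, fw)
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      val_loss <- NA_real_
      if (length(val_idx)) {
        val_loss <- nn_loss(params, Xs[val_idx, , drop = FALSE], yi[val_idx],
                            cfg$lambda_l2, cfg$activation)
        if (val_loss < best$val - 1e-9) {
          best <- list(val = val_loss, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         loss = mean(batch_losses),
                                         val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  val %.5f", epoch,
                        mean(batch_losses), val_loss))
      }
      epochs_run <- epoch
      if (length(val_idx) && wait >= cfg$patience) break
    }
    if (length(val_idx) && best$epoch > 0L) params <- best$params

    structure(list(
      weights = params$W, biases = params$b, config = cfg,
      populations = populations, markers = colnames(X),
      center = center, scale = scale_,
      history = dplyr::bind_rows(history[seq_len(epochs_run)]),
      epochs_run = epochs_run,
      best_epoch = if (length(val_idx)) best$epoch else epochs_run,
      n_train = length(tr_idx), n_validation = length(val_idx)
    ), class = "gate_classifier")
  })
}

#' @export
print.gate_classifier <- function(x, ...) {
  cat(sprintf(
    "<gate_classifier> %d markers -> [%s] -> %d populations (%s)\n",
    length(x$markers), paste(x$config$hidden_sizes, collapse = ", "),
    length(x$populations), x$config$activation))
  cat(sprintf("  trained %d epochs (best %d) on %d cells; final loss %.5f\n",
              x$epochs_run, x$best_epoch, x$n_train,
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Per-cell posterior population probabilities
#'
#' Runs the forward pass of a trained classifier; each returned row is a
#' softmax distribution over the canonical populations (rows sum to 1).
#'
#' @param model A `gate_classifier`.
#' @param data Marker data frame with the model's marker columns.
#' @return A tibble: `cell_id` plus one probability column per population.
#' @export
predict_posteriors <- function(model, data) {
  stopifnot(inherits(model, "gate_classifier"))
  missing <- setdiff(model$markers, names(data))
  if (length(missing)) {
    abort(paste0("marker-count mismatch: data lacks model marker(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- marker_matrix(data, model$markers)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  fw <- nn_forward(list(W = model$weights, b = model$biases), Xs,
                   model$config$activation)
  probs <- fw$probs
  colnames(probs) <- model$populations
  out <- dplyr::bind_cols(tibble::tibble(cell_id = cell_ids(data)),
                          tibble::as_tibble(as.data.frame(probs, check.names = FALSE)))
  attr(out, "populations") <- model$populations
  out
}

#' @export
predict.gate_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  post <- predict_posteriors(object, newdata)
  if (type == "prob") return(post)
  probs <- as.matrix(post[object$populations])
  factor(object$populations[max.col(probs, ties.method = "first")],
         levels = object$populations)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gate_classifier <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$weights),
    n_in = vapply(x$weights, nrow, integer(1)),
    n_out = vapply(x$weights, ncol, integer(1)),
    n_parameters = vapply(x$weights, length, integer(1)) +
      vapply(x$biases, length, integer(1)),
    mean_abs_weight = vapply(x$weights, function(w) mean(abs(w)), numeric(1))
  )
}

#' @export
glance.gate_classifier <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, n_populations = length(x$populations),
    n_markers = length(x$markers), epochs_run = x$epochs_run,
    final_loss = x$history$loss[nrow(x$history)],
    best_val_loss = if (x$n_validation > 0) min(x$history$val_loss, na.rm = TRUE) else NA_real_,
    lambda_l2 = x$config$lambda_l2, activation = x$config$activation
  )
}

#' Stratified k-fold cross-validated ROC areas
#'
#' Retrains the classifier on each of `folds` stratified splits of the
#' gated cells and scores one-vs-rest ROC curve areas per population on
#' the held-out fold.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (>= 2); default 4.
#' @param seed Seed for the fold assignment.
#' @return A tibble (`population`, `fold`, `roc_auc`) with attribute
#'   `mean_auc`; populations absent from a fold's test split are recorded
#'   as `NA` with a warning and excluded from the mean.
#' @export
crossvalidated_roc <- function(data, labels, config = classifier_config(),
                               folds = 4, markers = NULL, seed = 1) {
  if (folds < 2) abort("folds must be >= 2")
  y <- resolve_labels(data, labels)
  keep <- which(!is.na(y))
  y_lab <- droplevels(y[keep])
  fold_id <- integer(length(keep))
  with_seed(seed, {
    for (ix in split(seq_along(keep), y_lab)) {
      fold_id[sample(ix)] <- rep_len(seq_len(folds), length(ix))
    }
  })
  res <- list()
  for (f in seq_len(folds)) {
    tr <- keep[fold_id != f]
    te <- keep[fold_id == f]
    lab_tr <- replace(as.character(y), setdiff(seq_along(y), tr), NA)
    fit <- train_classifier(data, lab_tr, config = config, markers = markers)
    post <- predict_posteriors(fit, data[te, , drop = FALSE])
    truth <- as.character(y[te])
    aucs <- vapply(fit$populations, function(pop) {
      pos <- truth == pop
      if (!any(pos) || all(pos)) return(NA_real_)
      roc_curve_area(post[[pop]], pos)
    }, numeric(1))
    if (anyNA(aucs)) {
      warn(paste0("fold ", f, ": population(s) absent from test split: ",
                  paste(names(aucs)[is.na(aucs)], collapse = ", ")))
    }
    res[[f]] <- tibble::tibble(population = fit$populations, fold = f,
                               roc_auc = unname(aucs))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "mean_auc") <- mean(out$roc_auc, na.rm = TRUE)
  out
}
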