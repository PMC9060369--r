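# Spearman machinery: rank each cell's marker vector across markers, then
# correlate rank profiles between cells (Pearson on ranks = Spearman with
# average-rank ties).

rank_profiles <- function(X) {
  t(apply(X, 1, rank))          # ties: average ranks
}

# Mean pairwise Spearman correlation among the rows of rank matrix R
# (n cells x markers).  NA correlations (constant profiles) are dropped.
mean_pairwise_spearman <- function(R) {
  if (nrow(R) < 2L) return(NA_real_)
  C <- suppressWarnings(cor(t(R)))
  mean(C[upper.tri(C)], na.rm = TRUE)
}

#' Per-population Spearman correlation thresholds
#'
#' For each canonical population, computes the calibration threshold
#' `r_j`: the average Spearman correlation (across markers) between pairs
#' of cells currently assigned to that population.  Populations are
#' subsampled to `max_cells` cells for tractability; populations with
#' fewer than 2 assigned cells are skipped with a warning.
#'
#' @param data Marker data frame.
#' @param assignment Assignment tibble with `label` per cell (row-aligned
#'   with `data`).
#' @param max_cells Subsample cap per population (default 200).
#' @param markers Optional marker columns.
#' @param seed Seed for the subsampling.
#' @return A tibble (`population`, `r`, `n_cells_used`).
#' @export
population_thresholds <- function(data, assignment, max_cells = 200,
                                  markers = NULL, seed = 1) {
  X <- marker_matrix(data, markers, exclude = c("label", "population"))
  labels <- as.character(assignment$label)
  populations <- attr(assignment, "populations") %||%
    setdiff(unique(labels), c("unknown", "noise", NA))
  rows <- with_seed(seed, lapply(populations, function(pop) {
    ix <- which(labels == pop)
    if (length(ix) < 2L) {
      warn(sprintf("population '%s' has fewer than 2 assigned cells; threshold undefined", pop))
      return(tibble::tibble(population = pop, r = NA_real_, n_cells_used = length(ix)))
    }
    if (length(ix) > max_cells) ix <- sample(ix, max_cells)
    r <- mean_pairwise_spearman(rank_profiles(X[ix, , drop = FALSE]))
    tibble::tibble(population = pop, r = r, n_cells_used = length(ix))
  }))
  out <- dplyr::bind_rows(rows)
  if (sum(!is.na(out$r)) < 2L) {
    abort("fewer than 2 populations with valid correlation thresholds")
  }
  out
}

#' Feedback calibration of filtered cells
#'
#' The iterative correlation feedback loop: for every unknown cell, its
#' average Spearman correlation with (subsampled) members of each
#' canonical population is compared against that population's threshold
#' `r_j` (the population's internal average correlation,
#' [population_thresholds()]).  A cell exceeding the threshold of at least
#' one population is reallocated to the population with which it shows the
#' highest correlation, with `source = "calibrated"`.  Thresholds are
#' recomputed after each pass and the loop stops at a fixed point or after
#' `max_iterations` passes.  Reallocation is strictly unknown-to-canonical:
#' no cell ever leaves a canonical population.
#'
#' @param data Marker data frame (row-aligned with `assignment`).
#' @param assignment Assignment tibble from [filter_low_confidence()].
#' @param max_iterations Maximum feedback passes (default 10; 0 disables
#'   calibration).
#' @param max_cells Subsample cap per population for the correlations.
#' @param markers Optional marker columns.
#' @param seed Seed for subsampling.
#' @return A list of class `gate_calibration`: `assignment` (updated
#'   tibble), `thresholds` (tibble per pass), `history` (tibble with
#'   per-pass reallocation counts).
#' @export
calibrate_unknowns <- function(data, assignment, max_iterations = 10,
                               max_cells = 200, markers = NULL, seed = 1) {
  X <- marker_matrix(data, markers, exclude = c("label", "population"))
  R_all <- rank_profiles(X)
  labels <- as.character(assignment$label)
  source <- as.character(assignment$source)
  populations <- attr(assignment, "populations") %||%
    setdiff(unique(labels), c("unknown", "noise", NA))

  history <- list()
  thresholds <- NULL
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    unknown_ix <- which(labels == "unknown")
    if (length(unknown_ix) == 0L) break
    cur <- tibble::tibble(cell_id = assignment$cell_id, label = labels)
    attr(cur, "populations") <- populations
    thresholds <- population_thresholds(data, cur, max_cells = max_cells,
                                        markers = markers, seed = seed + iter)
    valid <- thresholds[!is.na(thresholds$r), ]

    # average correlation of each unknown cell with each population's
    # (subsampled) members, via one cross-correlation per population
    corr <- with_seed(seed + 1000L + iter, {
      vapply(valid$population, function(pop) {
        ix <- which(labels == pop)
        if (length(ix) > max_cells) ix <- sample(ix, max_cells)
        CC <- suppressWarnings(cor(t(R_all[unknown_ix, , drop = FALSE]),
                                   t(R_all[ix, , drop = FALSE])))
        rowMeans(CC, na.rm = TRUE)
      }, numeric(length(unknown_ix)))
    })
    corr <- matrix(corr, nrow = length(unknown_ix),
                   dimnames = list(NULL, valid$population))
    exceeds <- sweep(corr, 2, valid$r, `>`)
    exceeds[is.na(exceeds)] <- FALSE
    any_exceed <- rowSums(exceeds) > 0
    if (!any(any_exceed)) {
      history[[iter]] <- tibble::tibble(iteration = iter, reallocated = 0L)
      break
    }
    masked <- corr
    masked[!exceeds] <- -Inf
    target <- valid$population[max.col(masked, ties.method = "first")]
    move <- unknown_ix[any_exceed]
    labels[move] <- target[any_exceed]
    source[move] <- "calibrated"
    history[[iter]] <- tibble::tibble(iteration = iter,
                                      reallocated = length(move))
  }

  out <- assignment
  out$label <- labels
  out$source <- source
  attr(out, "populations") <- populations
  structure(list(assignment = out,
                 thresholds = thresholds,
                 history = if (length(history)) dplyr::bind_rows(history)
                           else tibble::tibble(iteration = integer(), reallocated = integer())),
            class = "gate_calibration")
}

#' @export
print.gate_calibration <- function(x, ...) {
  n <- sum(x$history$reallocated)
  cat(sprintf("<gate_calibration> %d cell(s) reallocated over %d pass(es)\n",
              n, nrow(x$history)))
  invisible(x)
}
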