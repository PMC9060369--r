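#' Describe a simulated cell population
#'
#' Builds one row of a population specification table for
#' [simulate_cells()]: a Gaussian component on the arcsinh-transformed
#' scale with a name, mean marker profile, (diagonal or full) covariance,
#' mixing proportion, and a flag saying whether the population is part of
#' the gated (labeled) reference or a planted novel population.
#'
#' @param name Population name.
#' @param mean Numeric vector of per-marker means (transformed scale).
#' @param sd Per-marker standard deviations (recycled), or a full
#'   symmetric positive semi-definite covariance matrix via `covariance`.
#' @param proportion Mixing proportion in (0, 1].
#' @param labeled Logical; `FALSE` marks a planted novel population absent
#'   from the gated subset.
#' @param covariance Optional full covariance matrix (overrides `sd`).
#' @return A one-row tibble; rows from several calls are combined with
#'   [dplyr::bind_rows()].
#' @export
population_spec <- function(name, mean, sd = 0.25, proportion, labeled = TRUE,
                            covariance = NULL) {
  mean <- as.numeric(mean)
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (nrow(covariance) != length(mean) || ncol(covariance) != length(mean)) {
      abort("covariance dimensions must match length(mean)")
    }
    if (max(abs(covariance - t(covariance))) > 1e-8) abort("covariance must be symmetric")
    if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("covariance must be positive semi-definite")
    }
  } else {
    sd <- rep_len(as.numeric(sd), length(mean))
    if (any(sd < 0)) abort("sd must be non-negative")
  }
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    abort("proportion must be in (0, 1]")
  }
  tibble::tibble(
    name = as.character(name),
    mean = list(mean),
    sd = list(if (is.null(covariance)) sd else NULL),
    covariance = list(covariance),
    proportion = as.numeric(proportion),
    labeled = isTRUE(labeled)
  )
}

#' Default CyTOF-like benchmark population layout
#'
#' Places `k_canonical + m_novel` population means on a sphere in marker
#' space so that the minimum pairwise distance is at least
#' `separation` times the average within-population standard deviation,
#' mimicking the structure of gated CyTOF reference sets: well-separated
#' canonical populations, planted novel populations absent from the gated
#' subset, and at least one rare canonical population (< 2% of cells).
#'
#' @param k_canonical Number of canonical (gated) populations, >= 2.
#' @param m_novel Number of planted novel populations, >= 0.
#' @param n_markers Number of markers, >= 2.
#' @param separation Minimum pairwise mean distance in units of the average
#'   within-population sigma; default 6 gives essentially non-overlapping
#'   populations.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @return A population spec tibble (see [population_spec()]).
#' @export
benchmark_populations <- function(k_canonical, m_novel = 0, n_markers = 10,
                                  separation = 6, seed = 1) {
  if (k_canonical < 2) abort("k_canonical must be >= 2")
  if (m_novel < 0) abort("m_novel must be >= 0")
  if (n_markers < 2) abort("n_markers must be >= 2")
  n_pop <- k_canonical + m_novel
  with_seed(seed, {
    sds <- matrix(runif(n_pop * n_markers, 0.18, 0.32), n_pop, n_markers)
    sigma_bar <- mean(sds)
    # unit directions on the sphere; radius chosen so the smallest chord
    # meets the separation requirement
    dirs <- matrix(rnorm(n_pop * n_markers), n_pop, n_markers)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    d_unit <- as.matrix(stats::dist(dirs))
    min_unit <- min(d_unit[upper.tri(d_unit)])
    if (min_unit < 1e-3) {
      abort(sprintf(
        "infeasible packing: %d populations cannot be separated in %d marker dimensions",
        n_pop, n_markers))
    }
    radius <- if (separation > 0) separation * sigma_bar / min_unit else 2
    center <- rep(2.5, n_markers)
    means <- sweep(radius * dirs, 2, center, `+`)

    # proportions: one rare canonical population (1.5%), novel populations
    # smaller than the typical canonical one, remainder spread evenly with
    # mild jitter
    p_novel <- if (m_novel > 0) rep(0.09, m_novel) else numeric()
    p_rare <- 0.015
    n_main <- k_canonical - 1
    w <- runif(n_main, 0.8, 1.2)
    p_main <- (1 - p_rare - sum(p_novel)) * w / sum(w)
    props <- c(p_main, p_rare, p_novel)

    specs <- lapply(seq_len(n_pop), function(i) {
      canonical <- i <= k_canonical
      population_spec(
        name = if (canonical) sprintf("pop_%02d", i) else sprintf("novel_%02d", i - k_canonical),
        mean = means[i, ],
        sd = sds[i, ],
        proportion = props[i],
        labeled = canonical
      )
    })
    dplyr::bind_rows(specs)
  })
}

#' Simulate a CyTOF-like labeled dataset
#'
#' Draws cells from the Gaussian mixture described by a population spec
#' table, on the arcsinh-transformed scale, and produces both the ground
#' truth and an "observed" gating in which cells of novel populations and a
#' random share of canonical cells are unassigned — the situation a
#' semi-supervised cell-type pipeline faces.
#'
#' @param specs Population spec tibble ([population_spec()],
#'   [benchmark_populations()]).
#' @param n_cells Total number of cells.
#' @param labeled_fraction Fraction of canonical-population cells carrying
#'   their gated label in the observed labeling (default 0.5, the
#'   roughly-half-gated regime of public CyTOF benchmarks).
#' @param seed Integer seed; output is reproducible byte-for-byte.
#' @return A tibble with `cell_id`, one numeric column per marker,
#'   `population` (ground-truth name) and `label` (observed gating; `NA` =
#'   unassigned), carrying attributes `transformed = TRUE` and
#'   `populations` (the canonical population names).
#' @export
simulate_cells <- function(specs, n_cells, labeled_fraction = 0.5, seed = 1) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1)
  if (abs(sum(specs$proportion) - 1) > 1e-9) {
    abort(sprintf("population proportions sum to %.6f, not 1", sum(specs$proportion)))
  }
  if (!any(specs$labeled)) abort("at least one population must be labeled")
  if (n_cells < nrow(specs)) abort("n_cells must be at least the number of populations")
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    abort("labeled_fraction must be in (0, 1]")
  }
  n_markers <- length(specs$mean[[1]])
  with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_cells, specs$proportion))
    blocks <- lapply(seq_len(nrow(specs)), function(i) {
      ni <- counts[i]
      if (ni == 0L) return(NULL)
      mu <- specs$mean[[i]]
      if (!is.null(specs$covariance[[i]])) {
        L <- chol(specs$covariance[[i]] + diag(1e-12, n_markers))
        z <- matrix(rnorm(ni * n_markers), ni, n_markers) %*% L
      } else {
        z <- matrix(rnorm(ni * n_markers), ni, n_markers) %*% diag(specs$sd[[i]], n_markers)
      }
      sweep(z, 2, mu, `+`)
    })
    values <- do.call(rbind, blocks)
    truth <- rep(specs$name, counts)
    observed <- ifelse(rep(specs$labeled, counts), truth, NA_character_)
    keep <- runif(length(observed)) < labeled_fraction
    observed[!keep] <- NA_character_

    ord <- sample.int(length(truth))
    values <- values[ord, , drop = FALSE]
    truth <- truth[ord]
    observed <- observed[ord]

    colnames(values) <- sprintf("marker_%02d", seq_len(n_markers))
    populations <- specs$name[specs$labeled]
    out <- dplyr::bind_cols(
      tibble::tibble(cell_id = sprintf("cell_%06d", seq_along(truth))),
      tibble::as_tibble(as.data.frame(values, check.names = FALSE)),
      tibble::tibble(
        population = factor(truth, levels = specs$name),
        label = factor(observed, levels = populations)
      )
    )
    attr(out, "transformed") <- TRUE
    attr(out, "populations") <- populations
    out
  })
}
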