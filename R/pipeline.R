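#' Identify canonical and novel cell populations end to end
#'
#' Runs the full tri-layer workflow on a cells-by-markers table with a
#' partial gating: (1) train the softmax classifier on the gated cells and
#' predict posteriors for the ungated ones; (2) filter low-confidence
#' predictions into an unknown pool using per-population posterior
#' cutoffs anchored on the gated cells; (3) iteratively reallocate unknown
#' cells back to canonical populations by Spearman-correlation feedback;
#' (4) embed the residual unknown pool and extract novel populations by
#' condensed-tree density clustering; (5) assemble a single per-cell
#' assignment with label provenance.
#'
#' @param data Marker data frame on the arcsinh-transformed scale.
#' @param labels Gated population per cell (column name in `data`, e.g.
#'   `"label"`, or a vector); `NA` marks ungated cells.
#' @param classifier A [classifier_config()].
#' @param filter_mode,filter_value Confidence filter: `"percentile"`
#'   (default, value 5 = the 5th percentile of each population's
#'   max-posterior histogram among gated cells) or `"fixed"` (value = a
#'   posterior cutoff in (0, 1)).
#' @param calibration_iterations Maximum feedback passes (0 disables
#'   calibration).
#' @param calibration_cells Subsample cap per population for the Spearman
#'   correlations.
#' @param k Neighbourhood size for the embedding of the unknown pool.
#' @param n_components Embedding dimensionality for discovery (2 or 3).
#' @param n_epochs Embedding SGD epochs.
#' @param min_cluster_size Minimum novel-cluster size; default
#'   `max(15, 0.5%` of the unknown pool`)`.
#' @param markers Optional marker column names.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param verbose Emit per-stage progress messages.
#' @return A `deepgate_result`: list with `assignment` (tibble `cell_id`,
#'   `label`, `source`, `confidence`), `classifier`, `filter_thresholds`,
#'   `calibration`, `embedding` and `clustering` of the unknown pool, and
#'   `report` (per-stage cell counts and durations).  Supports `print()`,
#'   `tidy()`, `glance()` and `autoplot()`.
#' @export
deepgate <- function(data, labels = "label",
                     classifier = classifier_config(),
                     filter_mode = c("percentile", "fixed"), filter_value = 5,
                     calibration_iterations = 10, calibration_cells = 200,
                     k = 20, n_components = 2, n_epochs = 200,
                     min_cluster_size = NULL,
                     markers = NULL, seed = 1, verbose = FALSE) {
  filter_mode <- match.arg(filter_mode)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  stage_times <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    stage_times[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  y <- resolve_labels(data, labels)
  populations_in <- levels(y)
  gated <- which(!is.na(y))
  ungated <- which(is.na(y))
  if (length(gated) == 0L) abort("pipeline requires gated cells to train on")
  ids <- cell_ids(data)

  say("training classifier on %d gated cells (%d populations)",
      length(gated), nlevels(droplevels(y[gated])))
  classifier <- classifier
  classifier$seed <- seed
  model <- train_classifier(data, y, config = classifier, markers = markers)
  tick("train")

  assignment <- tibble::tibble(
    cell_id = ids,
    label = as.character(y),
    source = ifelse(is.na(y), "unknown", "classified"),
    confidence = NA_real_
  )
  assignment$label[is.na(assignment$label)] <- "unknown"
  attr(assignment, "populations") <- model$populations

  filter_thresholds <- NULL
  n_classified <- 0L
  n_filtered <- 0L
  if (length(ungated)) {
    post_un <- predict_posteriors(model, data[ungated, , drop = FALSE])
    post_ref <- predict_posteriors(model, data[gated, , drop = FALSE])
    flt <- filter_low_confidence(post_un, mode = filter_mode,
                                 value = filter_value,
                                 reference_posteriors = post_ref,
                                 reference_labels = as.character(y[gated]))
    filter_thresholds <- attr(flt, "thresholds")
    assignment$label[ungated] <- flt$label
    assignment$source[ungated] <- flt$source
    assignment$confidence[ungated] <- flt$confidence
    n_classified <- sum(flt$source == "classified")
    n_filtered <- sum(flt$source == "unknown")
    say("filtered %d of %d ungated cells into the unknown pool",
        n_filtered, length(ungated))
  }
  tick("filter")

  calibration <- NULL
  if (length(ungated) && calibration_iterations > 0 && n_filtered > 0) {
    calibration <- calibrate_unknowns(data, assignment,
                                      max_iterations = calibration_iterations,
                                      max_cells = calibration_cells,
                                      markers = markers, seed = seed + 1)
    assignment <- calibration$assignment
    say("calibration reallocated %d cells over %d pass(es)",
        sum(calibration$history$reallocated), nrow(calibration$history))
  }
  tick("calibrate")

  embedding <- NULL
  clustering <- NULL
  unknown_ix <- which(assignment$label == "unknown")
  if (length(unknown_ix) > max(k, 2)) {
    say("embedding %d residual unknown cells", length(unknown_ix))
    embedding <- embed_cells(data[unknown_ix, , drop = FALSE],
                             n_components = n_components, k = k,
                             n_epochs = n_epochs, markers = markers,
                             seed = seed + 2)
    clustering <- cluster_embedding(embedding,
                                    min_cluster_size = min_cluster_size)
    fragment <- name_novel_clusters(clustering,
                                    existing_names = model$populations)
    assignment$label[unknown_ix] <- fragment$label
    assignment$source[unknown_ix] <- fragment$source
    say("extracted %d novel cluster(s)", nrow(attr(clustering, "clusters")))
  } else if (length(unknown_ix)) {
    say("unknown pool too small (%d cells) for discovery; left unassigned",
        length(unknown_ix))
  } else {
    say("empty unknown pool; discovery skipped")
  }
  tick("discover")

  src <- assignment$source[ungated]
  report <- list(
    n_total = nrow(data),
    n_gated = length(gated),
    n_ungated = length(ungated),
    n_classified = sum(src == "classified"),
    n_calibrated = sum(src == "calibrated"),
    n_novel = sum(src == "novel_cluster"),
    n_noise = sum(src == "noise"),
    n_unknown = sum(src == "unknown"),
    n_novel_clusters = if (is.null(clustering)) 0L
                       else nrow(attr(clustering, "clusters")),
    discovery_run = !is.null(clustering),
    stage_seconds = stage_times,
    seed = seed,
    config = list(classifier = unclass(classifier),
                  filter = list(mode = filter_mode, value = filter_value),
                  calibration = list(max_iterations = calibration_iterations,
                                     max_cells = calibration_cells),
                  discovery = list(k = k, n_components = n_components,
                                   n_epochs = n_epochs,
                                   min_cluster_size = min_cluster_size))
  )
  stopifnot(report$n_classified + report$n_calibrated + report$n_novel +
              report$n_noise + report$n_unknown == report$n_ungated)

  structure(list(assignment = assignment, classifier = model,
                 filter_thresholds = filter_thresholds,
                 calibration = calibration, embedding = embedding,
                 clustering = clustering, report = report,
                 populations = model$populations),
            class = "deepgate_result")
}

#' @export
print.deepgate_result <- function(x, ...) {
  r <- x$report
  cat("<deepgate_result>\n")
  cat(sprintf("  %d cells: %d gated, %d ungated\n", r$n_total, r$n_gated, r$n_ungated))
  cat(sprintf("  ungated resolved: %d classified, %d calibrated, %d novel (in %d cluster(s)), %d noise, %d unknown\n",
              r$n_classified, r$n_calibrated, r$n_novel, r$n_novel_clusters,
              r$n_noise, r$n_unknown))
  invisible(x)
}

#' @export
tidy.deepgate_result <- function(x, ...) {
  x$assignment
}

#' @export
glance.deepgate_result <- function(x, ...) {
  r <- x$report
  tibble::as_tibble(r[c("n_total", "n_gated", "n_ungated", "n_classified",
                        "n_calibrated", "n_novel", "n_noise", "n_unknown",
                        "n_novel_clusters", "seed")])
}

#' Write the pipeline run report as JSON
#'
#' Serialises the per-stage cell counts, durations, seeds and the echoed
#' configuration of a pipeline run, together with the calibration audit
#' trail (per-pass reallocation counts and final thresholds) when
#' calibration ran.
#'
#' @param result A `deepgate_result`.
#' @param path Output path for the JSON file.
#' @return Invisibly, the report list.
#' @export
write_run_report <- function(result, path) {
  stopifnot(inherits(result, "deepgate_result"))
  report <- result$report
  if (!is.null(result$calibration)) {
    report$calibration_passes <- result$calibration$history
    report$calibration_thresholds <- result$calibration$thresholds
  }
  if (!is.null(result$filter_thresholds)) {
    report$filter_thresholds <- as.list(result$filter_thresholds)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}

#' Project an assignment into three dimensions with a label axis
#'
#' Builds the coordinate table for the 3-D view of a labeled embedding.
#' In `"label_index"` mode (which requires a 2-D embedding) the X/Y axes
#' are the embedding coordinates and Z is the integer index of the final
#' label — canonical populations first, then novel clusters, then
#' unknown/noise — so that populations separate into parallel planes.  In
#' `"third_embedding_dim"` mode a 3-D embedding is passed through and the
#' label is carried as a colour attribute.
#'
#' @param embedding A `gate_embedding` (2-D or 3-D as required).
#' @param assignment Assignment tibble covering the embedded cells
#'   (matched by `cell_id`).
#' @param mode `"label_index"` or `"third_embedding_dim"`.
#' @param populations Optional canonical population ordering for the label
#'   axis.
#' @return A tibble (`cell_id`, `label`, `source`, `x`, `y`, `z`).
#' @export
make_3d_view <- function(embedding, assignment,
                         mode = c("label_index", "third_embedding_dim"),
                         populations = NULL) {
  mode <- match.arg(mode)
  coords <- embedding_coords(embedding)
  ids <- if ("cell_id" %in% names(embedding)) as.character(embedding$cell_id)
         else sprintf("cell_%d", seq_len(nrow(coords)))
  m <- match(ids, as.character(assignment$cell_id))
  if (anyNA(m)) abort("assignment does not cover every embedded cell")
  label <- as.character(assignment$label)[m]
  source <- if ("source" %in% names(assignment))
    as.character(assignment$source)[m] else NA_character_
  if (mode == "label_index") {
    if (ncol(coords) != 2L) {
      abort(sprintf("label_index mode requires a 2-D embedding (got %d-D)", ncol(coords)))
    }
    z <- label_axis_index(label, populations)
  } else {
    if (ncol(coords) != 3L) {
      abort(sprintf("third_embedding_dim mode requires a 3-D embedding (got %d-D)", ncol(coords)))
    }
    z <- coords[, 3]
  }
  tibble::tibble(cell_id = ids, label = label, source = source,
                 x = coords[, 1], y = coords[, 2], z = as.numeric(z))
}
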