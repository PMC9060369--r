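#' Confidence-threshold filtering into the unknown pool
#'
#' Implements the rejection step between classification and discovery: a
#' cell whose maximum posterior falls below its applicable cutoff is
#' removed from its predicted population and sent to the unknown pool for
#' later calibration or novel-population clustering.
#'
#' Two threshold modes are provided.  In `"percentile"` mode (the default,
#' value 5) the cutoff for population *j* is the stated percentile of the
#' max-posterior histogram of that population's cells — so about 5% of
#' cells end up unassigned.  The histograms are taken over cells whose
#' predicted population is *j*, or over a reference gating when
#' `reference_labels` (and matching `reference_posteriors`) are supplied;
#' the latter is what the full pipeline uses, anchoring the cutoffs on the
#' gated cells so that genuinely novel cells cannot dilute them.  In
#' `"fixed"` mode a single posterior cutoff `Th` in (0, 1) applies to
#' every cell.
#'
#' @param posteriors Posterior tibble from [predict_posteriors()].
#' @param mode `"percentile"` or `"fixed"`.
#' @param value Percentile in (0, 100) (default 5) or fixed cutoff in
#'   (0, 1).
#' @param reference_posteriors,reference_labels Optional posteriors and
#'   matching gated labels from which the per-population histograms are
#'   computed instead.
#' @return A tibble (`cell_id`, `label`, `source`, `confidence`) where
#'   filtered cells carry `label = "unknown"`, `source = "unknown"`; all
#'   others carry their argmax population and `source = "classified"`.
#'   Attribute `thresholds` records the per-population cutoffs.
#' @export
filter_low_confidence <- function(posteriors, mode = c("percentile", "fixed"),
                                  value = 5, reference_posteriors = NULL,
                                  reference_labels = NULL) {
  mode <- match.arg(mode)
  populations <- attr(posteriors, "populations") %||%
    setdiff(names(posteriors), "cell_id")
  if (length(populations) == 0L) abort("posterior matrix has no populations")
  probs <- as.matrix(posteriors[populations])
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9) ||
      any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort("invalid posterior matrix: rows must be probabilities summing to 1")
  }
  conf <- apply(probs, 1, max)
  pred <- populations[max.col(probs, ties.method = "first")]

  if (mode == "fixed") {
    if (value <= 0 || value >= 1) abort("fixed threshold must be in (0, 1)")
    thresholds <- stats::setNames(rep(value, length(populations)), populations)
  } else {
    if (value <= 0 || value >= 100) abort("percentile must be in (0, 100)")
    if (!is.null(reference_labels)) {
      ref <- reference_posteriors %||% posteriors
      ref_probs <- as.matrix(ref[populations])
      ref_conf <- apply(ref_probs, 1, max)
      ref_group <- as.character(reference_labels)
    } else {
      ref_conf <- conf
      ref_group <- pred
    }
    thresholds <- vapply(populations, function(pop) {
      x <- ref_conf[!is.na(ref_group) & ref_group == pop]
      if (length(x) == 0L) return(0)
      unname(quantile(x, value / 100))
    }, numeric(1))
  }

  unknown <- unname(conf < thresholds[pred])
  out <- tibble::tibble(
    cell_id = as.character(posteriors$cell_id),
    label = ifelse(unknown, "unknown", pred),
    source = ifelse(unknown, "unknown", "classified"),
    confidence = unname(conf)
  )
  attr(out, "thresholds") <- thresholds
  attr(out, "populations") <- populations
  out
}

#' Cells currently in the unknown pool
#' @param assignment An assignment tibble with `label` column.
#' @return Integer row indices of cells labeled `"unknown"`.
#' @export
unknown_cells <- function(assignment) {
  which(assignment$label == "unknown")
}
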