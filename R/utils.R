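#' @importFrom rlang %||% abort warn
#' @importFrom stats predict quantile rnorm runif rmultinom cor sd asinh
#' @importFrom utils head read.csv write.csv
NULL

UNASSIGNED_TOKENS <- c("", "na", "n/a", "unassigned", "unknown", "unlabeled", "unlabelled")

# Extract the cells x markers numeric matrix from a marker data frame.
# Markers default to every numeric column except `cell_id` and any columns
# named in `exclude`.
marker_matrix <- function(data, markers = NULL, exclude = character()) {
  stopifnot(is.data.frame(data))
  if (is.null(markers)) {
    num <- vapply(data, is.numeric, logical(1))
    markers <- setdiff(names(data)[num], c("cell_id", exclude))
  } else {
    missing <- setdiff(markers, names(data))
    if (length(missing)) {
      abort(paste0("marker column(s) not found: ", paste(missing, collapse = ", ")))
    }
  }
  if (length(markers) == 0L) abort("no marker columns found")
  m <- as.matrix(data[markers])
  if (!is.numeric(m)) abort("marker columns must be numeric")
  if (anyNA(m)) abort("marker values contain missing entries")
  rownames(m) <- cell_ids(data)
  m
}

cell_ids <- function(data) {
  if ("cell_id" %in% names(data)) as.character(data$cell_id) else sprintf("cell_%d", seq_len(nrow(data)))
}

# Resolve a label specification to a factor aligned with rows of `data`.
# `labels` may be a column name in `data` or a vector; NA marks unassigned
# cells.  Unassigned sentinel strings are normalised to NA.
resolve_labels <- function(data, labels, population_names = NULL) {
  if (is.character(labels) && length(labels) == 1L && labels %in% names(data)) {
    labels <- data[[labels]]
  }
  if (length(labels) != nrow(data)) {
    abort(sprintf("labels length (%d) does not match number of cells (%d)",
                  length(labels), nrow(data)))
  }
  as_label_vector(labels, population_names)
}

# Normalise a label vector: factor with levels = population names, NA for
# unassigned cells.
as_label_vector <- function(labels, population_names = NULL) {
  if (is.factor(labels)) {
    lv <- levels(labels)
    labels <- as.character(labels)
  } else {
    labels <- as.character(labels)
    lv <- NULL
  }
  labels[tolower(trimws(ifelse(is.na(labels), "", labels))) %in% UNASSIGNED_TOKENS] <- NA
  if (is.null(population_names)) {
    population_names <- if (!is.null(lv)) intersect(lv, unique(labels)) else unique(labels[!is.na(labels)])
  } else {
    bad <- setdiff(unique(labels[!is.na(labels)]), population_names)
    if (length(bad)) {
      abort(paste0("unknown population(s): ", paste(bad, collapse = ", ")))
    }
  }
  factor(labels, levels = population_names)
}

# Deterministic local RNG scope: runs `expr` under `seed` and restores the
# caller's RNG state afterwards, so package functions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}
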