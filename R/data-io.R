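#' Read a cells-by-markers expression matrix
#'
#' Reads single-cell marker intensities from delimited text (CSV/TSV with a
#' header row of marker names) or from an FCS 3.0/3.1 file.  Raw intensities
#' must be non-negative; the returned table is flagged as untransformed and
#' should normally be passed through [asinh_transform()] before modelling.
#'
#' @param path Path to the input file.
#' @param format One of `"csv"`, `"tsv"`, `"fcs"`.  Defaults from the file
#'   extension.
#' @return A tibble with a `cell_id` column and one numeric column per
#'   marker, carrying a `transformed = FALSE` attribute.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(CD3 = c(1, 0, 4), CD8 = c(2, 0.5, 4)), f, row.names = FALSE)
#' read_markers(f)
#' @export
read_markers <- function(path, format = c("auto", "csv", "tsv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", fcs = "fcs",
                     abort(paste0("cannot infer format from extension '.", ext, "'")))
  }
  if (format == "fcs") {
    parsed <- read_fcs(path)
    values <- parsed$values
    marker_names <- parsed$marker_names
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) abort("no cells: data section is empty")
    values <- as.matrix(df)
    if (!is.numeric(values)) {
      bad <- names(df)[!vapply(df, is.numeric, logical(1))][1]
      abort(sprintf("parse error: column '%s' is not numeric", bad))
    }
    marker_names <- colnames(df)
  }
  if (anyNA(values)) abort("parse error: missing values in data section")
  if (any(values < 0)) {
    abort(sprintf("validation error: negative intensity (%g) in raw data", min(values)))
  }
  if (anyDuplicated(marker_names)) abort("validation error: duplicated marker names")
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  names(out) <- marker_names
  out <- dplyr::bind_cols(tibble::tibble(cell_id = sprintf("cell_%d", seq_len(nrow(out)))), out)
  attr(out, "transformed") <- FALSE
  out
}

#' Variance-stabilising arcsinh transform
#'
#' Applies the standard cytometry transform `asinh(x / cofactor)` to every
#' marker column.  The community-conventional cofactor for CyTOF is 5.
#'
#' @param data A marker data frame (see [read_markers()]).
#' @param cofactor Positive scale divisor; default 5.
#' @param markers Optional character vector of marker columns; defaults to
#'   all numeric columns except `cell_id`.
#' @return `data` with marker columns transformed and attribute
#'   `transformed = TRUE`.
#' @export
asinh_transform <- function(data, cofactor = 5, markers = NULL) {
  check_positive_scalar(cofactor, "cofactor")
  if (isTRUE(attr(data, "transformed"))) {
    abort("data is already arcsinh-transformed (double transform)")
  }
  m <- marker_matrix(data, markers)
  out <- data
  out[colnames(m)] <- tibble::as_tibble(as.data.frame(asinh(m / cofactor), check.names = FALSE))
  attr(out, "transformed") <- TRUE
  attr(out, "cofactor") <- cofactor
  out
}

#' Is a marker table on the transformed scale?
#' @param data A marker data frame.
#' @return `TRUE`, `FALSE`, or `NA` when the provenance is unknown.
#' @export
is_transformed <- function(data) {
  t <- attr(data, "transformed")
  if (is.null(t)) NA else isTRUE(t)
}

#' Read a per-cell label vector
#'
#' Reads one label token per line (or the single column of a delimited
#' file).  Blank, `NA`, and `"unassigned"` tokens map to `NA` (ungated
#' cells).  Population names are inferred in first-appearance order unless
#' supplied.
#'
#' @param path Path to a text file with one label per cell.
#' @param population_names Optional fixed set of canonical population
#'   names; tokens outside it raise an error.
#' @return A factor of length = number of cells with levels =
#'   population names; `NA` marks unassigned cells.
#' @export
read_labels <- function(path, population_names = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tokens <- readLines(path, warn = FALSE)
  as_label_vector(tokens, population_names)
}

#' Write final cell assignments with embedding coordinates
#'
#' Serialises a cell assignment (label + label source) together with its
#' embedding coordinates and the categorical label-axis index to CSV, in the
#' fixed column order `cell_id, label, source, x, y, z`.  The file
#' round-trips losslessly through [read_assignments()].
#'
#' @param assignment A data frame with columns `cell_id`, `label`, `source`.
#' @param embedding A data frame of embedding coordinates for the same
#'   cells (columns `cell_id` and 2 or 3 coordinate columns), or `NULL` to
#'   write zero coordinates.
#' @param path Output file path.
#' @param z Optional numeric label-axis index per cell; computed from the
#'   label ordering via [make_3d_view()] when omitted and the embedding is
#'   two-dimensional.
#' @return Invisibly, the written tibble.
#' @export
write_assignments <- function(assignment, embedding = NULL, path, z = NULL) {
  stopifnot(is.data.frame(assignment), all(c("cell_id", "label", "source") %in% names(assignment)))
  n <- nrow(assignment)
  if (is.null(embedding)) {
    coords <- matrix(0, n, 2)
  } else {
    stopifnot(is.data.frame(embedding))
    if (nrow(embedding) != n) {
      abort(sprintf("cell-count mismatch: %d assignments vs %d embedded cells", n, nrow(embedding)))
    }
    coords <- marker_matrix(embedding)
    if (!identical(cell_ids(embedding), as.character(assignment$cell_id))) {
      abort("assignment and embedding cover different cells (cell_id mismatch)")
    }
  }
  if (is.null(z)) {
    z <- if (ncol(coords) >= 3) coords[, 3] else label_axis_index(assignment$label)
  }
  out <- tibble::tibble(
    cell_id = as.character(assignment$cell_id),
    label = as.character(assignment$label),
    source = as.character(assignment$source),
    x = coords[, 1],
    y = coords[, 2],
    z = as.numeric(z)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read back an assignment file written by [write_assignments()]
#' @param path Path to the CSV file.
#' @return A tibble with columns `cell_id, label, source, x, y, z`.
#' @export
read_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character", label = "character",
                                       source = "character"))
  tibble::as_tibble(df)
}

# Integer Z index for the categorical label axis: canonical populations
# first (in training order when supplied), then novel clusters by numeric
# suffix, then the unknown/noise sentinel last.
label_axis_index <- function(labels, populations = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  novel <- sort(lev[grepl("^new_\\d+$", lev)])
  sentinel <- intersect(c("unknown", "noise", "unassigned"), lev)
  canonical <- if (is.null(populations)) setdiff(lev, c(novel, sentinel))
               else intersect(populations, lev)
  ordering <- unique(c(canonical, setdiff(lev, c(novel, sentinel)), novel, sentinel))
  match(labels, ordering) - 1L
}
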