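# Minimal FCS 3.0 / 3.1 reader.
#
# Supports the list-mode layouts that cover CyTOF exports: $DATATYPE F
# (float32), D (float64) or I with common fixed bit widths, $MODE L, and
# either byte order ($BYTEORD 1,2,3,4 or 4,3,2,1).  Marker names are taken
# from $PnS, falling back to $PnN.  Compensation keywords are ignored.

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(sprintf("parse error: unsupported FCS version header '%s'", version))
  }
  offs <- suppressWarnings(as.integer(trimws(c(
    substr(header, 11, 18), substr(header, 19, 26),   # TEXT begin/end
    substr(header, 27, 34), substr(header, 35, 42)    # DATA begin/end
  ))))
  if (anyNA(offs[1:2])) abort("parse error: malformed TEXT segment offsets in header")

  seek(con, offs[1])
  text <- rawToChar(readBin(con, "raw", offs[2] - offs[1] + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) abort("parse error: empty TEXT segment")
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- trimws(parts[seq(2, length(parts), by = 2)])
  kw <- stats::setNames(vals, keys)

  need <- function(key) {
    if (!key %in% names(kw)) abort(paste0("parse error: missing required keyword ", key))
    kw[[key]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  mode <- toupper(need("$MODE"))
  if (mode != "L") abort(paste0("parse error: unsupported $MODE ", mode))
  if (n_tot == 0L) abort("no cells: $TOT is 0")

  data_beg <- offs[3]
  data_end <- offs[4]
  if (is.na(data_beg) || data_beg == 0L) data_beg <- as.integer(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0L) data_end <- as.integer(need("$ENDDATA"))

  bits <- as.integer(kw[paste0("$P", seq_len(n_par), "B")])
  if (anyNA(bits)) abort("parse error: missing $PnB keyword")
  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    what <- "double"
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(8L, 16L, 32L)) {
      abort("parse error: only uniform 8/16/32-bit $DATATYPE I supported")
    }
    size <- bits[1] %/% 8L
    what <- "integer"
  } else {
    abort(paste0("parse error: unsupported $DATATYPE ", dtype))
  }

  seek(con, data_beg)
  n_values <- n_par * n_tot
  raw_vals <- readBin(con, what, n = n_values, size = size, endian = endian,
                      signed = size > 2L)
  if (length(raw_vals) < n_values) {
    abort(sprintf("parse error: DATA segment truncated (%d of %d values)",
                  length(raw_vals), n_values))
  }
  values <- matrix(as.numeric(raw_vals), nrow = n_tot, ncol = n_par, byrow = TRUE)

  short <- kw[paste0("$P", seq_len(n_par), "N")]
  stain <- kw[paste0("$P", seq_len(n_par), "S")]
  marker_names <- ifelse(is.na(stain) | stain == "", short, stain)
  marker_names[is.na(marker_names) | marker_names == ""] <-
    paste0("P", which(is.na(marker_names) | marker_names == ""))

  list(values = values, marker_names = unname(marker_names), keywords = kw)
}
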