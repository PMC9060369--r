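# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Small 3-canonical + 1-novel benchmark for structural pipeline tests.
small_benchmark <- function() {
  memo("small_benchmark", function() {
    specs <- benchmark_populations(3, 1, n_markers = 6, separation = 6, seed = 1)
    simulate_cells(specs, 2500, labeled_fraction = 0.5, seed = 1)
  })
}

# Acceptance-scale benchmark: 5 canonical + 2 novel, 6 sigma, n = 10,000.
acceptance_benchmark <- function() {
  memo("acceptance_benchmark", function() {
    specs <- benchmark_populations(5, 2, n_markers = 10, separation = 6, seed = 1)
    simulate_cells(specs, 10000, labeled_fraction = 0.5, seed = 1)
  })
}

# Full pipeline result on the acceptance benchmark (shared by the
# planted-recovery and calibration-monotonicity checks).
acceptance_pipeline <- function() {
  memo("acceptance_pipeline", function() {
    deepgate(acceptance_benchmark(), "label", seed = 1)
  })
}

# Minimal FCS 3.0 writer (list-mode, float32) so the binary reader can be
# tested without shipping binary fixtures.
write_fcs_fixture <- function(path, values, short_names, stain_names = NULL,
                              version = "FCS3.0", datatype = "F",
                              drop_keyword = NULL) {
  n_par <- ncol(values)
  n_tot <- nrow(values)
  kw <- c("$DATATYPE", datatype, "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", n_par, "$TOT", n_tot)
  for (p in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dB", p), "32", sprintf("$P%dN", p), short_names[p])
    if (!is.null(stain_names) && !is.na(stain_names[p])) {
      kw <- c(kw, sprintf("$P%dS", p), stain_names[p])
    }
  }
  if (!is.null(drop_keyword)) {
    ix <- which(kw == drop_keyword)
    if (length(ix)) kw <- kw[-c(ix, ix + 1L)]
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_beg <- 100L
  text_end <- text_beg + nchar(text) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  header <- sprintf("%-10s%8d%8d%8d%8d%8d%8d", version, text_beg, text_end,
                    data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeBin(raw(text_beg - nchar(header)), con)
  writeChar(text, con, eos = NULL)
  # list mode: one event (row) at a time
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
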