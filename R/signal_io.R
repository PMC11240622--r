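#' Construct a single-lead ECG record
#'
#' The basic container passed between pipeline stages: a sampled amplitude
#' sequence in millivolts plus its sampling frequency, optionally carrying
#' R-peak annotations (0-based sample indices) and per-beat class labels.
#'
#' @param samples Numeric vector of amplitudes (mV). Must be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @param r_peaks Optional integer vector of 0-based R-peak sample indices,
#'   strictly increasing, each in `[0, length(samples))`.
#' @param labels Optional character vector of per-beat class tags
#'   (e.g. `"normal"`, `"anomalous"`); when present must have one entry per
#'   R-peak.
#' @param meta Free-form list describing the source.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, r_peaks = NULL, labels = NULL, meta = list()) {
  samples <- as.numeric(samples)
  stopifnot_finite(samples, "samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (!is.null(r_peaks)) {
    r_peaks <- as.integer(round(r_peaks))
    if (any(r_peaks < 0L) || any(r_peaks >= length(samples)))
      stop("r_peaks must lie in [0, length(samples))")
    if (length(r_peaks) > 1L && any(diff(r_peaks) <= 0L))
      stop("r_peaks must be strictly increasing")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (is.null(r_peaks) || length(labels) != length(r_peaks))
      stop("labels must have one entry per R-peak")
  }
  structure(list(samples = samples, fs = fs, r_peaks = r_peaks,
                 labels = labels, meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)", length(x$samples),
              x$fs, length(x$samples) / x$fs))
  if (!is.null(x$r_peaks)) cat(sprintf(", %d annotated beats", length(x$r_peaks)))
  cat("\n")
  invisible(x)
}

#' Read a single-lead signal from CSV
#'
#' Accepts either a one-column file of amplitudes (mV) or a two-column
#' `time, amplitude` file. With two columns the sampling frequency implied by
#' the median time step is cross-checked against `fs` and must agree within
#' 1\%.
#'
#' @param path CSV file path. A header row is detected automatically.
#' @param fs Sampling frequency in Hz.
#' @return An [ecg_record] without annotations.
#' @export
read_csv_signal <- function(path, fs) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: ", path, " is empty")
  first <- strsplit(lines[[1L]], ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stop("parse error: ", path, " has no data rows")
  fields <- strsplit(body, ",")
  ncol <- length(fields[[1L]])
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)) || length(v) != ncol, TRUE))
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: non-numeric row", path,
                 bad[1L] + if (has_header) 1L else 0L))
  m <- do.call(rbind, vals)
  if (ncol >= 2L) {
    tstep <- stats::median(diff(m[, 1L]))
    if (is.na(tstep) || tstep <= 0)
      stop("parse error: time column is not increasing in ", path)
    if (abs(1 / tstep - fs) / fs > 0.01)
      stop(sprintf("fs = %g Hz disagrees with median time step (%.6g s) by > 1%%",
                   fs, tstep))
    amp <- m[, 2L]
  } else amp <- m[, 1L]
  ecg_record(amp, fs, meta = list(source = path))
}

#' Write a signal to CSV
#'
#' Writes `time, amplitude` columns at full double precision so that
#' `read_csv_signal(write_csv_signal(x))` round-trips to 1e-12. Annotations
#' are not stored in the CSV; use the JSON sidecar written by the pipeline.
#'
#' @param record An [ecg_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_signal <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  t <- (seq_along(record$samples) - 1) / record$fs
  lines <- c("time,amplitude",
             paste(format(t, digits = 17, scientific = TRUE, trim = TRUE),
                   format(record$samples, digits = 17, scientific = TRUE, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a beats-by-features matrix
#'
#' @param values Numeric matrix, one row per beat.
#' @param names Unique feature names, one per column; the name prefix records
#'   which transform produced the feature (`fdct_*`, `rw_*`, `frwt_*`).
#' @param labels Per-beat class labels (length `nrow(values)`).
#' @param scaling Optional list with `center`/`scale` vectors recording the
#'   z-scoring statistics fitted on the training split.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, names, labels, scaling = NULL) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("feature matrix must have at least one row")
  if (anyDuplicated(names)) stop("duplicate feature names")
  if (length(names) != ncol(values)) stop("one name per column required")
  if (length(labels) != nrow(values)) stop("one label per row required")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at beat %d, feature '%s'",
                 bad[1L], names[bad[2L]]))
  }
  colnames(values) <- names
  structure(list(values = values, names = as.character(names),
                 labels = as.character(labels), scaling = scaling),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d beats x %d features; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(names(table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' The CSV has one quoted header row of feature names plus a final `label`
#' column; values are written at full precision so the round-trip is exact to
#' 1e-12.
#'
#' @param matrix A [feature_matrix].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_matrix].
#' @export
write_feature_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  df <- as.data.frame(matrix$values, check.names = FALSE)
  df$label <- matrix$labels
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"label" %in% names(df)) stop("feature table lacks a 'label' column")
  labs <- df$label
  df$label <- NULL
  vals <- vapply(df, as.numeric, numeric(nrow(df)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(df))
  feature_matrix(vals, names(df), labs)
}
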