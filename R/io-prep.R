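# Data interchange and envelope preparation: analytic-signal amplitude
# envelopes (the slow "energy" signals on which instantaneous causality is
# modeled) and anti-aliased downsampling.

#' Time series table
#'
#' @param values n x p numeric matrix (rows = time points, columns =
#'   variables/sources).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param names Optional unique column labels; defaults to existing
#'   column names or `v1..vp`.
#' @return A `ts_table` object.
#' @export
ts_table <- function(values, sampling_rate_hz = 1, names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("values must be finite numeric")
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (is.null(names)) names <- colnames(values)
  if (is.null(names)) names <- paste0("v", seq_len(ncol(values)))
  if (anyDuplicated(names)) stop("duplicate variable names")
  if (length(names) != ncol(values)) stop("names length must match columns")
  colnames(values) <- names
  structure(list(values = values, sampling_rate_hz = sampling_rate_hz,
                 names = names),
            class = "ts_table")
}

#' @export
print.ts_table <- function(x, ...) {
  cat("ts_table:", nrow(x$values), "samples x", ncol(x$values),
      "variables @", x$sampling_rate_hz, "Hz\n")
  invisible(x)
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope via the analytic signal
#'
#' Per column, the modulus of the analytic signal (FFT construction of the
#' Hilbert transform): the slowly varying energy of an oscillatory signal.
#' The first and last 2% of samples are affected by the circularity of the
#' transform; set `trim_edges = TRUE` to drop them.
#'
#' @param table A [ts_table()] (or plain matrix, assumed 1 Hz).
#' @param trim_edges Drop 2% of samples at each end.
#' @return A `ts_table` of envelopes at the same sampling rate.
#' @export
amplitude_envelope <- function(table, trim_edges = FALSE) {
  if (!inherits(table, "ts_table")) table <- ts_table(table)
  n <- nrow(table$values)
  if (n < 8) stop("need at least 8 samples for an envelope")
  env <- apply(table$values, 2, function(col) Mod(analytic_signal(col)))
  if (trim_edges) {
    k <- ceiling(0.02 * n)
    env <- env[(k + 1):(n - k), , drop = FALSE]
  }
  ts_table(env, table$sampling_rate_hz, table$names)
}

#' Anti-aliased downsampling of a time series table
#'
#' Rational-factor polyphase resampling of every column to `target_hz`;
#' only downsampling (or the identity) is supported. Output length is
#' `floor(n * target / source)`.
#'
#' @param table A [ts_table()].
#' @param target_hz Target rate, `0 < target_hz <= sampling_rate_hz`.
#' @return A `ts_table` at the new rate.
#' @export
resample_table <- function(table, target_hz) {
  stopifnot(inherits(table, "ts_table"))
  if (target_hz <= 0) stop("target_hz must be positive")
  if (target_hz > table$sampling_rate_hz) {
    stop("upsampling is not supported (target_hz > sampling rate)")
  }
  if (isTRUE(all.equal(target_hz, table$sampling_rate_hz))) return(table)
  frac <- ratio_pq(target_hz / table$sampling_rate_hz)
  n <- nrow(table$values)
  n_out <- floor(n * target_hz / table$sampling_rate_hz)
  # reflect-pad to suppress the polyphase filter's edge transients
  pad <- min(n - 1, 3 * frac$q)
  pad_out <- floor(pad * frac$p / frac$q)
  out <- apply(table$values, 2, function(col) {
    ext <- c(col[(pad + 1):2], col, col[(n - 1):(n - pad)])
    r <- signal::resample(ext, frac$p, frac$q)
    r[pad_out + seq_len(n_out)]
  })
  ts_table(as.matrix(out), target_hz, table$names)
}

# small rational approximation of a ratio in (0, 1]
ratio_pq <- function(ratio, max_den = 10000) {
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9 && round(p) >= 1) {
      return(list(p = as.integer(round(p)), q = as.integer(q)))
    }
  }
  stop("cannot express resampling ratio as a small rational number")
}

#' Read a delimited numeric time series table
#'
#' @param path CSV/TSV file, rows = time points, columns = variables,
#'   optional header of unique names.
#' @param sampling_rate_hz Sampling rate of the stored series.
#' @param header Does the first row carry variable names? If `FALSE`,
#'   names `v1..vp` are generated.
#' @param sep Field separator; guessed from the extension by default.
#' @return A `ts_table`.
#' @export
read_ts_table <- function(path, sampling_rate_hz = 1, header = TRUE,
                          sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged rows in ", path, ": line ", bad, " has ", widths[bad],
         " fields, expected ", widths[1])
  }
  names <- NULL
  if (header) {
    names <- trimws(fields[[1]])
    fields <- fields[-1]
    if (length(fields) == 0) stop("no data rows in ", path)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(trimws(unlist(fields))), nrow = length(fields),
           byrow = TRUE)
  )
  if (any(is.na(vals))) {
    bad <- which(rowSums(is.na(vals)) > 0)[1] + as.integer(header)
    stop("non-numeric cell in ", path, " at line ", bad)
  }
  ts_table(vals, sampling_rate_hz, names)
}

#' Write a time series table as delimited text
#'
#' @param table A [ts_table()].
#' @param path Output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly. Round-trips with [read_ts_table()] within
#'   float formatting precision.
#' @export
write_ts_table <- function(table, path) {
  stopifnot(inherits(table, "ts_table"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table$values, path, sep = sep, row.names = FALSE,
                     col.names = table$names, quote = FALSE)
  invisible(path)
}
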