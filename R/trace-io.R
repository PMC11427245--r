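#' Read recordings from disk
#'
#' Supported formats: delimited text (`csv`, `tsv`) with waves in columns and
#' an optional single header row, and raw little-endian 16-bit integer binary
#' (`raw16`) with a JSON sidecar `<path>.json` holding
#' `{fs_hz, scale, offset, units}` (samples are reconstructed as
#' `value * scale + offset`). With `format = "auto"` the format is inferred
#' from the extension (`.csv`; `.tsv`/`.txt`; `.dat`/`.bin`/`.raw`).
#'
#' @param path Path to the data file.
#' @param format One of `"csv"`, `"tsv"`, `"raw16"`, `"auto"`.
#' @param fs Sampling rate in Hz. Required for text formats (which carry no
#'   rate); ignored for `raw16`, whose sidecar provides it.
#' @param units Unit label for text formats (default `"pA"`).
#' @return A list of [new_trace()] objects, one per wave (column).
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write.csv(data.frame(w0 = rnorm(100), w1 = rnorm(100)), p, row.names = FALSE)
#' traces <- read_trace(p, fs = 1000)
#' length(traces)
read_trace <- function(path, format = c("auto", "csv", "tsv", "raw16"),
                       fs = NULL, units = "pA") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv",
      dat = "raw16", bin = "raw16", raw = "raw16",
      stop("cannot infer format from extension '.", ext, "'")
    )
  }
  switch(format,
    csv = read_trace_text(path, sep = ",", fs = fs, units = units),
    tsv = read_trace_text(path, sep = "\t", fs = fs, units = units),
    raw16 = read_trace_raw16(path)
  )
}

read_trace_text <- function(path, sep, fs, units) {
  if (is.null(fs)) stop("`fs` must be supplied for text formats")
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- read.table(path, sep = sep, header = has_header,
                   colClasses = "numeric")
  if (any(vapply(df, function(col) anyNA(col), TRUE))) {
    stop("non-numeric cells in ", path)
  }
  lapply(seq_along(df), function(j) {
    new_trace(df[[j]], fs = fs, units = units,
              source = sprintf("%s[%d]", path, j))
  })
}

read_trace_raw16 <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("raw16 requires a sidecar metadata file: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("fs_hz", "scale", "offset", "units")
  if (!all(need %in% names(meta))) {
    stop("raw16 sidecar missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  }
  n <- file.size(path) / 2L
  raw <- readBin(path, what = "integer", n = n, size = 2L,
                 signed = TRUE, endian = "little")
  list(new_trace(raw * meta$scale + meta$offset, fs = meta$fs_hz,
                 units = meta$units, source = path))
}

#' Write a trace to disk
#'
#' Text formats store the samples to full `%.17g` precision, so a text
#' roundtrip reproduces the samples exactly; `raw16` quantises to the sidecar
#' scale (exact when the samples are representable on the integer grid).
#'
#' @param trace A `psc_trace`, or (text formats only) a list of equal-length
#'   traces written as columns.
#' @param path Output path.
#' @param format `"csv"`, `"tsv"`, or `"raw16"`.
#' @param scale,offset Quantisation for `raw16`: integers stored are
#'   `round((sample - offset) / scale)`.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path, format = c("csv", "tsv", "raw16"),
                        scale = 0.1, offset = 0) {
  format <- match.arg(format)
  traces <- if (inherits(trace, "psc_trace")) list(trace) else trace
  stopifnot(all(vapply(traces, inherits, TRUE, "psc_trace")))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    if (length(unique(lengths(lapply(traces, `[[`, "samples")))) != 1L) {
      stop("all waves must have equal length for column output")
    }
    cols <- lapply(traces, function(tr) sprintf("%.17g", tr$samples))
    lines <- c(paste(sprintf("wave%d", seq_along(cols) - 1L), collapse = sep),
               do.call(paste, c(cols, sep = sep)))
    writeLines(lines, path)
  } else {
    if (length(traces) != 1L) stop("raw16 stores a single wave per file")
    tr <- traces[[1]]
    ints <- as.integer(round((tr$samples - offset) / scale))
    if (any(abs(ints) > 32767)) stop("samples overflow int16 at this scale")
    writeBin(ints, path, size = 2L, endian = "little")
    jsonlite::write_json(
      list(fs_hz = tr$fs, scale = scale, offset = offset, units = tr$units),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Split a trace into fixed-duration epochs
#'
#' A continuous acquisition is cut into `floor(duration / epoch_s)` waves of
#' equal sample count. Any remainder shorter than `epoch_s` is kept as a
#' final wave flagged `partial = TRUE` rather than silently discarded.
#' Concatenating the returned epochs reproduces the original samples.
#'
#' @inheritParams trace_duration
#' @param epoch_s Epoch duration in seconds, `0 < epoch_s <= duration`.
#' @return List of `psc_trace` epochs.
#' @export
#' @examples
#' tr <- new_trace(rnorm(4000), fs = 1000)  # 4 s
#' length(split_trace(tr, 1))               # 4 waves
split_trace <- function(trace, epoch_s) {
  stopifnot(inherits(trace, "psc_trace"))
  dur <- trace_duration(trace)
  if (!is.numeric(epoch_s) || length(epoch_s) != 1L || epoch_s <= 0) {
    stop("`epoch_s` must be a single positive duration")
  }
  if (epoch_s > dur + 1e-12) stop("`epoch_s` longer than the trace")
  n_per <- round(epoch_s * trace$fs)
  n <- length(trace$samples)
  n_full <- n %/% n_per
  out <- vector("list", n_full + as.integer(n %% n_per > 0))
  for (k in seq_len(n_full)) {
    i0 <- (k - 1L) * n_per + 1L
    out[[k]] <- new_trace(trace$samples[i0:(i0 + n_per - 1L)], trace$fs,
                          units = trace$units,
                          source = sprintf("%s#epoch%d", trace$source, k))
  }
  if (n %% n_per > 0) {
    out[[n_full + 1L]] <- new_trace(
      trace$samples[(n_full * n_per + 1L):n], trace$fs, units = trace$units,
      source = sprintf("%s#epoch%d", trace$source, n_full + 1L),
      partial = TRUE)
  }
  out
}
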