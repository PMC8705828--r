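#' Construct a sampled electrophysiology trace
#'
#' A `trace` is the universal signal container of the package: a uniformly
#' sampled 1-D signal with physical units and a sampling rate. Sample `k`
#' (1-based in R) maps to time `t0_s + (k - 1) / rate_hz`; windows are
#' half-open `[start, end)` in seconds throughout the package.
#'
#' @param samples Numeric vector of samples, length >= 2, all finite.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param units One of `"pA"` (voltage-clamp current), `"mV"` (current-clamp
#'   voltage) or `"uV"` (extracellular LFP).
#' @param t0_s Time of the first sample in seconds (default 0).
#' @param meta Named list of free-form annotations (cell id, slice id,
#'   holding potential, ...).
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(sin(seq(0, 1, by = 1e-3)), rate_hz = 1000, units = "uV")
#' trace_duration(tr)
#' @export
trace <- function(samples, rate_hz, units = c("pA", "mV", "uV"),
                  t0_s = 0, meta = list()) {
  units <- sub("µ", "u", units[1L])
  units <- match.arg(units, c("pA", "mV", "uV"))
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("trace samples must all be finite", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    stop("rate_hz must be a single positive number", call. = FALSE)
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz), units = units,
         t0_s = as.numeric(t0_s), meta = meta),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz [%s], t = [%g, %g) s\n",
              length(x$samples), x$rate_hz, x$units, x$t0_s,
              x$t0_s + length(x$samples) / x$rate_hz))
  invisible(x)
}

#' @rdname trace
#' @param x A `trace`.
#' @export
is_trace <- function(x) inherits(x, "trace")

#' Sample times of a trace
#'
#' @param x A `trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(is_trace(x))
  x$t0_s + (seq_along(x$samples) - 1) / x$rate_hz
}

#' Duration of a trace in seconds
#'
#' The duration covered by the half-open support `[t0, t0 + n/rate)`.
#'
#' @param x A `trace`.
#' @export
trace_duration <- function(x) {
  stopifnot(is_trace(x))
  length(x$samples) / x$rate_hz
}

#' Extract a time window from a trace
#'
#' Returns the half-open window `[start_s, end_s)`. The first sample of the
#' result is the first sample at or after `start_s`; its time becomes the
#' new `t0_s`, so slicing then re-slicing with relative times equals slicing
#' once with absolute times.
#'
#' @param x A `trace`.
#' @param start_s,end_s Window bounds in seconds (absolute time).
#' @return A `trace` covering the window.
#' @export
slice_trace <- function(x, start_s, end_s) {
  stopifnot(is_trace(x))
  t_end <- x$t0_s + length(x$samples) / x$rate_hz
  if (!(start_s < end_s))
    stop("empty window: start_s must be < end_s", call. = FALSE)
  tol <- 0.5 / x$rate_hz
  if (start_s < x$t0_s - tol || end_s > t_end + tol)
    stop("window [", start_s, ", ", end_s, ") outside trace support",
         call. = FALSE)
  i0 <- ceiling((start_s - x$t0_s) * x$rate_hz - 1e-9) + 1
  i1 <- ceiling((end_s - x$t0_s) * x$rate_hz - 1e-9)   # last sample < end_s
  i0 <- max(i0, 1L)
  i1 <- min(i1, length(x$samples))
  if (i1 - i0 + 1 < 2L)
    stop("window contains fewer than 2 samples", call. = FALSE)
  trace(x$samples[i0:i1], x$rate_hz, x$units,
        t0_s = x$t0_s + (i0 - 1) / x$rate_hz, meta = x$meta)
}

# header serialization shared by the text and binary containers
.trace_header <- function(x) {
  c(sprintf("rate_hz=%.17g", x$rate_hz),
    sprintf("units=%s", x$units),
    sprintf("t0_s=%.17g", x$t0_s))
}

.parse_header <- function(lines) {
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed header line: ", lines[bad][1L], call. = FALSE)
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  if (!all(c("rate_hz", "units") %in% names(vals)))
    stop("trace header must declare rate_hz and units", call. = FALSE)
  vals
}

#' Read a trace from disk
#'
#' Two containers are supported. `columnar_text`: `#`-prefixed header lines
#' (`key=value`; `rate_hz` and `units` mandatory) followed by one sample per
#' line, or two whitespace-separated columns (time, value) of which the
#' second is used. `binary_container`: the same header as a length-prefixed
#' ASCII block followed by the samples as little-endian doubles; this
#' round-trips bit-exactly with [write_trace()].
#'
#' @param path File path.
#' @param format `"columnar_text"` or `"binary_container"`; default guesses
#'   from the file's leading byte.
#' @return A `trace`.
#' @export
read_trace <- function(path, format = c("auto", "columnar_text",
                                        "binary_container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readBin(path, "raw", n = 4L)
    format <- if (length(first) >= 4L && rawToChar(first) == "EPHY")
      "binary_container" else "columnar_text"
  }
  if (format == "binary_container") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 4L, useBytes = TRUE)
    if (!identical(magic, "EPHY")) stop("not a binary trace container",
                                        call. = FALSE)
    hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    header <- strsplit(readChar(con, hlen, useBytes = TRUE), "\n",
                       fixed = TRUE)[[1L]]
    n <- readBin(con, "integer", 1L, size = 8L, endian = "little")
    samples <- readBin(con, "double", n, size = 8L, endian = "little")
    kv <- .parse_header(header)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    kv <- .parse_header(sub("^#\\s*", "", lines[hdr]))
    body <- lines[!hdr & nzchar(trimws(lines))]
    fields <- strsplit(trimws(body), "\\s+|,")
    ncol <- length(fields[[1L]])
    samples <- suppressWarnings(
      as.numeric(vapply(fields, `[`, "", ncol)))
  }
  rate <- suppressWarnings(as.numeric(kv[["rate_hz"]]))
  if (!isTRUE(is.finite(rate)) || rate <= 0)
    stop("invalid rate_hz in header: ", kv[["rate_hz"]], call. = FALSE)
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("non-finite samples in ", path, call. = FALSE)
  t0 <- if ("t0_s" %in% names(kv)) as.numeric(kv[["t0_s"]]) else 0
  trace(samples, rate, kv[["units"]], t0_s = t0)
}

#' Write a trace to disk
#'
#' @param x A `trace`.
#' @param path Destination file.
#' @param format `"columnar_text"` (samples printed with 17 significant
#'   digits, lossless for doubles to printed precision) or
#'   `"binary_container"` (bit-exact).
#' @param two_column For text output, also write a time column.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, format = c("columnar_text",
                                            "binary_container"),
                        two_column = FALSE) {
  stopifnot(is_trace(x))
  format <- match.arg(format)
  if (format == "binary_container") {
    header <- paste(.trace_header(x), collapse = "\n")
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("EPHY", con, eos = NULL, useBytes = TRUE)
    writeBin(nchar(header, type = "bytes"), con, size = 4L,
             endian = "little")
    writeChar(header, con, eos = NULL, useBytes = TRUE)
    writeBin(length(x$samples), con, size = 8L, endian = "little")
    writeBin(x$samples, con, size = 8L, endian = "little")
  } else {
    body <- if (two_column)
      sprintf("%.17g %.17g", trace_times(x), x$samples)
    else sprintf("%.17g", x$samples)
    writeLines(c(paste0("# ", .trace_header(x)), body), path)
  }
  invisible(path)
}
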