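#' Source-space region time-series recording
#'
#' Container for one subject-visit: a regions x samples matrix of ROI
#' time series (one row per parcellated region) and its sampling rate. This is
#' the pipeline's entry point, downstream of beamformer projection: the rows
#' are assumed to already be source-space region signals.
#'
#' @param data Numeric matrix, regions x samples, finite values.
#' @param sample_rate Sampling rate in Hz, `> 0`.
#' @param subject,visit Optional identifiers carried through the pipeline.
#' @return An object of class `roi_recording`.
#' @export
roi_recording <- function(data, sample_rate, subject = NA_character_,
                          visit = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  structure(list(data = data, sample_rate = sample_rate,
                 subject = as.character(subject), visit = as.character(visit)),
            class = "roi_recording")
}

#' @export
print.roi_recording <- function(x, ...) {
  cat(sprintf("<roi_recording> %d regions x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate,
              if (is.na(x$subject)) "" else
                sprintf(" [%s/%s]", x$subject, x$visit)))
  invisible(x)
}

#' Fixed-length epoch set
#'
#' Epochs x regions x samples array of fixed-length windows cut from a
#' recording, optionally tagged with the frequency band it has been filtered
#' in. A band tag may be set only once: filtering an already band-filtered
#' epoch set is rejected.
#'
#' @param epochs 3-d numeric array `[epoch, region, sample]`.
#' @param sample_rate Sampling rate in Hz.
#' @param band Optional [frequency_band()] tag.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, sample_rate, band = NULL) {
  if (!is.array(epochs) || length(dim(epochs)) != 3L)
    stop("epochs must be a 3-d array [epoch, region, sample]", call. = FALSE)
  if (dim(epochs)[1L] < 1L)
    stop("epoch set must contain at least one epoch", call. = FALSE)
  if (!is.null(band) && !inherits(band, "frequency_band"))
    stop("band must be a frequency_band or NULL", call. = FALSE)
  structure(list(epochs = epochs, sample_rate = sample_rate, band = band),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d regions x %d samples @ %g Hz%s\n",
              d[1L], d[2L], d[3L], x$sample_rate,
              if (is.null(x$band)) " (broadband)" else
                sprintf(" [%s]", x$band$name)))
  invisible(x)
}

#' Write / read a region recording as plain text
#'
#' Simple documented array format: a `#`-prefixed header line holding
#' `sample_rate`, `subject` and `visit`, followed by one tab-separated row of
#' samples per region.
#'
#' @param rec A [roi_recording()].
#' @param path File path.
#' @return `write_roi_recording()` returns `path` invisibly;
#'   `read_roi_recording()` returns a [roi_recording()].
#' @export
write_roi_recording <- function(rec, path) {
  stopifnot(inherits(rec, "roi_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate=%.10g subject=%s visit=%s",
                     rec$sample_rate, rec$subject, rec$visit), con)
  utils::write.table(format(rec$data, digits = 10, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_recording
#' @export
read_roi_recording <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("missing recording header line", call. = FALSE)
  fields <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                          vapply(kv, `[[`, character(1), 1L))
  data <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t"))
  dimnames(data) <- NULL
  roi_recording(data, as.numeric(vals[["sample_rate"]]),
                subject = vals[["subject"]], visit = vals[["visit"]])
}
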