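# Signal containers and delimited-text I/O.
#
# Index convention used throughout the package: sample indices are 0-based and
# ranges are half-open, i.e. a signal of length L occupies indices [0, L).
# Human-readable CLI output converts to 1-based at the printing boundary only.

#' Construct a sampled single-channel signal
#'
#' A signal is an amplitude series (conventionally microvolts) together with
#' its sampling frequency. Sample indices everywhere in this package are
#' 0-based.
#'
#' @param samples Numeric vector of amplitudes; all values must be finite.
#' @param fs Sampling frequency in Hz; must be a single positive number.
#' @return An object of class `eeg_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' s <- eeg_signal(sin(seq(0, 2 * pi, length.out = 100)), fs = 256)
#' signal_length(s)
#' @export
eeg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("a signal needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Number of samples in a signal
#' @param signal An `eeg_signal`.
#' @return Integer length L; valid sample indices are `0:(L-1)`.
#' @export
signal_length <- function(signal) length(signal$samples)

# Amplitude at 0-based index (vectorized). Single conversion point to R's
# 1-based storage.
xval <- function(signal, idx) signal$samples[idx + 1L]

#' Construct a validated set of peak annotations
#'
#' Ground-truth peak locations as 0-based sample indices. Input is sorted and
#' deduplicated; indices outside `[0, signal_length)` are an error.
#'
#' @param indices Integer vector of 0-based sample indices.
#' @param signal_length Length of the annotated signal.
#' @return An object of class `annotation_set`: a sorted integer vector with
#'   attribute `signal_length`.
#' @export
annotation_set <- function(indices, signal_length) {
  indices <- as.integer(round(as.numeric(indices)))
  signal_length <- as.integer(signal_length)
  bad <- indices < 0L | indices >= signal_length
  if (any(bad)) {
    stop(sprintf("annotation index %d outside [0, %d)",
                 indices[which(bad)[1L]], signal_length), call. = FALSE)
  }
  out <- sort(unique(indices))
  structure(out, signal_length = signal_length, class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d peak indices on a %d-sample signal\n",
              length(x), attr(x, "signal_length")))
  invisible(x)
}

#' Read a sampled signal from delimited text
#'
#' Accepts one numeric value per row, comma- or whitespace-delimited, with an
#' optional single (non-numeric) header row and optional `#`-prefixed comment
#' lines. The sampling frequency is taken from a comment line of the form
#' `# fs: 256` if present, otherwise from the `fs` argument; supplying `fs`
#' overrides the file.
#'
#' @param path Path to the text file.
#' @param fs Sampling frequency in Hz; required when the file carries none.
#' @param column For multi-column files, which column holds the amplitudes;
#'   defaults to the last column (e.g. the `v` of a `t,v` table).
#' @return An [eeg_signal()].
#' @seealso [write_signal()]
#' @export
read_signal <- function(path, fs = NULL, column = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  file_fs <- NULL
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("fs\\s*[:=]\\s*([0-9.eE+-]+)", cl))[[1L]]
    if (length(m) == 2L) file_fs <- as.numeric(m[2L])
  }
  keep <- !is_comment & nzchar(trimws(lines))
  body <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(body) == 0L) stop("empty signal file: ", path, call. = FALSE)

  split_row <- function(s) strsplit(trimws(s), "[,;[:space:]]+")[[1L]]
  first <- suppressWarnings(as.numeric(split_row(body[1L])))
  has_header <- any(is.na(first))
  if (has_header) {
    body <- body[-1L]
    line_no <- line_no[-1L]
    if (length(body) == 0L) stop("signal file has a header but no data rows: ",
                                 path, call. = FALSE)
  }
  rows <- lapply(body, split_row)
  ncol <- length(rows[[1L]])
  if (is.null(column)) column <- ncol
  vals <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    if (length(r) < column) {
      stop(sprintf("line %d of %s has %d field(s), need column %d",
                   line_no[i], path, length(r), column), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(r[[column]]))
    if (is.na(v)) {
      stop(sprintf("non-numeric value %s on line %d of %s",
                   sQuote(r[[column]]), line_no[i], path), call. = FALSE)
    }
    v
  }, numeric(1L))

  if (is.null(fs)) fs <- file_fs
  if (is.null(fs)) {
    stop("sampling frequency not in file header; pass fs=", call. = FALSE)
  }
  eeg_signal(vals, fs)
}

#' Write a signal as delimited text
#'
#' Emits a `# fs: <Hz>` comment header followed by one amplitude per row, the
#' format [read_signal()] accepts.
#'
#' @param signal An [eeg_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "eeg_signal"))
  writeLines(c(sprintf("# fs: %.10g", signal$fs),
               format(signal$samples, digits = 15, trim = TRUE,
                      scientific = FALSE)),
             path)
  invisible(path)
}

#' Read peak annotations (one 0-based index per row)
#'
#' Indices are validated against the signal length, sorted and deduplicated.
#' An empty file yields an empty annotation set.
#'
#' @param path Path to the text file; `#` comments and blank lines ignored.
#' @param signal_length Length of the signal the annotations refer to.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, signal_length) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(annotation_set(integer(0), signal_length))
  vals <- suppressWarnings(as.numeric(lines))
  if (any(is.na(vals))) {
    stop("non-integer annotation ", sQuote(lines[which(is.na(vals))[1L]]),
         " in ", path, call. = FALSE)
  }
  annotation_set(vals, signal_length)
}

#' Write peak annotations, one 0-based index per row
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  writeLines(format(as.integer(annotations)), path)
  invisible(path)
}

#' Split a labelled recording into training and testing partitions
#'
#' The training partition takes samples `[0, boundary)`, the testing partition
#' `[boundary, L)`. Annotations are routed to the partition containing them,
#' and testing annotations are re-based to the testing partition's origin
#' (index `boundary` becomes 0).
#'
#' @param signal An [eeg_signal()].
#' @param annotations An [annotation_set()] on the same signal.
#' @param boundary 0-based split index, strictly inside `(0, L)`; both
#'   partitions must be non-empty.
#' @return A list with elements `train` and `test`, each a list holding
#'   `signal` and `annotations`.
#' @examples
#' s <- eeg_signal(rnorm(100), fs = 256)
#' a <- annotation_set(c(10, 60), 100)
#' halves <- split_recording(s, a, 50)
#' as.integer(halves$test$annotations)  # 60 re-based to 10
#' @export
split_recording <- function(signal, annotations, boundary) {
  stopifnot(inherits(signal, "eeg_signal"))
  L <- signal_length(signal)
  boundary <- as.integer(boundary)
  if (length(boundary) != 1L || is.na(boundary) ||
      boundary <= 0L || boundary >= L) {
    stop(sprintf("boundary must lie strictly inside (0, %d)", L),
         call. = FALSE)
  }
  ann <- as.integer(annotations)
  in_train <- ann < boundary
  list(
    train = list(
      signal = eeg_signal(signal$samples[seq_len(boundary)], signal$fs),
      annotations = annotation_set(ann[in_train], boundary)
    ),
    test = list(
      signal = eeg_signal(signal$samples[(boundary + 1L):L], signal$fs),
      annotations = annotation_set(ann[!in_train] - boundary, L - boundary)
    )
  )
}
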