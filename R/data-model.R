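#' Flash event markers
#'
#' Builds the marker table attached to a [continuous_recording()]. Each row
#' describes one speller flash: the sample at which the flash appeared, which
#' of the 13 grid lines flashed (`0..5` rows, `6..12` columns), and whether
#' that line contains the attended character.
#'
#' @param onset_sample Integer vector of 0-based sample indices.
#' @param line_index Integer vector in `0..12`.
#' @param is_target Logical vector; `TRUE` when the flashed line contains the
#'   attended character.
#' @param code Integer flash code carried alongside the marker (defaults to
#'   `line_index + 1`).
#' @return A `data.frame` with columns `onset_sample`, `code`, `line_index`,
#'   `is_target`, ordered by onset.
#' @export
flash_markers <- function(onset_sample = integer(0), line_index = integer(0),
                          is_target = logical(0), code = line_index + 1L) {
  onset_sample <- as.integer(onset_sample)
  line_index <- as.integer(line_index)
  code <- as.integer(code)
  is_target <- as.logical(is_target)
  n <- length(onset_sample)
  if (length(line_index) != n || length(is_target) != n || length(code) != n) {
    stopf("marker fields must have equal length")
  }
  if (n > 0) {
    if (any(onset_sample < 0)) stopf("marker onsets must be >= 0")
    if (any(line_index < 0 | line_index > 12)) {
      stopf("line_index must lie in 0..12")
    }
  }
  m <- data.frame(onset_sample = onset_sample, code = code,
                  line_index = line_index, is_target = is_target)
  m[order(m$onset_sample), , drop = FALSE]
}

#' Continuous multichannel EEG recording
#'
#' The in-memory representation of a continuous recording: a channels-by-
#' samples matrix in microvolts, its sampling rate, ordered channel labels and
#' the flash marker table. Amplitudes are always stored in microvolts; file
#' readers rescale on the way in.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one label per data row.
#' @param markers Marker table from [flash_markers()].
#' @param subject_id Participant identifier.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_names,
                                 markers = flash_markers(),
                                 subject_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stopf("fs must be > 0")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stopf("need one channel name per data row (%d names, %d rows)",
          length(channel_names), nrow(data))
  }
  if (nrow(markers) > 0 && any(markers$onset_sample >= ncol(data))) {
    stopf("marker onsets must fall inside the recording")
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         markers = markers, subject_id = as.character(subject_id)),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> subject %s: %d channels x %d samples @ %g Hz, %d markers\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$markers)))
  invisible(x)
}

#' Stacked stimulus-locked epochs
#'
#' Container for a stack of fixed-length EEG epochs cut around stimulus
#' markers, together with their binary target labels and per-epoch subject
#' identifiers. The window runs from `t_start_ms` to `t_end_ms` relative to
#' stimulus onset (default -100 to +800 ms, i.e. a 900 ms epoch), and the
#' sample count must equal `round(0.9 * fs)`.
#'
#' @param epochs Numeric array `n x channels x samples`, microvolts.
#' @param labels Binary vector (1 = target flash), length `n`.
#' @param subject_ids Character vector of per-epoch subject ids, length `n`.
#' @param fs Sampling rate of the epoched data in Hz.
#' @param t_start_ms,t_end_ms Epoch window relative to stimulus onset, ms.
#' @param channel_names Optional channel labels (length = second dimension).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, subject_ids, fs,
                      t_start_ms = -100, t_end_ms = 800,
                      channel_names = NULL) {
  if (length(dim(epochs)) != 3) stopf("epochs must be an n x channels x samples array")
  storage.mode(epochs) <- "double"
  n <- dim(epochs)[1]
  labels <- as.numeric(labels)
  if (length(labels) != n || length(subject_ids) != n) {
    stopf("labels and subject_ids must match the number of epochs")
  }
  if (n > 0 && !all(labels %in% c(0, 1))) {
    stopf("labels must be binary (0/1)")
  }
  if ((t_end_ms - t_start_ms) != 900) {
    stopf("epoch window must span 900 ms (got %g)", t_end_ms - t_start_ms)
  }
  if (dim(epochs)[3] != round(0.9 * fs)) {
    stopf("epoch sample count %d does not equal round(0.9 * fs) = %d",
          dim(epochs)[3], round(0.9 * fs))
  }
  if (!is.null(channel_names) && length(channel_names) != dim(epochs)[2]) {
    stopf("channel_names length must equal the channel dimension")
  }
  structure(
    list(epochs = epochs, labels = as.integer(labels),
         subject_ids = as.character(subject_ids), fs = fs,
         t_start_ms = t_start_ms, t_end_ms = t_end_ms,
         channel_names = channel_names),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz [%g, %g) ms; %d targets\n",
              d[1], d[2], d[3], x$fs, x$t_start_ms, x$t_end_ms,
              sum(x$labels)))
  invisible(x)
}

#' Number of epochs
#' @param x An `epoch_set`.
#' @export
n_epochs <- function(x) dim(x$epochs)[1]

#' Subset an epoch set
#' @param x An `epoch_set`.
#' @param i Index vector (integer or logical) over epochs.
#' @param ... Ignored.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$epochs[i, , , drop = FALSE], x$labels[i], x$subject_ids[i],
            x$fs, x$t_start_ms, x$t_end_ms, x$channel_names)
}

## ---------------------------------------------------------------------------
## Portable container: one gzip-compressed JSON document.  Numeric arrays are
## stored as base64-encoded little-endian float64 so the roundtrip is bitwise
## exact.  Schema: {format, version, type, ...fields...}.

b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8, endian = "little"))

unb64_doubles <- function(s, n) {
  readBin(jsonlite::base64_dec(s), what = "double", n = n, size = 8,
          endian = "little")
}

write_container_json <- function(obj, path) {
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  invisible(path)
}

read_container_json <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw <- tryCatch(readBin(con, "raw", n = file.size(path) * 60 + 1e6),
                  error = function(e) stopf("cannot read '%s': %s", path, conditionMessage(e)))
  obj <- tryCatch(jsonlite::fromJSON(rawToChar(raw), simplifyVector = TRUE),
                  error = function(e) stopf("'%s' is not a valid container: %s", path, conditionMessage(e)))
  if (!identical(obj$format, "p300wd-container")) {
    stopf("'%s' is not a p300wd container (missing format tag)", path)
  }
  obj
}

#' Write / read the portable epoch container
#'
#' Serializes an [epoch_set()] to a single gzip-compressed JSON document.
#' Arrays are embedded as base64-encoded little-endian float64, so
#' `read_epochs(write_epochs(x))` reproduces every field bitwise.
#'
#' @param epochs An `epoch_set`.
#' @param path Output file path (conventionally `.epo.json.gz`).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) > 0 && !all(epochs$labels %in% c(0L, 1L))) {
    stopf("labels must be binary (0/1)")
  }
  obj <- list(
    format = "p300wd-container", version = 1L, type = "epoch_set",
    dim = dim(epochs$epochs), fs = epochs$fs,
    t_start_ms = epochs$t_start_ms, t_end_ms = epochs$t_end_ms,
    labels = epochs$labels, subject_ids = epochs$subject_ids,
    channel_names = epochs$channel_names,
    epochs_b64 = b64_doubles(epochs$epochs)
  )
  write_container_json(obj, path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- read_container_json(path)
  if (!identical(obj$type, "epoch_set")) {
    stopf("'%s' holds a %s, not an epoch_set", path, obj$type)
  }
  d <- as.integer(obj$dim)
  arr <- array(unb64_doubles(obj$epochs_b64, prod(d)), dim = d)
  epoch_set(arr, as.integer(obj$labels), as.character(obj$subject_ids),
            as.numeric(obj$fs), as.numeric(obj$t_start_ms),
            as.numeric(obj$t_end_ms),
            channel_names = if (is.null(obj$channel_names)) NULL else as.character(obj$channel_names))
}

#' Write / read continuous recordings
#'
#' `write_recording()` stores a [continuous_recording()] either as EDF+ (with
#' flash markers as EDF annotations) or as the package's portable container;
#' `read_recording()` reads either format back. Amplitudes are always returned
#' in microvolts: an EDF channel whose physical dimension is `mV` or `V` is
#' rescaled on read.
#'
#' EDF stores samples as 16-bit integers, so an EDF roundtrip is exact only to
#' the quantization step (physical range / 65534); the container roundtrip is
#' bitwise. Marker onsets are sample-exact through both formats.
#'
#' @param rec A `continuous_recording`.
#' @param path File path.
#' @param format `"edf"` or `"container"`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `continuous_recording` with markers ordered by onset.
#' @export
write_recording <- function(rec, path, format = c("container", "edf")) {
  stopifnot(inherits(rec, "continuous_recording"))
  format <- match.arg(format)
  if (format == "edf") return(write_recording_edf(rec, path))
  obj <- list(
    format = "p300wd-container", version = 1L, type = "continuous_recording",
    dim = dim(rec$data), fs = rec$fs, channel_names = rec$channel_names,
    subject_id = rec$subject_id,
    markers = list(onset_sample = rec$markers$onset_sample,
                   code = rec$markers$code,
                   line_index = rec$markers$line_index,
                   is_target = rec$markers$is_target),
    data_b64 = b64_doubles(rec$data)
  )
  write_container_json(obj, path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("container", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_recording_edf(path))
  obj <- read_container_json(path)
  if (!identical(obj$type, "continuous_recording")) {
    stopf("'%s' holds a %s, not a continuous_recording", path, obj$type)
  }
  d <- as.integer(obj$dim)
  dat <- matrix(unb64_doubles(obj$data_b64, prod(d)), d[1], d[2])
  mk <- obj$markers
  markers <- flash_markers(as.integer(mk$onset_sample),
                           as.integer(mk$line_index),
                           as.logical(mk$is_target),
                           code = as.integer(mk$code))
  continuous_recording(dat, as.numeric(obj$fs),
                       as.character(obj$channel_names), markers,
                       obj$subject_id)
}
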