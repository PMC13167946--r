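#' Construct a multichannel fNIRS recording
#'
#' Light container for one subject x session recording: a time x channel
#' matrix of oxygenated haemoglobin (HbO2) concentration change in
#' mmol/L*mm, with subject metadata and the sampling rate. Optionally
#' carries raw dual-wavelength light intensities (for conversion with
#' [mbll_convert()]).
#'
#' @param data Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param subject Subject identifier.
#' @param group `"intervention"` or `"control"` (or `NA`).
#' @param timepoint `"pre"` or `"post"` (or `NA`).
#' @param channels Integer channel ids; defaults to `1:ncol(data)`.
#' @param intensity Optional named list of two samples x channels intensity
#'   matrices, names giving the wavelengths in nm (e.g. `"785"`, `"825"`).
#' @param units Unit string for `data`.
#' @return An object of class `nirs_recording`.
#' @export
nirs_recording <- function(data, fs, subject = NA_character_,
                           group = NA_character_, timepoint = NA_character_,
                           channels = NULL, intensity = NULL,
                           units = "mmol/L*mm") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channels <- as.integer(channels %||% seq_len(ncol(data)))
  stopifnot(length(channels) == ncol(data), fs > 0)
  colnames(data) <- sprintf("ch%02d", channels)
  structure(
    list(subject = subject, group = group, timepoint = timepoint,
         fs = fs, channels = channels, data = data, intensity = intensity,
         units = units, steps = character()),
    class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf(
    "<nirs_recording> subject=%s group=%s timepoint=%s: %d ch x %d samples @ %g Hz [%s]\n",
    x$subject, x$group, x$timepoint, ncol(x$data), nrow(x$data), x$fs,
    x$units))
  if (length(x$steps)) cat("  steps:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' @method as_tibble nirs_recording
#' @export
as_tibble.nirs_recording <- function(x, ...) {
  tibble::tibble(
    subject = x$subject, group = x$group, timepoint = x$timepoint,
    time = rep((seq_len(nrow(x$data)) - 1) / x$fs, times = ncol(x$data)),
    channel = rep(x$channels, each = nrow(x$data)),
    hbo = as.vector(x$data))
}

#' @method tidy nirs_recording
#' @export
tidy.nirs_recording <- function(x, ...) as_tibble.nirs_recording(x, ...)

# internal: record a provenance step on a recording
add_step <- function(rec, label) {
  rec$steps <- c(rec$steps, label)
  rec
}

#' Write / read a recording as a tabular TSV
#'
#' The recording is persisted as plain text: `#key<TAB>value` metadata
#' header lines followed by a `time` column and one column per channel.
#' Raw intensities, if present, are not persisted.
#'
#' @param rec A `nirs_recording`.
#' @param path Output file path.
#' @return `path` (write) or a `nirs_recording` (read).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  meta <- c(subject = rec$subject, group = rec$group,
            timepoint = rec$timepoint, fs = format(rec$fs), units = rec$units)
  hdr <- sprintf("#%s\t%s", names(meta), unname(meta))
  df <- data.frame(time = (seq_len(nrow(rec$data)) - 1) / rec$fs, rec$data,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path, n = 20L)
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  chcols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  rec <- nirs_recording(
    as.matrix(df[chcols]), fs = as.numeric(meta[["fs"]]),
    subject = meta[["subject"]], group = meta[["group"]],
    timepoint = meta[["timepoint"]],
    channels = as.integer(sub("^ch", "", chcols)),
    units = meta[["units"]])
  rec
}
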