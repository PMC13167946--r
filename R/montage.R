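#' Region-of-interest names for the 48-channel frontotemporal montage
#'
#' Canonical ordering of the nine regions of interest (ROIs): bilateral
#' superior frontal cortex (SFC), dorsolateral prefrontal cortex (DLPFC),
#' superior temporal cortex (STC), ventrolateral prefrontal cortex (VLPFC),
#' and the medial prefrontal cortex (mPFC). The `l`/`r` prefix is the
#' hemisphere.
#'
#' @return Character vector of the nine ROI names, in canonical order.
#' @export
roi_names <- function() {
  c("rSFC", "lSFC", "rDLPFC", "lDLPFC", "rSTC", "lSTC",
    "rVLPFC", "lVLPFC", "mPFC")
}

#' Default 48-channel frontotemporal montage
#'
#' A plausible default layout for a 15-source / 16-detector probe cap
#' generating 48 channels over bilateral frontal and temporal cortex,
#' partitioned into the nine ROIs of [roi_names()]. Channel numbering runs
#' in source-detector scan order from the right temporal margin across the
#' midline; the midline block (including channels 16 and 36) is assigned to
#' the mPFC and channel 18 to the left DLPFC. Left/right channel counts are
#' equal for the eight lateral ROIs (SFC and VLPFC 5 each, DLPFC 6 each,
#' STC 4 each; mPFC 8). Only those anchors and the counts are fixed by
#' design; the full map is a documented default and every downstream
#' computation is map-agnostic, so a device-specific map can be supplied via
#' [load_montage()].
#'
#' @return A montage tibble (class `nirs_montage`) with columns `channel`,
#'   `source`, `detector`, `roi`.
#' @examples
#' m <- default_montage()
#' roi_of(m, 16)  # "mPFC"
#' @export
default_montage <- function() {
  roi <- character(48)
  roi[1:4]   <- "rSTC"
  roi[5:9]   <- "rVLPFC"
  roi[10:15] <- "rDLPFC"
  roi[c(16, 17, 24, 25, 32, 33, 35, 36)] <- "mPFC"
  roi[18:23] <- "lDLPFC"
  roi[26:30] <- "rSFC"
  roi[c(31, 34, 37, 38, 39)] <- "lSFC"
  roi[40:44] <- "lVLPFC"
  roi[45:48] <- "lSTC"
  ch <- 1:48
  m <- tibble::tibble(
    channel = as.integer(ch),
    source = as.integer((ch - 1L) %% 15L + 1L),
    detector = as.integer((ch - 1L) %% 16L + 1L),
    roi = roi)
  validate_montage(m)
}

#' Validate a montage table
#'
#' Checks the montage invariants: exactly 48 unique channel ids 1..48, ROI
#' names drawn from the nine canonical names, every channel assigned to
#' exactly one ROI, sources in 1..15 and detectors in 1..16 when present.
#'
#' @param m A data frame with columns `channel`, `roi` and optionally
#'   `source`, `detector`.
#' @return The validated montage as a `nirs_montage` tibble (invisibly the
#'   same data), or an error describing the violation.
#' @export
validate_montage <- function(m) {
  m <- tibble::as_tibble(m)
  if (!all(c("channel", "roi") %in% names(m)))
    rlang::abort("montage needs `channel` and `roi` columns")
  m$channel <- as.integer(m$channel)
  if (nrow(m) != 48L || anyDuplicated(m$channel) ||
      !setequal(m$channel, 1:48))
    rlang::abort("montage must contain each channel id 1..48 exactly once")
  bad <- setdiff(unique(m$roi), roi_names())
  if (length(bad))
    rlang::abort(paste0("unknown ROI name(s): ", paste(bad, collapse = ", ")))
  if (anyNA(m$roi)) rlang::abort("every channel must have an ROI")
  if (!"source" %in% names(m)) m$source <- as.integer((m$channel - 1L) %% 15L + 1L)
  if (!"detector" %in% names(m)) m$detector <- as.integer((m$channel - 1L) %% 16L + 1L)
  if (any(m$source < 1 | m$source > 15)) rlang::abort("sources must be in 1..15")
  if (any(m$detector < 1 | m$detector > 16)) rlang::abort("detectors must be in 1..16")
  m <- m[order(m$channel), c("channel", "source", "detector", "roi")]
  class(m) <- c("nirs_montage", class(tibble::tibble()))
  m
}

#' Read a montage from a configuration file
#'
#' Accepts either a tabular file (`.tsv`/`.csv` with columns `channel`,
#' `roi`, optionally `source`, `detector`) or a YAML file with a top-level
#' `rois:` mapping from ROI name to a vector of channel ids. The parsed
#' montage is validated with [validate_montage()].
#'
#' @param path Path to the montage file.
#' @return A validated `nirs_montage` tibble.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such montage file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$rois)) rlang::abort("YAML montage needs a `rois:` mapping")
    ids <- unlist(cfg$rois, use.names = FALSE)
    if (anyDuplicated(ids))
      rlang::abort("a channel is assigned to more than one ROI")
    m <- tibble::tibble(
      channel = as.integer(ids),
      roi = rep(names(cfg$rois), lengths(cfg$rois)))
    if (!is.null(cfg$sources)) m$source <- as.integer(unlist(cfg$sources))[m$channel]
    if (!is.null(cfg$detectors)) m$detector <- as.integer(unlist(cfg$detectors))[m$channel]
  } else {
    m <- readr::read_delim(path, delim = if (ext == "csv") "," else "\t",
                           show_col_types = FALSE, comment = "#")
    if (anyDuplicated(m$channel))
      rlang::abort("duplicate channel id in montage file")
  }
  validate_montage(m)
}

#' Export a montage as a two-column TSV
#'
#' @param m A validated montage.
#' @param path Output path; columns `channel`, `roi` (plus `source`,
#'   `detector`).
#' @return `path`, invisibly.
#' @export
write_montage <- function(m, path) {
  m <- validate_montage(m)
  readr::write_tsv(m, path)
  invisible(path)
}

#' Look up the ROI of a channel
#'
#' @param m A validated montage.
#' @param channel_id Integer channel id in 1..48.
#' @return The ROI name (character scalar).
#' @examples
#' roi_of(default_montage(), 36)  # "mPFC"
#' @export
roi_of <- function(m, channel_id) {
  m <- validate_montage(m)
  if (length(channel_id) != 1L || is.na(channel_id) ||
      channel_id != as.integer(channel_id) ||
      channel_id < 1 || channel_id > 48)
    rlang::abort("channel_id must be a single integer in 1..48")
  m$roi[match(as.integer(channel_id), m$channel)]
}

#' All unordered ROI pairs
#'
#' The 36 unordered pairs of distinct ROIs, in the deterministic order
#' induced by [roi_names()] (useful for region-pair connectivity tables).
#'
#' @param m A validated montage (used only for validation; the pair set is
#'   fixed by the ROI names).
#' @return A tibble with columns `roi_a`, `roi_b`, one row per unordered
#'   pair, `roi_a` preceding `roi_b` in canonical order.
#' @export
roi_pairs <- function(m) {
  validate_montage(m)
  nm <- roi_names()
  idx <- utils::combn(length(nm), 2)
  tibble::tibble(roi_a = nm[idx[1, ]], roi_b = nm[idx[2, ]])
}

# internal: named list roi -> integer channel ids
roi_channel_sets <- function(m) {
  split(m$channel, factor(m$roi, levels = roi_names()))
}
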