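#' Verbal fluency task paradigm
#'
#' Describes the timed block structure of the verbal fluency task (VFT):
#' a pre-task rest, a sequence of contiguous task blocks, and a post-task
#' rest, sampled at a fixed rate. The default is the standard 140 s
#' frontotemporal VFT protocol: 25 s rest, three consecutive 20 s
#' word-generation blocks (no inter-block rest), 55 s rest, at 5 Hz.
#'
#' @param pre_rest_s Pre-task rest duration in seconds.
#' @param task_block_s Duration of one task block in seconds.
#' @param n_blocks Number of contiguous task blocks.
#' @param post_rest_s Post-task rest duration in seconds.
#' @param fs Sampling rate in Hz.
#'
#' @return An object of class `vft_paradigm`: a list with the inputs plus
#'   `task_s` (total task duration), `total_s`, and `n_samples`.
#' @examples
#' p <- vft_paradigm()
#' p$total_s    # 140
#' p$n_samples  # 700
#' @export
vft_paradigm <- function(pre_rest_s = 25, task_block_s = 20, n_blocks = 3,
                         post_rest_s = 55, fs = 5) {
  stopifnot(pre_rest_s > 0, task_block_s > 0, n_blocks >= 0, post_rest_s > 0,
            fs > 0)
  task_s <- task_block_s * n_blocks
  total_s <- pre_rest_s + task_s + post_rest_s
  structure(
    list(pre_rest_s = pre_rest_s, task_block_s = task_block_s,
         n_blocks = n_blocks, post_rest_s = post_rest_s, fs = fs,
         task_s = task_s, total_s = total_s,
         n_samples = as.integer(round(total_s * fs))),
    class = "vft_paradigm")
}

#' @export
print.vft_paradigm <- function(x, ...) {
  cat(sprintf(
    "<vft_paradigm> %gs rest + %dx%gs task + %gs rest @ %g Hz (%d samples)\n",
    x$pre_rest_s, x$n_blocks, x$task_block_s, x$post_rest_s, x$fs,
    x$n_samples))
  invisible(x)
}

# internal: 1-based sample index ranges for the paradigm windows.
# Times are [start, end) in seconds; sample i covers time (i-1)/fs.
paradigm_windows <- function(p) {
  idx <- function(t0, t1) {
    lo <- round(t0 * p$fs) + 1L
    hi <- round(t1 * p$fs)
    seq.int(lo, hi)
  }
  list(
    baseline = idx(0, p$pre_rest_s),
    task = idx(p$pre_rest_s, p$pre_rest_s + p$task_s),
    post = idx(p$pre_rest_s + p$task_s, p$total_s)
  )
}

# internal: time of each sample in seconds (sample i at (i-1)/fs)
paradigm_times <- function(p) (seq_len(p$n_samples) - 1) / p$fs
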