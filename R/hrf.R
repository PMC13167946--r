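#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response lobe peaking near
#' `peak_s` and a late undershoot peaking near `undershoot_s`, weighted by
#' `undershoot_ratio`. With rate fixed at 1/s, a gamma density with shape
#' `k + 1` has its mode at `k` seconds, so the defaults (peak 6 s,
#' undershoot 16 s, ratio 1:6) give the standard canonical shape. The
#' response is 0 at `t = 0` and integrates to `1 - undershoot_ratio`.
#' This HRF is internal to the simulator; the analysis side never fits it.
#'
#' @param t Times in seconds (vector, all `>= 0`).
#' @param peak_s Mode of the response lobe, seconds.
#' @param undershoot_s Mode of the undershoot lobe, seconds.
#' @param undershoot_ratio Weight of the undershoot (0 disables it).
#' @return Unitless response sampled at `t`.
#' @examples
#' h <- hrf(seq(0, 30, by = 0.1))
#' seq(0, 30, by = 0.1)[which.max(h)]  # ~6
#' @export
hrf <- function(t, peak_s = 6, undershoot_s = 16, undershoot_ratio = 1 / 6) {
  if (any(t < 0)) rlang::abort("t must be nonnegative")
  if (peak_s <= 0 || undershoot_s <= 0 || undershoot_ratio < 0)
    rlang::abort("invalid HRF shape parameters")
  stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
}

#' Task regressor: block boxcar convolved with the HRF
#'
#' Builds the expected task-locked HbO2 time course for a paradigm: a
#' boxcar that is 1 during the contiguous task blocks and 0 elsewhere,
#' convolved with [hrf()], truncated to the paradigm length and rescaled to
#' a maximum of 1. Zero before task onset (the HRF is causal).
#'
#' @param paradigm A [vft_paradigm()].
#' @param peak_s,undershoot_s,undershoot_ratio HRF parameters, see [hrf()].
#' @return Numeric vector of length `paradigm$n_samples`, max 1 (all zeros
#'   when the paradigm has no task blocks).
#' @export
task_regressor <- function(paradigm, peak_s = 6, undershoot_s = 16,
                           undershoot_ratio = 1 / 6) {
  p <- paradigm
  n <- p$n_samples
  box <- numeric(n)
  if (p$n_blocks > 0) box[paradigm_windows(p)$task] <- 1
  if (!any(box > 0)) return(box)
  # HRF kernel sampled over 32 s (support of the canonical shape)
  tk <- seq(0, 32, by = 1 / p$fs)
  h <- hrf(tk, peak_s, undershoot_s, undershoot_ratio)
  reg <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] / p$fs
  reg / max(reg)
}
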