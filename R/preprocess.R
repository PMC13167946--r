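#' Preprocessing configuration
#'
#' Parameters for the fixed preprocessing chain
#' (optional MBLL conversion) -> motion detection/repair -> low-pass
#' filter -> baseline panning, plus channel quality thresholds.
#'
#' @param lowpass_cutoff_hz Butterworth low-pass cutoff, Hz (default 0.1).
#' @param filter_order Butterworth order (default 4; applied forward and
#'   backward, so the effective magnitude response is 8th order).
#' @param zero_phase Apply the filter forward-backward (default `TRUE`).
#' @param highpass_cutoff_hz Optional high-pass cutoff, Hz; `NULL` (the
#'   default) disables it - offset removal is the panning step's job.
#' @param baseline_tail_s Length of the pre-task rest tail used both as the
#'   panning window and the MBLL intensity reference (default 10 s).
#' @param motion_method `"interpolate"` (cubic repair) or `"none"`.
#' @param motion_window_s Moving window for the derivative z-score, seconds.
#' @param motion_z Z threshold on the first-difference score (default 5).
#' @param detrend Remove slow linear drift fitted on the rest windows
#'   (default `TRUE`; see [detrend_rest()]).
#' @param detrend_washout_s Post-task washout excluded from the drift fit.
#' @param sd_floor Channels with SD at or below this are flat/saturated.
#' @param max_artifact_frac Maximum tolerated fraction of artifact-flagged
#'   samples for a good channel.
#' @param min_good_channels Subject inclusion gate: minimum number of good
#'   channels required at both timepoints (default 36, inclusive).
#' @param mbll MBLL constants from [mbll_coefficients()].
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(lowpass_cutoff_hz = 0.1, filter_order = 4,
                           zero_phase = TRUE, highpass_cutoff_hz = NULL,
                           baseline_tail_s = 10,
                           motion_method = c("interpolate", "none"),
                           motion_window_s = 2, motion_z = 5,
                           detrend = TRUE, detrend_washout_s = 20,
                           sd_floor = 1e-6, max_artifact_frac = 0.2,
                           min_good_channels = 36,
                           mbll = mbll_coefficients()) {
  motion_method <- match.arg(motion_method)
  stopifnot(lowpass_cutoff_hz > 0, filter_order >= 1, baseline_tail_s > 0,
            motion_window_s > 0, motion_z > 0,
            min_good_channels >= 1, min_good_channels <= 48)
  structure(list(
    lowpass_cutoff_hz = lowpass_cutoff_hz, filter_order = filter_order,
    zero_phase = zero_phase, highpass_cutoff_hz = highpass_cutoff_hz,
    baseline_tail_s = baseline_tail_s, motion_method = motion_method,
    motion_window_s = motion_window_s, motion_z = motion_z,
    detrend = detrend, detrend_washout_s = detrend_washout_s,
    sd_floor = sd_floor, max_artifact_frac = max_artifact_frac,
    min_good_channels = min_good_channels, mbll = mbll),
    class = "preproc_config")
}

#' Modified Beer-Lambert law constants
#'
#' Extinction coefficients (optical density per mmol/L*mm of chromophore
#' concentration x pathlength) for oxygenated and deoxygenated haemoglobin
#' at the two measurement wavelengths, and differential pathlength factors.
#' Defaults follow the standard literature shape for 785/825 nm continuous
#' wave devices: HbR absorbs more strongly than HbO2 below the ~800 nm
#' isosbestic point and more weakly above it.
#'
#' @param wavelengths Two wavelengths, nm.
#' @param extinction 2x2 matrix, rows = wavelengths, columns = (HbO2, HbR).
#' @param dpf Differential pathlength factor per wavelength.
#' @param hbr_ratio Ratio of -HbR to HbO2 change used by the simulator's
#'   intensity emission (a fixed anticorrelated fraction).
#' @return An `mbll_coefficients` list.
#' @export
mbll_coefficients <- function(wavelengths = c(785, 825),
                              extinction = matrix(
                                c(0.74, 1.10,
                                  0.90, 0.75),
                                nrow = 2, byrow = TRUE,
                                dimnames = list(c("785", "825"),
                                                c("HbO2", "HbR"))),
                              dpf = c(6.2, 5.8), hbr_ratio = 1 / 3) {
  stopifnot(length(wavelengths) == 2, all(dim(extinction) == c(2, 2)),
            length(dpf) == 2)
  if (abs(det(extinction)) < 1e-12)
    rlang::abort("singular extinction matrix: rows are proportional")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 dpf = dpf, hbr_ratio = hbr_ratio),
            class = "mbll_coefficients")
}

# internal (simulator side): emit dual-wavelength intensities from an HbO2
# matrix by the forward MBLL, referenced to the mean over the first
# baseline_tail_s (the same reference mbll_convert uses), with
# HbR = -hbr_ratio * HbO2 and unit resting intensity.
emit_intensity <- function(hbo, baseline_tail_s, fs,
                           mbll = mbll_coefficients()) {
  nref <- max(1L, round(baseline_tail_s * fs))
  ref <- colMeans(hbo[seq_len(nref), , drop = FALSE])
  d_hbo <- sweep(hbo, 2, ref)
  hbr <- -mbll$hbr_ratio * d_hbo
  out <- list()
  for (i in 1:2) {
    od <- mbll$dpf[i] * (mbll$extinction[i, "HbO2"] * d_hbo +
                           mbll$extinction[i, "HbR"] * hbr)
    out[[as.character(mbll$wavelengths[i])]] <- 10^(-od)
  }
  out
}

#' Convert dual-wavelength intensities to haemoglobin concentration change
#'
#' Modified Beer-Lambert law: per wavelength, the optical density change is
#' `dOD = -log10(I / I0)` with `I0` the geometric-mean intensity over the
#' first `baseline_tail_s` seconds (the mean optical density of the
#' reference window); the 2x2 extinction system (scaled by the
#' differential pathlength factors) is then solved per sample for the HbO2
#' and HbR concentration x pathlength changes (mmol/L*mm). This is the
#' exact algebraic inverse of the simulator's intensity emission.
#'
#' @param rec A [nirs_recording()] carrying an `intensity` list (two
#'   wavelengths).
#' @param cfg A [preproc_config()].
#' @return The recording with `data` replaced by the HbO2 change and an
#'   `hbr` matrix attached.
#' @export
mbll_convert <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (is.null(rec$intensity) || length(rec$intensity) != 2)
    rlang::abort("recording carries no dual-wavelength intensities")
  mb <- cfg$mbll
  if (abs(det(mb$extinction)) < 1e-12)
    rlang::abort("singular extinction matrix: rows are proportional")
  nref <- max(1L, round(cfg$baseline_tail_s * rec$fs))
  M <- mb$extinction * mb$dpf  # row-scaled by dpf
  Minv <- solve(M)
  od <- lapply(rec$intensity, function(I) {
    if (any(I <= 0)) rlang::abort("intensities must be strictly positive")
    # reference = geometric mean over the window, i.e. the mean in optical
    # density space; keeps the conversion an exact linear re-reference
    I0 <- exp(colMeans(log(I[seq_len(nref), , drop = FALSE])))
    -log10(sweep(I, 2, I0, "/"))
  })
  hbo <- od[[1]] * Minv[1, 1] + od[[2]] * Minv[1, 2]
  hbr <- od[[1]] * Minv[2, 1] + od[[2]] * Minv[2, 2]
  rec$data <- hbo
  colnames(rec$data) <- sprintf("ch%02d", rec$channels)
  rec$hbr <- hbr
  rec$units <- "mmol/L*mm"
  add_step(rec, "mbll")
}

#' Detect motion artifacts
#'
#' Flags samples whose first difference is an outlier: the difference
#' series is centred by a running median over `motion_window_s` and scaled
#' by its robust (MAD-based) standard deviation; samples with |z| above
#' `motion_z` are flagged and the flags are dilated by half a window on
#' each side. Robust centring/scaling keeps large spikes from masking
#' themselves.
#'
#' @param rec A [nirs_recording()].
#' @param cfg A [preproc_config()].
#' @return Logical samples x channels matrix (`TRUE` = artifact).
#' @export
detect_motion <- function(rec, cfg = preproc_config()) {
  X <- rec$data
  n <- nrow(X)
  w <- max(3L, round(cfg$motion_window_s * rec$fs))
  if (n < 2L * w) rlang::abort("recording too short for motion detection")
  if (w %% 2L == 0L) w <- w + 1L  # runmed needs odd k
  half <- ceiling(cfg$motion_window_s * rec$fs / 2)
  mask <- matrix(FALSE, n, ncol(X))
  if (!is.finite(cfg$motion_z)) return(mask)
  for (ch in seq_len(ncol(X))) {
    x <- X[, ch]
    d <- diff(x)
    ctr <- stats::runmed(d, w, endrule = "median")
    s <- stats::mad(d)
    if (s <= 0) s <- stats::sd(d)
    if (!isTRUE(s > 0)) next
    hit <- which(abs((d - ctr) / s) > cfg$motion_z)
    # complementary amplitude criterion on the residual from a running
    # median: a transient whose rise is split across two first differences
    # halves its derivative z, but its level excursion is intact
    resid <- x - stats::runmed(x, w, endrule = "median")
    s2 <- stats::mad(resid)
    hit2 <- if (isTRUE(s2 > 0)) which(abs(resid) > cfg$motion_z * s2)
    else integer()
    if (length(hit) || length(hit2)) {
      # a difference outlier at i implicates samples i and i+1, dilated
      bad <- unique(c(
        unlist(lapply(hit, function(i)
          max(1L, i - half):min(n, i + 1L + half))),
        unlist(lapply(hit2, function(i)
          max(1L, i - half):min(n, i + half)))))
      mask[bad, ch] <- TRUE
    }
  }
  mask
}

#' Repair motion artifacts
#'
#' `method = "interpolate"` replaces flagged spans by shape-preserving
#' piecewise-cubic (monotone Hermite) interpolation through the flanking
#' clean samples: exact on linear ramps, and bounded by the neighbouring
#' clean samples so long artifact spans cannot introduce overshoot.
#' `"none"` passes the data through. Output is finite everywhere.
#'
#' @param rec A [nirs_recording()].
#' @param mask Logical samples x channels matrix from [detect_motion()].
#' @param method `"interpolate"` or `"none"`.
#' @return The repaired recording.
#' @export
correct_motion <- function(rec, mask, method = c("interpolate", "none")) {
  method <- match.arg(method)
  if (method == "none" || !any(mask)) return(add_step(rec, "motion:none"))
  X <- rec$data
  n <- nrow(X)
  for (ch in seq_len(ncol(X))) {
    bad <- mask[, ch]
    if (!any(bad)) next
    if (all(bad)) rlang::abort(
      sprintf("channel %d is entirely artifact; cannot interpolate", ch))
    idx <- seq_len(n)
    # shape-preserving piecewise cubic: exact on ramps, and bounded by the
    # flanking samples, so long merged artifact spans cannot overshoot
    f <- stats::splinefun(idx[!bad], X[!bad, ch], method = "monoH.FC")
    X[bad, ch] <- f(idx[bad])
  }
  rec$data <- X
  add_step(rec, "motion:interpolate")
}

# internal: memoised Butterworth design (same coefficients are reused for
# every recording in a cohort)
.butter_cache <- new.env(parent = emptyenv())
butter_cached <- function(order, W, type) {
  key <- paste(order, format(W, digits = 15), type)
  if (is.null(.butter_cache[[key]]))
    .butter_cache[[key]] <- signal::butter(order, W, type)
  .butter_cache[[key]]
}

# internal: column standard deviations (much faster than apply(x, 2, sd))
col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(0, (colSums(X * X) - n * mu^2) / (n - 1)))
}

# internal: zero-phase IIR application, vectorized over columns.
# Odd-reflection padding suppresses edge transients; the channel mean is
# subtracted first and restored after, so the DC response is exact.
filtfilt_mat <- function(b, a, X, padlen = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  padlen <- min(n - 1L, padlen %||% (n - 1L))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  out <- .iir_filtfilt(as.numeric(b), as.numeric(a), Xc,
                       as.integer(padlen))
  sweep(out, 2, mu, "+")
}

#' Remove slow linear drift using the rest windows
#'
#' Fits a straight line per channel by least squares through the rest
#' samples only - the pre-task rest and the post-task rest after a washout
#' for the hemodynamic tail - and subtracts it from the whole recording.
#' Slow instrumental drift corrupts task-window statistics (it inflates
#' channel variance and adds spurious inter-channel correlation), but a
#' high-pass filter sharp enough to remove it would also attenuate the
#' single-block task response (fundamental below 0.01 Hz); restricting the
#' fit to rest samples removes the drift while leaving the task response
#' untouched.
#'
#' @param rec A [nirs_recording()].
#' @param paradigm A [vft_paradigm()].
#' @param washout_s Seconds of post-task rest excluded from the fit while
#'   the hemodynamic response decays (default 20).
#' @return The detrended recording.
#' @export
detrend_rest <- function(rec, paradigm = vft_paradigm(), washout_s = 20) {
  w <- paradigm_windows(paradigm)
  post <- w$post[w$post > min(w$post) + round(washout_s * rec$fs)]
  fit_idx <- c(w$baseline, post)
  if (length(fit_idx) < 3) rlang::abort("too few rest samples to detrend")
  tt <- (fit_idx - 1) / rec$fs
  X <- stats::lm.fit(cbind(1, tt), rec$data[fit_idx, , drop = FALSE])
  all_t <- (seq_len(nrow(rec$data)) - 1) / rec$fs
  trend <- cbind(1, all_t) %*% X$coefficients
  rec$data <- rec$data - trend
  colnames(rec$data) <- sprintf("ch%02d", rec$channels)
  add_step(rec, "detrend:rest")
}

#' Low-pass filter a recording
#'
#' Butterworth low-pass of the configured order and cutoff (default 0.1 Hz,
#' order 4), applied forward-backward (zero phase) by default so the
#' effective magnitude response is the squared Butterworth. DC gain is
#' exactly 1. An optional high-pass (off by default) can be enabled via
#' `highpass_cutoff_hz`.
#'
#' @param rec A [nirs_recording()].
#' @param cfg A [preproc_config()].
#' @return The filtered recording.
#' @export
lowpass <- function(rec, cfg = preproc_config()) {
  nyq <- rec$fs / 2
  if (cfg$lowpass_cutoff_hz >= nyq)
    rlang::abort("low-pass cutoff must be below the Nyquist frequency")
  bf <- butter_cached(cfg$filter_order, cfg$lowpass_cutoff_hz / nyq, "low")
  if (any(abs(polyroot(rev(bf$a))) >= 1 + 1e-8))
    rlang::abort("unstable filter design: cutoff too close to Nyquist")
  padlen <- min(nrow(rec$data) - 1L,
                ceiling(3 * rec$fs / cfg$lowpass_cutoff_hz))
  if (isTRUE(cfg$zero_phase)) {
    rec$data <- filtfilt_mat(bf$b, bf$a, rec$data, padlen)
  } else {
    # single-pass (causal) application
    mu <- colMeans(rec$data)
    Xc <- sweep(rec$data, 2, mu)
    V <- stats::filter(rbind(matrix(0, length(bf$b) - 1L, ncol(Xc)), Xc),
                       bf$b, method = "convolution", sides = 1)
    V <- V[-seq_len(length(bf$b) - 1L), , drop = FALSE]
    V[is.na(V)] <- 0
    rec$data <- sweep(matrix(
      as.numeric(stats::filter(V, -bf$a[-1], method = "recursive")),
      nrow(Xc), ncol(Xc)), 2, mu, "+")
  }
  if (!is.null(cfg$highpass_cutoff_hz)) {
    bh <- signal::butter(cfg$filter_order, cfg$highpass_cutoff_hz / nyq,
                         "high")
    rec$data <- filtfilt_mat(bh$b, bh$a, rec$data, padlen)
  }
  colnames(rec$data) <- sprintf("ch%02d", rec$channels)
  add_step(rec, sprintf("lowpass:%gHz", cfg$lowpass_cutoff_hz))
}

#' Baseline panning
#'
#' Re-zeroes each channel by subtracting its minimum over the last
#' `baseline_tail_s` seconds of the pre-task rest (the baseline state that
#' precedes the task). After panning, that window's minimum is exactly 0;
#' the operation is idempotent.
#'
#' @param rec A [nirs_recording()].
#' @param paradigm A [vft_paradigm()].
#' @param cfg A [preproc_config()].
#' @return The panned recording.
#' @export
baseline_pan <- function(rec, paradigm = vft_paradigm(),
                         cfg = preproc_config()) {
  if (cfg$baseline_tail_s > paradigm$pre_rest_s)
    rlang::abort("baseline tail longer than the pre-task rest")
  lo <- round((paradigm$pre_rest_s - cfg$baseline_tail_s) * rec$fs) + 1L
  hi <- round(paradigm$pre_rest_s * rec$fs)
  if (hi < lo || hi > nrow(rec$data))
    rlang::abort("panning window is empty or out of bounds")
  mins <- apply(rec$data[lo:hi, , drop = FALSE], 2, min)
  rec$data <- sweep(rec$data, 2, mins)
  add_step(rec, "pan")
}

#' Assess channel signal quality
#'
#' A channel is good iff it is finite everywhere, not flat/saturated
#' (SD above `sd_floor`), and its motion-artifact fraction is below
#' `max_artifact_frac`. Deterministic given the recording and config.
#'
#' @param rec A [nirs_recording()].
#' @param cfg A [preproc_config()].
#' @param mask Optional artifact mask from [detect_motion()]; computed if
#'   missing.
#' @return A `quality_report` tibble (`channel`, `good`, `sd`,
#'   `artifact_frac`, `reason`) with attribute `n_good`.
#' @export
assess_quality <- function(rec, cfg = preproc_config(), mask = NULL) {
  X <- rec$data
  if (!nrow(X)) rlang::abort("empty recording")
  if (is.null(mask)) mask <- detect_motion(rec, cfg)
  finite <- colSums(!is.finite(X)) == 0
  sds <- rep(NA_real_, ncol(X))
  sds[finite] <- col_sds(X[, finite, drop = FALSE])
  sds[!finite] <- apply(X[, !finite, drop = FALSE], 2,
                        function(ch) stats::sd(ch[is.finite(ch)]))
  frac <- colMeans(mask)
  good <- finite & (sds > cfg$sd_floor) & (frac < cfg$max_artifact_frac)
  reason <- dplyr::case_when(
    !finite ~ "nonfinite",
    sds <= cfg$sd_floor ~ "flat",
    frac >= cfg$max_artifact_frac ~ "artifact",
    .default = "")
  rep <- tibble::tibble(channel = rec$channels, good = good, sd = sds,
                        artifact_frac = frac, reason = reason)
  attr(rep, "n_good") <- sum(good)
  class(rep) <- c("quality_report", class(rep))
  rep
}

#' Subject inclusion gate on paired quality reports
#'
#' A subject's fNIRS data are valid only if at least `min_good_channels`
#' channels are good at both timepoints (the boundary is inclusive: exactly
#' the minimum passes).
#'
#' @param report_pre,report_post Quality reports from [assess_quality()].
#' @param min_good_channels Threshold (default 36).
#' @return A list: `n_good_pre`, `n_good_post`, `subject_valid`.
#' @export
subject_quality_gate <- function(report_pre, report_post,
                                 min_good_channels = 36) {
  n1 <- attr(report_pre, "n_good")
  n2 <- attr(report_post, "n_good")
  list(n_good_pre = n1, n_good_post = n2,
       subject_valid = n1 >= min_good_channels && n2 >= min_good_channels)
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed order, logged in the recording's provenance: optional MBLL
#' conversion (when raw intensities are present), motion-artifact
#' detection and repair, Butterworth low-pass, baseline panning. Returns
#' the preprocessed recording with its quality report attached as
#' attribute `quality` (assessed on the motion mask before repair).
#'
#' @param rec A [nirs_recording()].
#' @param paradigm A [vft_paradigm()].
#' @param cfg A [preproc_config()].
#' @return The preprocessed `nirs_recording`.
#' @export
preprocess_recording <- function(rec, paradigm = vft_paradigm(),
                                 cfg = preproc_config()) {
  if (!is.null(rec$intensity)) rec <- mbll_convert(rec, cfg)
  mask <- detect_motion(rec, cfg)
  quality <- assess_quality(rec, cfg, mask)
  rec <- correct_motion(rec, mask, cfg$motion_method)
  if (isTRUE(cfg$detrend))
    rec <- detrend_rest(rec, paradigm, cfg$detrend_washout_s)
  rec <- lowpass(rec, cfg)
  rec <- baseline_pan(rec, paradigm, cfg)
  attr(rec, "quality") <- quality
  rec
}
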