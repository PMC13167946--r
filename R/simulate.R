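#' Physiological noise specification for the simulator
#'
#' The noise model superimposed on every simulated channel: a slow
#' autoregressive (AR(1)) physiological background, white measurement
#' noise, sinusoidal physiological oscillations (defaults: Mayer waves at
#' 0.10 Hz, respiration at 0.25 Hz, cardiac pulsation at 1.10 Hz, with a
#' random phase per channel), and a random linear drift. Amplitudes are in
#' the signal units (mmol/L*mm).
#'
#' @param ar1_sd Marginal standard deviation of the AR(1) background.
#' @param ar1_coef AR(1) coefficient in `[0, 1)` (at the sampling rate).
#' @param white_sd Standard deviation of additive white noise.
#' @param oscillations Data frame with columns `freq` (Hz), `amp`
#'   (sinusoid amplitude), `random_phase` (logical).
#' @param drift_slope_sd Standard deviation of the per-channel linear drift
#'   slope, units per second.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(ar1_sd = 0.08, ar1_coef = 0.95, white_sd = 0.02,
                       oscillations = tibble::tibble(
                         freq = c(0.10, 0.25, 1.10),
                         amp = c(0.04, 0.06, 0.08),
                         random_phase = TRUE),
                       drift_slope_sd = 0.002) {
  stopifnot(ar1_sd >= 0, white_sd >= 0, drift_slope_sd >= 0,
            ar1_coef >= 0, ar1_coef < 1)
  structure(list(ar1_sd = ar1_sd, ar1_coef = ar1_coef, white_sd = white_sd,
                 oscillations = tibble::as_tibble(oscillations),
                 drift_slope_sd = drift_slope_sd),
            class = "noise_spec")
}

#' Motion artifact specification for the simulator
#'
#' Transient spikes (1-3 samples, amplitude drawn from a zero-mean normal)
#' and persistent baseline shifts (step changes), injected after signal
#' composition so that preprocessing has genuine artifacts to remove.
#' Motion spikes in scalp optical recordings are large events - an order
#' of magnitude above the physiological noise floor - and the default
#' amplitude (SD 2 mmol/L*mm against a ~0.1 noise floor) reflects that;
#' a derivative z-score detector is designed for exactly this regime.
#' Shifts default to rate 0: cubic-interpolation repair removes transients
#' but cannot undo a level change, so shifts are opt-in (see the methods
#' vignette).
#'
#' @param spike_rate Expected spikes per minute per channel.
#' @param spike_amp_sd SD of spike amplitude (mmol/L*mm).
#' @param shift_rate Expected baseline shifts per minute per channel.
#' @param shift_amp_sd SD of shift amplitude (mmol/L*mm).
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(spike_rate = 2, spike_amp_sd = 2,
                          shift_rate = 0, shift_amp_sd = 0.3) {
  stopifnot(spike_rate >= 0, shift_rate >= 0, spike_amp_sd >= 0,
            shift_amp_sd >= 0)
  structure(list(spike_rate = spike_rate, spike_amp_sd = spike_amp_sd,
                 shift_rate = shift_rate, shift_amp_sd = shift_amp_sd),
            class = "artifact_spec")
}

#' Default group x timepoint x ROI activation amplitudes
#'
#' Task-response amplitudes (mmol/L*mm) for the simulated cohort. Baseline
#' (pre) sessions respond with amplitude 0 in every ROI; post sessions gain
#' ROI-specific increments that mirror the qualitative group x region
#' pattern of a frontotemporal VFT trial: the largest intervention-group
#' gains in mPFC, lDLPFC, rVLPFC and lSFC, and a broad smaller gain in the
#' control group with its largest response in rVLPFC.
#'
#' @return Tibble with columns `group`, `timepoint`, `roi`, `amplitude`.
#' @export
default_amplitudes <- function() {
  rois <- roi_names()
  post_int <- c(rSFC = 0.026, lSFC = 0.059, rDLPFC = 0.048, lDLPFC = 0.066,
                rSTC = 0.000, lSTC = 0.032, rVLPFC = 0.063, lVLPFC = 0.047,
                mPFC = 0.075)
  post_ctl <- c(rSFC = 0.034, lSFC = 0.028, rDLPFC = 0.048, lDLPFC = 0.047,
                rSTC = 0.012, lSTC = 0.023, rVLPFC = 0.065, lVLPFC = 0.035,
                mPFC = 0.047)
  dplyr::bind_rows(
    tibble::tibble(group = "intervention", timepoint = "pre", roi = rois,
                   amplitude = 0),
    tibble::tibble(group = "intervention", timepoint = "post", roi = rois,
                   amplitude = unname(post_int[rois])),
    tibble::tibble(group = "control", timepoint = "pre", roi = rois,
                   amplitude = 0),
    tibble::tibble(group = "control", timepoint = "post", roi = rois,
                   amplitude = unname(post_ctl[rois])))
}

#' Default connectivity communities and latent loadings
#'
#' The simulated inter-channel correlation structure is a latent-factor
#' model: each community is a channel set sharing one latent signal; a
#' channel with loading `w` on a latent of unit variance and passband
#' idiosyncratic noise of SD `sigma` correlates with a same-community
#' channel at `r = w_a w_b / sqrt((w_a^2 + s^2)(w_b^2 + s^2))`. Two default
#' communities: a `global` community spanning all 48 channels (systemic
#' physiology; its loading increment carries the group difference in mean
#' FC) and a `frontal` community over the lSFC, lDLPFC, mPFC and rDLPFC
#' channels whose post-intervention loading increment produces the
#' region-pair FC gains.
#'
#' @param montage Montage used to resolve ROI names to channel sets.
#' @return List with `communities` (named list of channel id vectors) and
#'   `loadings` (tibble `community`, `group`, `timepoint`, `loading`).
#' @export
default_fc_communities <- function(montage = default_montage()) {
  sets <- roi_channel_sets(validate_montage(montage))
  frontal <- sort(unlist(sets[c("lSFC", "lDLPFC", "mPFC", "rDLPFC")],
                         use.names = FALSE))
  loadings <- dplyr::bind_rows(
    tibble::tibble(community = "global",
                   group = rep(c("intervention", "control"), each = 2),
                   timepoint = rep(c("pre", "post"), 2),
                   loading = c(0.059, 0.075, 0.059, 0.063)),
    tibble::tibble(community = "frontal",
                   group = rep(c("intervention", "control"), each = 2),
                   timepoint = rep(c("pre", "post"), 2),
                   loading = c(0.040, 0.070, 0.040, 0.044)))
  list(communities = list(global = 1:48, frontal = frontal),
       loadings = loadings)
}

#' Simulation configuration for a two-group, two-timepoint fNIRS cohort
#'
#' Bundles everything the generator needs: montage, paradigm, HRF shape,
#' activation amplitudes, latent connectivity structure, noise and artifact
#' models, subject-level heterogeneity, and the coupling between the change
#' in mean functional connectivity and the change in the PSQI total score.
#'
#' Subject heterogeneity has two parts: per-subject, per-timepoint ROI
#' amplitude deviations (SD `amp_subject_sd`) that create realistic
#' between-subject spread in activation contrasts, and a per-subject
#' treatment-response multiplier (SD `resp_sd`) applied to the pre-to-post
#' connectivity loading increment, which makes the true change in mean FC
#' vary across subjects so that the behavioural coupling is identifiable.
#'
#' The PSQI change is generated as
#' `change_mean(group) + slope * (dz_i - mean(dz)) + noise`, where `dz_i`
#' is the subject's true change in mean Fisher-z connectivity and the noise
#' SD is set from the realized spread of `dz_i` so that the population
#' correlation between PSQI change and true FC change is
#' `-scale_population_r` (improvement correlates positively with FC gain).
#'
#' @param seed Integer seed; all randomness flows from it via named
#'   substreams, so a config is fully reproducible.
#' @param n_per_group Subjects per group (>= 2).
#' @param montage,paradigm See [default_montage()], [vft_paradigm()].
#' @param hrf_peak_s,hrf_undershoot_s,hrf_undershoot_ratio HRF shape.
#' @param amplitudes Activation amplitude table, see [default_amplitudes()].
#' @param amp_subject_sd SD of subject x timepoint ROI amplitude deviations.
#' @param fc Communities + loadings, see [default_fc_communities()].
#' @param resp_sd SD of the subject response multiplier on loading
#'   increments (1 + N(0, resp_sd), may be negative: non-responders).
#' @param noise A [noise_spec()].
#' @param artifact An [artifact_spec()].
#' @param scale_slope Points of PSQI change per unit change in true mean
#'   Fisher-z FC (negative: FC gain goes with sleep improvement).
#' @param scale_population_r Target population correlation magnitude
#'   between PSQI improvement and true mean-FC change.
#' @param scales Clinical scale baseline/change table (see source for the
#'   default layout).
#' @param psqi_baseline_mean,psqi_baseline_sd Baseline PSQI total moments.
#' @param psqi_change Named change means per group, points.
#' @param emit_intensity If `TRUE`, also emit dual-wavelength raw
#'   intensities by inverting the modified Beer-Lambert law (round-trip
#'   testing of [mbll_convert()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_per_group = 32L,
                       montage = default_montage(),
                       paradigm = vft_paradigm(),
                       hrf_peak_s = 6, hrf_undershoot_s = 16,
                       hrf_undershoot_ratio = 1 / 6,
                       amplitudes = default_amplitudes(),
                       amp_subject_sd = 0.10,
                       fc = default_fc_communities(montage),
                       resp_sd = 3.5,
                       noise = noise_spec(),
                       artifact = artifact_spec(),
                       scale_slope = -6,
                       scale_population_r = 0.5,
                       scales = default_scale_table(),
                       psqi_baseline_mean = 13.1, psqi_baseline_sd = 2.9,
                       psqi_change = c(intervention = -4.69, control = -2.13),
                       emit_intensity = FALSE) {
  stopifnot(n_per_group >= 2, amp_subject_sd >= 0, resp_sd >= 0,
            scale_population_r > 0, scale_population_r < 1)
  if (any(!is.finite(amplitudes$amplitude)))
    rlang::abort("amplitudes must be finite")
  if (any(fc$loadings$loading < 0 | fc$loadings$loading >= 1))
    rlang::abort("loadings must be in [0, 1)")
  if (any(noise$oscillations$freq >= paradigm$fs / 2))
    rlang::abort("oscillation frequencies must be below fs/2")
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         montage = validate_montage(montage), paradigm = paradigm,
         hrf = list(peak_s = hrf_peak_s, undershoot_s = hrf_undershoot_s,
                    undershoot_ratio = hrf_undershoot_ratio),
         amplitudes = tibble::as_tibble(amplitudes),
         amp_subject_sd = amp_subject_sd, fc = fc, resp_sd = resp_sd,
         noise = noise, artifact = artifact,
         scale_slope = scale_slope, scale_population_r = scale_population_r,
         scales = scales, psqi_baseline_mean = psqi_baseline_mean,
         psqi_baseline_sd = psqi_baseline_sd, psqi_change = psqi_change,
         emit_intensity = emit_intensity),
    class = "sim_config")
}

#' Default clinical scale table for the simulator
#'
#' Baseline moments and per-group 4-week change means for the PSQI
#' sub-dimensions (0-3 integer scores; the hypnotic-drug dimension is
#' excluded by design), the Zung depression (SDS) and anxiety (SAS)
#' indices and the 14-item Perceived Stress Scale. Sub-dimension scores
#' are rounded and clamped to their instrument range, which makes them
#' discrete and skewed (so normality gating has real work to do).
#'
#' @return Tibble with columns `scale`, `baseline_mean`, `baseline_sd`,
#'   `change_intervention`, `change_control`, `change_sd`, `discrete`,
#'   `min`, `max`.
#' @export
default_scale_table <- function() {
  tibble::tribble(
    ~scale, ~baseline_mean, ~baseline_sd, ~change_intervention,
    ~change_control, ~change_sd, ~discrete, ~min, ~max,
    "psqi_quality",     2.44, 0.60, -1.38, -0.81, 0.75, TRUE, 0, 3,
    "psqi_latency",     2.20, 0.57, -0.50, -0.03, 0.70, TRUE, 0, 3,
    "psqi_duration",    2.36, 0.57, -0.88, -0.50, 0.80, TRUE, 0, 3,
    "psqi_efficiency",  2.33, 0.60, -0.94, -0.47, 0.85, TRUE, 0, 3,
    "psqi_disturbance", 1.72, 1.00, -0.38, -0.03, 0.75, TRUE, 0, 3,
    "psqi_daytime",     2.00, 0.75, -0.63, -0.28, 0.85, TRUE, 0, 3,
    "sds",              53.5, 13.4, -7.78, -3.31, 7.8, FALSE, 25, 100,
    "sas",              49.1, 14.0, -8.63, -4.38, 7.3, FALSE, 25, 100,
    "pss14",            42.0, 7.30, -4.38, -1.94, 6.4, FALSE, 0, 56)
}

# internal: n x p matrix of stationary AR(1) columns with marginal sd 1
ar1_matrix <- function(n, p, phi) {
  e <- matrix(stats::rnorm(n * p), n, p)
  if (phi == 0) return(e)
  e[-1, ] <- e[-1, ] * sqrt(1 - phi^2)  # first row already marginal sd 1
  m <- stats::filter(e, phi, method = "recursive")
  matrix(as.numeric(m), n, p)
}

# internal: loading matrix (communities x channels) for one group/timepoint,
# with the subject's response multiplier applied to the pre->post increment
loading_matrix <- function(cfg, group, timepoint, resp = 0) {
  K <- length(cfg$fc$communities)
  W <- matrix(0, K, 48, dimnames = list(names(cfg$fc$communities), NULL))
  for (k in names(cfg$fc$communities)) {
    ld <- cfg$fc$loadings
    w_pre <- ld$loading[ld$community == k & ld$group == group &
                          ld$timepoint == "pre"]
    w_tp <- ld$loading[ld$community == k & ld$group == group &
                         ld$timepoint == timepoint]
    w <- if (timepoint == "pre") w_pre else w_pre + (w_tp - w_pre) * (1 + resp)
    w <- min(max(w, 0), 0.999)
    W[k, cfg$fc$communities[[k]]] <- w
  }
  W
}

# internal: model (true) 48x48 correlation matrix implied by a loading
# matrix and the passband idiosyncratic noise sd
true_correlation <- function(W, idio_sd) {
  C <- crossprod(W) + diag(idio_sd^2, ncol(W))
  stats::cov2cor(C)
}

# internal: true mean Fisher-z FC over all off-diagonal unordered pairs
true_mean_z <- function(W, idio_sd) {
  R <- true_correlation(W, idio_sd)
  mean(atanh(R[upper.tri(R)]))
}

#' Simulate one subject x session recording
#'
#' Composes, channel by channel: the task response (amplitude for the
#' channel's ROI times the HRF-convolved block regressor), shared latent
#' community signals, AR(1) + white idiosyncratic noise, physiological
#' oscillations, linear drift, and finally motion artifacts. Reproducible:
#' the RNG substream is derived from `(cfg$seed, subject, timepoint)`.
#'
#' @param cfg A [sim_config()].
#' @param subject Subject identifier (string).
#' @param group `"intervention"` or `"control"`.
#' @param timepoint `"pre"` or `"post"`.
#' @param subject_effects Optional list with `resp` (response multiplier)
#'   and `amp_dev` (named ROI amplitude deviations for this timepoint);
#'   `NULL` means no subject-level deviations.
#' @return A [nirs_recording()].
#' @export
simulate_recording <- function(cfg, subject, group, timepoint,
                               subject_effects = NULL) {
  p <- cfg$paradigm
  n <- p$n_samples
  m <- cfg$montage
  tt <- paradigm_times(p)
  reg <- task_regressor(p, cfg$hrf$peak_s, cfg$hrf$undershoot_s,
                        cfg$hrf$undershoot_ratio)

  amp_tab <- cfg$amplitudes
  amp_roi <- amp_tab$amplitude[amp_tab$group == group &
                                 amp_tab$timepoint == timepoint]
  names(amp_roi) <- amp_tab$roi[amp_tab$group == group &
                                  amp_tab$timepoint == timepoint]
  a <- unname(amp_roi[m$roi])
  if (!is.null(subject_effects$amp_dev))
    a <- a + unname(subject_effects$amp_dev[m$roi])

  W <- loading_matrix(cfg, group, timepoint, subject_effects$resp %||% 0)
  ns <- cfg$noise
  art <- cfg$artifact

  with_seed(substream_seed(cfg$seed, "rec", subject, timepoint), {
    X <- outer(reg, a)
    if (nrow(W) > 0 && any(W > 0)) {
      L <- ar1_matrix(n, nrow(W), ns$ar1_coef)
      X <- X + L %*% W
    }
    if (ns$ar1_sd > 0)
      X <- X + ns$ar1_sd * ar1_matrix(n, 48, ns$ar1_coef)
    if (ns$white_sd > 0)
      X <- X + matrix(stats::rnorm(n * 48, sd = ns$white_sd), n, 48)
    for (i in seq_len(nrow(ns$oscillations))) {
      o <- ns$oscillations[i, ]
      ph <- if (isTRUE(o$random_phase)) stats::runif(48, 0, 2 * pi) else
        rep(0, 48)
      # sin(wt + ph) expanded so sin/cos run over 700 samples, not 700 x 48
      wt <- 2 * pi * o$freq * tt
      X <- X + o$amp * (outer(sin(wt), cos(ph)) + outer(cos(wt), sin(ph)))
    }
    if (ns$drift_slope_sd > 0) {
      slopes <- stats::rnorm(48, sd = ns$drift_slope_sd)
      X <- X + outer(tt - mean(tt), slopes)
    }
    dur_min <- p$total_s / 60
    if (art$spike_rate > 0) {
      for (ch in 1:48) {
        k <- stats::rpois(1, art$spike_rate * dur_min)
        if (k > 0) {
          pos <- sample.int(n - 3L, k, replace = TRUE) + 1L
          amp_s <- stats::rnorm(k, sd = art$spike_amp_sd)
          for (j in seq_len(k)) {  # 3-sample triangular transient
            X[pos[j] + (-1:1), ch] <-
              X[pos[j] + (-1:1), ch] + amp_s[j] * c(0.5, 1, 0.5)
          }
        }
      }
    }
    if (art$shift_rate > 0) {
      for (ch in 1:48) {
        k <- stats::rpois(1, art$shift_rate * dur_min)
        if (k > 0) {
          pos <- sample.int(n - 1L, k, replace = TRUE)
          amp_s <- stats::rnorm(k, sd = art$shift_amp_sd)
          for (j in seq_len(k))
            X[(pos[j] + 1L):n, ch] <- X[(pos[j] + 1L):n, ch] + amp_s[j]
        }
      }
    }
    rec <- nirs_recording(X, fs = p$fs, subject = subject, group = group,
                          timepoint = timepoint, channels = m$channel)
    if (isTRUE(cfg$emit_intensity))
      rec$intensity <- emit_intensity(X, baseline_tail_s = 10, fs = p$fs)
    rec
  })
}

#' Simulate a full two-group, two-timepoint cohort
#'
#' Draws per-subject effects (response multiplier, amplitude deviations),
#' generates pre and post recordings for `n_per_group` subjects per group,
#' and generates clinical scale scores with the PSQI total change linearly
#' coupled to each subject's true change in mean Fisher-z connectivity (see
#' [sim_config()]). Fully deterministic given the config.
#'
#' @param cfg A [sim_config()].
#' @param groups Arms to generate (default both; a single arm is useful
#'   for focused simulation studies).
#' @return A `vft_cohort` list: `recordings` (list of [nirs_recording()]),
#'   `scales` (tibble, one row per subject x timepoint), `truth` (list with
#'   per-subject ground truth incl. `delta_z_true`, the config, and the
#'   realized scale-noise SD).
#' @export
simulate_cohort <- function(cfg, groups = c("intervention", "control")) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- match.arg(groups, c("intervention", "control"),
                      several.ok = TRUE)
  subjects <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(length(groups) * cfg$n_per_group)),
    group = rep(groups, each = cfg$n_per_group))
  rois <- roi_names()

  # subject-level effects (one substream per subject)
  eff <- purrr::pmap(subjects, function(subject, group) {
    with_seed(substream_seed(cfg$seed, "subj", subject), {
      list(
        resp = stats::rnorm(1, 0, cfg$resp_sd),
        amp_dev = list(
          pre = stats::setNames(stats::rnorm(9, 0, cfg$amp_subject_sd), rois),
          post = stats::setNames(stats::rnorm(9, 0, cfg$amp_subject_sd), rois)))
    })
  })

  # true per-subject connectivity summaries
  truth_subj <- purrr::map2_dfr(seq_len(nrow(subjects)), eff, function(i, e) {
    g <- subjects$group[i]
    z_pre <- true_mean_z(loading_matrix(cfg, g, "pre", e$resp),
                         cfg$noise$ar1_sd)
    z_post <- true_mean_z(loading_matrix(cfg, g, "post", e$resp),
                          cfg$noise$ar1_sd)
    tibble::tibble(subject = subjects$subject[i], group = g, resp = e$resp,
                   mean_z_pre = z_pre, mean_z_post = z_post,
                   delta_z_true = z_post - z_pre)
  })

  recordings <- purrr::flatten(purrr::map(seq_len(nrow(subjects)), function(i) {
    e <- eff[[i]]
    purrr::map(c("pre", "post"), function(tp) {
      simulate_recording(cfg, subjects$subject[i], subjects$group[i], tp,
                         subject_effects = list(resp = e$resp,
                                                amp_dev = e$amp_dev[[tp]]))
    })
  }))

  scales <- simulate_scales(cfg, subjects, truth_subj)

  structure(
    list(recordings = recordings, scales = scales$table,
         truth = list(subjects = truth_subj, config = cfg,
                      scale_noise_sd = scales$noise_sd,
                      amp_effects = eff)),
    class = "vft_cohort")
}

# internal: clinical scales with PSQI total coupled to true FC change
simulate_scales <- function(cfg, subjects, truth_subj) {
  with_seed(substream_seed(cfg$seed, "scales"), {
    ns <- nrow(subjects)
    dz <- truth_subj$delta_z_true
    grp <- subjects$group
    # residual SD giving the target population correlation, from the
    # realized spread of true FC change in the intervention arm
    sd_dz <- stats::sd(dz[grp == "intervention"])
    if (!is.finite(sd_dz) || sd_dz == 0) sd_dz <- stats::sd(dz)
    if (!is.finite(sd_dz) || sd_dz == 0) sd_dz <- 1e-6
    noise_sd <- abs(cfg$scale_slope) * sd_dz *
      sqrt(1 / cfg$scale_population_r^2 - 1)
    ctr <- stats::ave(dz, grp) # group-wise mean of dz
    change_psqi <- unname(cfg$psqi_change[grp]) +
      cfg$scale_slope * (dz - ctr) + stats::rnorm(ns, 0, noise_sd)
    base_psqi <- pmin(21, pmax(0, round(
      stats::rnorm(ns, cfg$psqi_baseline_mean, cfg$psqi_baseline_sd))))
    post_psqi <- pmin(21, pmax(0, base_psqi + change_psqi))

    tab <- cfg$scales
    one_scale <- function(s) {
      base <- stats::rnorm(ns, s$baseline_mean, s$baseline_sd)
      chg <- ifelse(grp == "intervention", s$change_intervention,
                    s$change_control) + stats::rnorm(ns, 0, s$change_sd)
      post <- base + chg
      clamp <- function(x) pmin(s$max, pmax(s$min, x))
      if (s$discrete) list(pre = clamp(round(base)), post = clamp(round(post)))
      else list(pre = clamp(base), post = clamp(post))
    }
    vals <- purrr::map(seq_len(nrow(tab)), function(i) one_scale(tab[i, ]))
    names(vals) <- tab$scale

    mk <- function(tp) {
      out <- tibble::tibble(subject = subjects$subject, group = grp,
                            timepoint = tp,
                            psqi_total = if (tp == "pre") base_psqi else
                              post_psqi)
      for (s in tab$scale) out[[s]] <- vals[[s]][[if (tp == "pre") "pre" else
        "post"]]
      out
    }
    list(table = dplyr::bind_rows(mk("pre"), mk("post")), noise_sd = noise_sd)
  })
}

#' Persist a simulated cohort as plain-text files
#'
#' Writes one recording TSV per subject x session, the cohort scale table
#' as CSV, and the ground-truth record as YAML.
#'
#' @param cohort A `vft_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, sprintf("%s_%s.tsv", rec$subject,
                                                rec$timepoint)))
  readr::write_csv(cohort$scales, file.path(dir, "scales.csv"))
  yaml::write_yaml(
    list(subjects = lapply(seq_len(nrow(cohort$truth$subjects)), function(i)
      as.list(cohort$truth$subjects[i, ])),
      scale_noise_sd = cohort$truth$scale_noise_sd,
      seed = cohort$truth$config$seed),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `*_pre.tsv` / `*_post.tsv` recordings and
#'   `scales.csv`.
#' @return A `vft_cohort` list (without ground truth unless `truth.yaml` is
#'   present).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "_(pre|post)\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) rlang::abort(paste0("no recordings found in ", dir))
  recordings <- purrr::map(files, read_recording)
  scales_path <- file.path(dir, "scales.csv")
  scales <- if (file.exists(scales_path))
    readr::read_csv(scales_path, show_col_types = FALSE) else NULL
  truth_path <- file.path(dir, "truth.yaml")
  truth <- if (file.exists(truth_path)) yaml::read_yaml(truth_path) else NULL
  structure(list(recordings = recordings, scales = scales, truth = truth),
            class = "vft_cohort")
}
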