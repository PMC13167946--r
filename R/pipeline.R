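#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> quality gate ->
#' activation -> connectivity -> clinical statistics -> brain-behaviour
#' correlation, as one configured, reproducible run.
#'
#' Exactly one input mode: pass a [sim_config()] to simulate a cohort
#' on the fly, or `input_dir` pointing to files written by
#' [write_cohort()]. Subjects enter the imaging analyses only if they
#' pass the quality gate (at least `min_good_channels` good channels at
#' both timepoints); scale statistics use all subjects with scale data.
#' The correlation report relates each intervention-group subject's PSQI
#' improvement (pre minus post) to their mean-FC change.
#'
#' @param sim A [sim_config()], or `NULL` when reading from `input_dir`.
#' @param preproc A [preproc_config()].
#' @param paradigm A [vft_paradigm()].
#' @param montage A montage; defaults to the simulation montage or
#'   [default_montage()].
#' @param input_dir Optional cohort directory (mutually exclusive with
#'   `sim`).
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as TSV plus a provenance YAML.
#' @param write_fc_matrices Also write one FC matrix TSV per subject x
#'   session (off by default).
#' @return A `vft_run` list: `quality`, `included`, `contrasts`,
#'   `channel_tests`, `activation_map`, `roi_activation`, `fc`,
#'   `fc_pair_tests`, `fc_roi_tests`, `fc_mean_tests`, `clinical`,
#'   `baseline`, `correlation`, `provenance`.
#' @export
run_pipeline <- function(sim = sim_config(), preproc = preproc_config(),
                         paradigm = NULL, montage = NULL, input_dir = NULL,
                         out_dir = NULL, write_fc_matrices = FALSE) {
  if (!is.null(sim) && !is.null(input_dir))
    rlang::abort("choose one input mode: `sim` or `input_dir`")
  if (is.null(sim) && is.null(input_dir))
    rlang::abort("no input: give `sim` or `input_dir`")

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) rlang::abort(
      paste0("pipeline stage [", label, "] failed: ", conditionMessage(e)),
      parent = e))
  }

  cohort <- stage("input", {
    if (!is.null(sim)) simulate_cohort(sim) else read_cohort(input_dir)
  })
  paradigm <- paradigm %||% (if (!is.null(sim)) sim$paradigm else
    vft_paradigm())
  montage <- montage %||% (if (!is.null(sim)) sim$montage else
    default_montage())

  pp <- stage("preprocess", purrr::map(cohort$recordings,
                                       preprocess_recording,
                                       paradigm = paradigm, cfg = preproc))

  gate <- stage("quality", {
    key <- vapply(pp, function(r) r$subject, character(1))
    tp <- vapply(pp, function(r) r$timepoint, character(1))
    quality <- purrr::map_dfr(pp, function(r) {
      q <- attr(r, "quality")
      q$subject <- r$subject; q$group <- r$group; q$timepoint <- r$timepoint
      q
    })
    subjects <- unique(key)
    valid <- vapply(subjects, function(s) {
      pre <- pp[[which(key == s & tp == "pre")[1]]]
      post <- pp[[which(key == s & tp == "post")[1]]]
      subject_quality_gate(attr(pre, "quality"), attr(post, "quality"),
                           preproc$min_good_channels)$subject_valid
    }, logical(1))
    list(quality = quality,
         included = tibble::tibble(subject = subjects, valid = valid))
  })
  included <- gate$included$subject[gate$included$valid]
  if (!length(included))
    rlang::abort(paste0(
      "empty cohort: no subject has >= ", preproc$min_good_channels,
      " good channels at both timepoints"))
  pp_in <- purrr::keep(pp, function(r) r$subject %in% included)

  contrasts <- stage("activation",
                     cohort_contrasts(pp_in, paradigm, montage))
  channel_tests <- stage("activation",
                         channel_activation_tests(contrasts, "change"))
  activation_map <- stage("activation",
                          channel_activation_tests(contrasts, "activation"))
  roi_activation <- stage("activation", roi_tests(contrasts, montage))

  fc <- stage("connectivity", cohort_fc(pp_in, paradigm, montage))
  fc_pair_tests <- stage("connectivity", fc_change_tests(fc, "pair"))
  fc_roi_tests <- stage("connectivity", fc_change_tests(fc, "roi_pair"))
  fc_mean_tests <- stage("connectivity", fc_change_tests(fc, "mean"))

  clinical <- baseline <- NULL
  if (!is.null(cohort$scales)) {
    clinical <- stage("clinical", clinical_table(cohort$scales))
    baseline <- stage("clinical", baseline_table(cohort$scales))
  }

  correlation <- NULL
  if (!is.null(cohort$scales)) {
    correlation <- stage("correlation", {
      dfc <- fc$summary |>
        dplyr::select("subject", "group", "timepoint", "mean_fc") |>
        tidyr::pivot_wider(names_from = "timepoint",
                           values_from = "mean_fc") |>
        dplyr::mutate(delta_fc = .data$post - .data$pre)
      psqi <- cohort$scales |>
        dplyr::select("subject", "timepoint", "psqi_total") |>
        tidyr::pivot_wider(names_from = "timepoint",
                           values_from = "psqi_total") |>
        dplyr::mutate(psqi_improvement = .data$pre - .data$post)
      dat <- dplyr::inner_join(dfc, psqi, by = "subject",
                               suffix = c("_fc", "_psqi")) |>
        dplyr::filter(.data$group == "intervention")
      res <- correlate_outcome(dat, .data$delta_fc, .data$psqi_improvement)
      res$comparison <- "psqi_improvement_vs_delta_mean_fc"
      res
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("nirsvft")),
    seed = if (!is.null(sim)) sim$seed else NA_integer_,
    config_hash = rlang::hash(list(sim = sim, preproc = preproc,
                                   paradigm = paradigm, montage = montage)),
    n_subjects = length(unique(gate$included$subject)),
    n_included = length(included),
    steps = pp_in[[1]]$steps)

  run <- structure(
    list(quality = gate$quality, included = gate$included,
         contrasts = contrasts, channel_tests = channel_tests,
         activation_map = activation_map, roi_activation = roi_activation,
         fc = fc, fc_pair_tests = fc_pair_tests,
         fc_roi_tests = fc_roi_tests, fc_mean_tests = fc_mean_tests,
         clinical = clinical, baseline = baseline,
         correlation = correlation, truth = cohort$truth,
         provenance = provenance),
    class = "vft_run")

  if (!is.null(out_dir))
    write_run(run, out_dir, write_fc_matrices = write_fc_matrices)
  run
}

#' Write a pipeline run's result tables
#'
#' @param run A `vft_run`.
#' @param out_dir Output directory (created if missing).
#' @param write_fc_matrices Also write per-subject FC matrices.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, write_fc_matrices = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) if (!is.null(x))
    readr::write_tsv(x, file.path(out_dir, f))
  w(run$quality, "quality_report.tsv")
  w(run$included, "included_subjects.tsv")
  w(run$channel_tests, "channel_change_tests.tsv")
  w(run$activation_map, "channel_activation_map.tsv")
  w(run$roi_activation, "roi_activation.tsv")
  w(run$fc$summary, "fc_summary.tsv")
  w(run$fc_pair_tests, "fc_pair_tests.tsv")
  w(run$fc_roi_tests, "fc_roi_pair_tests.tsv")
  w(run$fc_mean_tests, "fc_mean_tests.tsv")
  w(run$clinical, "clinical_table.tsv")
  w(run$baseline, "baseline_table.tsv")
  w(run$correlation, "correlation_report.tsv")
  if (write_fc_matrices) {
    for (f in run$fc$matrices) {
      df <- as.data.frame(f$r)
      df <- cbind(channel = rownames(f$r), df)
      readr::write_tsv(df, file.path(
        out_dir, sprintf("fc_%s_%s.tsv", f$subject, f$timepoint)))
    }
  }
  yaml::write_yaml(run$provenance, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' @export
print.vft_run <- function(x, ...) {
  cat(sprintf("<vft_run> %d/%d subjects passed the quality gate\n",
              x$provenance$n_included, x$provenance$n_subjects))
  if (!is.null(x$correlation))
    cat(sprintf("  PSQI improvement vs delta mean FC: r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  invisible(x)
}

#' @method glance vft_run
#' @export
glance.vft_run <- function(x, ...) {
  mfc <- x$fc_mean_tests
  bt <- mfc[mfc$comparison == "between", ]
  wi <- mfc[mfc$comparison == "within_intervention", ]
  tibble::tibble(
    n_subjects = x$provenance$n_subjects,
    n_included = x$provenance$n_included,
    mean_fc_change_intervention = fisher_z_inv(wi$estimate[1]),
    mean_fc_within_p = wi$p[1],
    mean_fc_between_t = bt$statistic[1],
    mean_fc_between_p = bt$p[1],
    n_sig_channel_pairs_intervention = sum(
      x$fc_pair_tests$sig[x$fc_pair_tests$comparison ==
                            "within_intervention"], na.rm = TRUE),
    psqi_fc_r = if (!is.null(x$correlation)) x$correlation$r else NA_real_,
    psqi_fc_p = if (!is.null(x$correlation)) x$correlation$p else NA_real_)
}
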