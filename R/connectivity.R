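#' Fisher z-transform and its inverse
#'
#' `fisher_z()` is `atanh(r)` (variance-stabilising transform for Pearson
#' correlations); `fisher_z_inv()` is `tanh(z)`. Correlations are clamped
#' to `|r| <= 1 - 1e-15` before transforming so exact +/-1 stays finite.
#'
#' @param r,z Correlations / z-values.
#' @return Transformed values.
#' @export
fisher_z <- function(r) atanh(pmax(pmin(r, 1 - 1e-15), -1 + 1e-15))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Task-window functional connectivity matrix
#'
#' Pearson correlation between every pair of channels, computed over the
#' task window only (the 60 s task state; rest windows are excluded).
#' Bad channels - excluded by the quality report or with zero variance in
#' the window - get missing rows/columns. The matrix is symmetric with
#' unit diagonal on good channels.
#'
#' @param rec A preprocessed [nirs_recording()].
#' @param paradigm A [vft_paradigm()].
#' @param good Optional logical channel mask; defaults to the attached
#'   quality report, else all good.
#' @return An `nirs_fc` object: list with `r` (48x48 matrix), `good`,
#'   `subject`, `group`, `timepoint`, `channels`.
#' @export
fc_matrix <- function(rec, paradigm = vft_paradigm(), good = NULL) {
  w <- paradigm_windows(paradigm)$task
  if (length(w) < 3) rlang::abort("task window has fewer than 3 samples")
  if (max(w) > nrow(rec$data))
    rlang::abort("task window extends beyond the recording")
  if (is.null(good)) {
    q <- attr(rec, "quality")
    good <- if (!is.null(q)) q$good else rep(TRUE, ncol(rec$data))
  }
  X <- rec$data[w, , drop = FALSE]
  good <- good & col_sds(X) > 0
  R <- matrix(NA_real_, ncol(X), ncol(X))
  if (any(good)) {
    R[good, good] <- stats::cor(X[, good, drop = FALSE])
    diag(R)[!good] <- NA_real_
  }
  dimnames(R) <- list(colnames(rec$data), colnames(rec$data))
  structure(list(r = R, good = good, subject = rec$subject,
                 group = rec$group, timepoint = rec$timepoint,
                 channels = rec$channels),
            class = "nirs_fc")
}

#' @export
print.nirs_fc <- function(x, ...) {
  cat(sprintf("<nirs_fc> subject=%s group=%s timepoint=%s: %d good channels, mean FC %.3f\n",
              x$subject, x$group, x$timepoint, sum(x$good), mean_fc(x)))
  invisible(x)
}

#' Tidy edge list of a connectivity matrix
#'
#' @param x An `nirs_fc`.
#' @param ... Unused.
#' @return Tibble with one row per unordered good channel pair:
#'   `channel_a`, `channel_b`, `r`, `z`.
#' @method tidy nirs_fc
#' @export
tidy.nirs_fc <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  r <- x$r[upper.tri(x$r)]
  keep <- !is.na(r)
  tibble::tibble(
    subject = x$subject, group = x$group, timepoint = x$timepoint,
    channel_a = x$channels[idx[keep, 1]], channel_b = x$channels[idx[keep, 2]],
    r = r[keep], z = fisher_z(r[keep]))
}

#' Mean functional connectivity of a matrix
#'
#' The grand average over all good off-diagonal unordered channel pairs
#' (1128 pairs when all 48 channels are good), averaged on the Fisher z
#' scale and back-transformed to r.
#'
#' @param fc An `nirs_fc`.
#' @return Scalar mean FC in `[-1, 1]`.
#' @export
mean_fc <- function(fc) {
  r <- fc$r[upper.tri(fc$r)]
  r <- r[!is.na(r)]
  if (!length(r)) rlang::abort("no good channel pairs")
  fisher_z_inv(mean(fisher_z(r)))
}

#' Region-pair functional connectivity
#'
#' Aggregates a channel-level FC matrix to the 9x9 ROI level: entry (A, B)
#' is the back-transformed mean Fisher-z over all good channel pairs with
#' one member in A and one in B; the diagonal (A, A) averages the distinct
#' within-ROI pairs. ROIs with no good channels give missing rows/columns.
#'
#' @param fc An `nirs_fc`.
#' @param montage A montage mapping channels to ROIs.
#' @return 9x9 symmetric named matrix.
#' @export
roi_fc <- function(fc, montage = default_montage()) {
  m <- validate_montage(montage)
  sets <- roi_channel_sets(m)
  nm <- roi_names()
  Z <- fisher_z(fc$r)
  out <- matrix(NA_real_, 9, 9, dimnames = list(nm, nm))
  pos <- match(fc$channels, m$channel)
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      a <- which(fc$channels %in% sets[[nm[i]]] & fc$good)
      b <- which(fc$channels %in% sets[[nm[j]]] & fc$good)
      if (!length(a) || !length(b)) next
      zz <- Z[a, b, drop = FALSE]
      vals <- if (i == j) zz[upper.tri(zz)] else as.vector(zz)
      vals <- vals[is.finite(vals)]
      if (length(vals))
        out[i, j] <- out[j, i] <- fisher_z_inv(mean(vals))
    }
  }
  out
}

#' Connectivity for a whole cohort
#'
#' Computes [fc_matrix()] per recording and returns the per-subject
#' matrices plus tidy channel-pair and ROI-pair tables and mean FC.
#'
#' @param recordings List of preprocessed recordings.
#' @param paradigm A [vft_paradigm()].
#' @param montage A montage.
#' @return List: `matrices` (list of `nirs_fc`), `edges` (tidy channel-pair
#'   tibble), `roi_edges` (tidy ROI-pair tibble incl. within-ROI
#'   diagonal), `summary` (per subject x timepoint `mean_fc`).
#' @export
cohort_fc <- function(recordings, paradigm = vft_paradigm(),
                      montage = default_montage()) {
  mats <- purrr::map(recordings, fc_matrix, paradigm = paradigm)
  edges <- purrr::map_dfr(mats, tidy)
  roi_edges <- purrr::map_dfr(mats, function(f) {
    RF <- roi_fc(f, montage)
    idx <- which(upper.tri(RF, diag = TRUE), arr.ind = TRUE)
    vals <- RF[upper.tri(RF, diag = TRUE)]
    tibble::tibble(subject = f$subject, group = f$group,
                   timepoint = f$timepoint,
                   roi_a = rownames(RF)[idx[, 1]],
                   roi_b = colnames(RF)[idx[, 2]],
                   r = vals, z = fisher_z(vals))
  })
  summary <- purrr::map_dfr(mats, function(f)
    tibble::tibble(subject = f$subject, group = f$group,
                   timepoint = f$timepoint, n_good = sum(f$good),
                   mean_fc = mean_fc(f), mean_z = fisher_z(mean_fc(f))))
  list(matrices = mats, edges = edges, roi_edges = roi_edges,
       summary = summary)
}

#' Pre/post and between-group connectivity statistics
#'
#' Inference on Fisher-z connectivity at one of three levels:
#' * `"pair"`: every good channel pair (family of up to 1128);
#' * `"roi_pair"`: the 36 ROI pairs plus the 9 within-ROI averages
#'   (family of 45);
#' * `"mean"`: the single mean-FC summary (no correction; mirrors a
#'   single-statistic group comparison).
#'
#' Within each group, a paired t-test on `z_post - z_pre` across subjects;
#' between groups, a pooled two-sample t-test on the change `delta z` with
#' Cohen's d. BH-FDR is applied within each comparison family (pairs with
#' missing data shrink the family). Estimates are also reported on the r
#' scale (back-transformed change).
#'
#' @param fc A [cohort_fc()] result (or a tibble shaped like its `edges` /
#'   `roi_edges` component).
#' @param level `"pair"`, `"roi_pair"` or `"mean"`.
#' @return Tibble with one row per comparison x edge: `comparison` in
#'   `within_intervention`, `within_control`, `between`, plus statistics.
#' @export
fc_change_tests <- function(fc, level = c("pair", "roi_pair", "mean")) {
  level <- match.arg(level)
  edges <- if (is.list(fc) && !is.data.frame(fc)) {
    switch(level,
           pair = fc$edges,
           roi_pair = fc$roi_edges,
           mean = dplyr::mutate(fc$summary, z = .data$mean_z))
  } else fc
  if (level == "mean") {
    edges$edge <- "mean_fc"
  } else if (level == "pair") {
    edges$edge <- sprintf("ch%02d-ch%02d", edges$channel_a, edges$channel_b)
  } else {
    edges$edge <- paste0(edges$roi_a, "-", edges$roi_b)
  }
  keys <- sort(unique(edges$edge))
  grp_of <- edges |>
    dplyr::distinct(.data$subject, .data$group)
  mats <- function(g) {
    sub <- edges[edges$group == g, ]
    pre <- sub[sub$timepoint == "pre", ]
    post <- sub[sub$timepoint == "post", ]
    PRE <- long_to_matrix(pre$subject, pre$edge, pre$z, keys)
    POST <- long_to_matrix(post$subject, post$edge, post$z, keys)
    list(PRE = PRE, POST = POST, DZ = {
      dz <- POST - PRE
      dz[!is.finite(dz)] <- NA_real_
      dz
    })
  }
  gi <- mats("intervention")
  gc <- mats("control")
  within <- purrr::map_dfr(
    list(within_intervention = gi, within_control = gc),
    function(m) {
      st <- paired_cols_stats(m$PRE, m$POST)
      st$edge <- keys
      st
    }, .id = "comparison")
  between <- two_sample_cols_stats(gi$DZ, gc$DZ)
  between$edge <- keys
  between$comparison <- "between"
  out <- dplyr::bind_rows(within, between) |>
    dplyr::group_by(.data$comparison) |>
    dplyr::mutate(q = if (level == "mean") .data$p else
      benjamini_hochberg(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(estimate_r = fisher_z_inv(.data$estimate),
                  sig = !is.na(.data$q) & .data$q < 0.05)
  out[, c("comparison", "edge", "n", "n1", "n2",
          "estimate", "estimate_r", "conf.low", "conf.high",
          "statistic", "df", "p", "q", "d", "sig")]
}

#' Brain-behaviour correlation
#'
#' Pearson correlation between a per-subject connectivity change and a
#' per-subject clinical change, with the two-sided p-value from the
#' t-transform `t = r sqrt((n-2)/(1-r^2))` and a Fisher-z 95% CI.
#'
#' @param data Data frame with one row per subject.
#' @param fc,scale Columns (tidy-eval) holding the connectivity and scale
#'   changes.
#' @return One-row tibble: `r`, `statistic`, `df`, `p`, `n`, `conf.low`,
#'   `conf.high`.
#' @examples
#' d <- data.frame(dfc = c(0.1, 0.2, 0.05, 0.3), dpsqi = c(2, 4, 1, 5))
#' correlate_outcome(d, dfc, dpsqi)
#' @export
correlate_outcome <- function(data, fc, scale) {
  x <- dplyr::pull(data, {{ fc }})
  y <- dplyr::pull(data, {{ scale }})
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    rlang::abort("zero variance in one of the vectors")
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  zc <- stats::qnorm(0.975) / sqrt(n - 3)
  tibble::tibble(r = r, statistic = tval, df = n - 2, p = p, n = n,
                 conf.low = fisher_z_inv(fisher_z(r) - zc),
                 conf.high = fisher_z_inv(fisher_z(r) + zc))
}
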