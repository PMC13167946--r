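#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: with order statistics `p_(1) <= ... <= p_(m)`, the
#' adjusted value is `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and
#' mapped back to input order. `NA` p-values are excluded from the family
#' (they do not count toward `m`) and propagate as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param m Family size; defaults to the number of non-missing p-values.
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' benjamini_hochberg(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.02 0.04 0.04
#' @export
benjamini_hochberg <- function(p, m = sum(!is.na(p))) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    rlang::abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  k <- sum(ok)
  if (k == 0) return(q)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  qs <- pmin(1, rev(cummin(rev((m / seq_len(k)) * ps))))
  q[ok][ord] <- qs
  q
}

#' Baseline-vs-task block contrast for one recording
#'
#' Per channel: the mean HbO2 over the full pre-task rest (baseline), the
#' mean over the task period, and their difference (the activation
#' contrast). Channels marked bad yield missing values, not zeros.
#'
#' @param rec A preprocessed [nirs_recording()].
#' @param paradigm A [vft_paradigm()].
#' @param good Optional logical vector (one per channel); defaults to the
#'   quality report attached by [preprocess_recording()], else all good.
#' @return Tibble with `channel`, `baseline_mean`, `task_mean`, `contrast`.
#' @export
block_contrast <- function(rec, paradigm = vft_paradigm(), good = NULL) {
  w <- paradigm_windows(paradigm)
  if (max(w$task) > nrow(rec$data))
    rlang::abort("task window extends beyond the recording")
  if (is.null(good)) {
    q <- attr(rec, "quality")
    good <- if (!is.null(q)) q$good else rep(TRUE, ncol(rec$data))
  }
  base <- colMeans(rec$data[w$baseline, , drop = FALSE])
  task <- colMeans(rec$data[w$task, , drop = FALSE])
  base[!good] <- NA_real_
  task[!good] <- NA_real_
  tibble::tibble(channel = rec$channels, baseline_mean = unname(base),
                 task_mean = unname(task),
                 contrast = unname(task - base))
}

#' Block contrasts for a whole cohort
#'
#' Applies [block_contrast()] to every recording and binds the results
#' with subject metadata and the channel's ROI.
#'
#' @param recordings List of preprocessed [nirs_recording()] objects.
#' @param paradigm A [vft_paradigm()].
#' @param montage A montage for the ROI column.
#' @return Long tibble: `subject`, `group`, `timepoint`, `channel`, `roi`,
#'   `baseline_mean`, `task_mean`, `contrast`.
#' @export
cohort_contrasts <- function(recordings, paradigm = vft_paradigm(),
                             montage = default_montage()) {
  m <- validate_montage(montage)
  purrr::map_dfr(recordings, function(rec) {
    bc <- block_contrast(rec, paradigm)
    bc$subject <- rec$subject
    bc$group <- rec$group
    bc$timepoint <- rec$timepoint
    bc$roi <- m$roi[match(bc$channel, m$channel)]
    bc[, c("subject", "group", "timepoint", "channel", "roi",
           "baseline_mean", "task_mean", "contrast")]
  })
}

# internal: vectorized paired t over the columns of subjects x K matrices
# (pairwise-complete); same statistics as paired_t_row, one row per column
paired_cols_stats <- function(PRE, POST) {
  ok <- is.finite(PRE) & is.finite(POST)
  D <- POST - PRE
  D[!ok] <- NA_real_
  dimnames(D) <- dimnames(ok) <- NULL
  n <- colSums(ok)
  sums <- colSums(D, na.rm = TRUE)
  md <- ifelse(n > 0, sums / n, NA_real_)
  ss <- colSums(D * D, na.rm = TRUE) - n * md^2
  sdd <- ifelse(n > 1, sqrt(pmax(0, ss) / (n - 1)), NA_real_)
  se <- sdd / sqrt(n)
  tval <- ifelse(se > 0, md / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tval), n - 1),
              ifelse(md == 0, 1, 0))  # degenerate: no spread
  tc <- stats::qt(0.975, pmax(1, n - 1))
  bad <- n < 2
  out <- tibble::tibble(
    n = as.integer(n), estimate = md, conf.low = md - tc * se,
    conf.high = md + tc * se, statistic = tval, df = n - 1, p = p,
    d = ifelse(sdd > 0, md / sdd, 0))
  out[bad, setdiff(names(out), "n")] <- NA_real_
  out
}

# internal: vectorized pooled two-sample t over columns with Cohen's d
two_sample_cols_stats <- function(X1, X2) {
  dimnames(X1) <- dimnames(X2) <- NULL
  n1 <- colSums(is.finite(X1))
  n2 <- colSums(is.finite(X2))
  m1 <- colMeans(X1, na.rm = TRUE)
  m2 <- colMeans(X2, na.rm = TRUE)
  v1 <- (colSums(X1 * X1, na.rm = TRUE) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2 * X2, na.rm = TRUE) - n2 * m2^2) / (n2 - 1)
  sp <- sqrt(pmax(0, ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  est <- m1 - m2
  tval <- ifelse(se > 0, est / se, 0)
  df <- n1 + n2 - 2
  bad <- n1 < 2 | n2 < 2
  out <- tibble::tibble(
    n1 = as.integer(n1), n2 = as.integer(n2), estimate = est,
    statistic = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
    d = ifelse(sp > 0, est / sp, 0))
  out[bad, setdiff(names(out), c("n1", "n2"))] <- NA_real_
  out
}

# internal: long (subject x key x value) -> subjects x keys matrix
long_to_matrix <- function(subject, key, value, keys = sort(unique(key))) {
  subs <- sort(unique(subject))
  M <- matrix(NA_real_, length(subs), length(keys),
              dimnames = list(subs, keys))
  M[cbind(match(subject, subs), match(key, keys))] <- value
  M
}

#' Channel-wise activation tests with FDR correction
#'
#' Group-level inference on the per-subject block contrasts, per channel.
#' Two comparisons:
#' * `"change"`: paired t-test of the post vs pre contrast within each
#'   group (did task activation change after treatment?);
#' * `"activation"`: one-sample t-test of the contrast against 0 within
#'   each group x timepoint (is the task state above baseline?).
#'
#' Benjamini-Hochberg correction is applied within each family of (up to)
#' 48 channels per group (x timepoint for `"activation"`); all-missing
#' channels are flagged and excluded, shrinking the family size.
#' Significance is `q < 0.05`.
#'
#' @param contrasts Cohort contrast tibble from [cohort_contrasts()].
#' @param comparison `"change"` or `"activation"`.
#' @return Tibble, one row per group (x timepoint) x channel, with
#'   `statistic`, `df`, `p`, `q`, `d`, mean change + 95% CI, `sig`.
#' @export
channel_activation_tests <- function(contrasts,
                                     comparison = c("change", "activation")) {
  comparison <- match.arg(comparison)
  roi_map <- dplyr::distinct(contrasts[, c("channel", "roi")])
  fam <- function(sub) {
    # family = the channels with testable data in this group (x timepoint)
    keys <- sort(unique(sub$channel))
    if (comparison == "change") {
      pre <- sub[sub$timepoint == "pre", ]
      post <- sub[sub$timepoint == "post", ]
      PRE <- long_to_matrix(pre$subject, pre$channel, pre$contrast, keys)
      POST <- long_to_matrix(post$subject, post$channel, post$contrast, keys)
    } else {
      POST <- long_to_matrix(sub$subject, sub$channel, sub$contrast, keys)
      PRE <- POST * 0
    }
    st <- paired_cols_stats(PRE, POST)
    st$channel <- keys
    st
  }
  grouping <- if (comparison == "change") "group" else c("group", "timepoint")
  res <- contrasts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(~ fam(.x)) |>
    dplyr::mutate(excluded = .data$n < 2,
                  q = benjamini_hochberg(ifelse(.data$excluded, NA, .data$p)),
                  sig = !is.na(.data$q) & .data$q < 0.05) |>
    dplyr::ungroup() |>
    dplyr::left_join(roi_map, by = "channel")
  res[, c(grouping, "channel", "roi", "n", "estimate", "conf.low",
          "conf.high", "statistic", "df", "p", "q", "d", "excluded", "sig")]
}

#' Region-of-interest activation table
#'
#' Mirrors the per-region activation summary of a two-arm pre/post trial:
#' for each ROI, the per-subject ROI contrast is the mean over its good
#' member channels; within each group the pre-vs-post change is tested
#' with a normality-gated paired test ([paired_change()]), and between
#' groups the change scores are compared with a normality-gated two-sample
#' test with Cohen's d or rank r ([between_group_change()]). Raw p-values
#' are reported (9 regions), with BH q-values alongside.
#'
#' @param contrasts Cohort contrast tibble from [cohort_contrasts()].
#' @param montage A montage (defines the ROI set).
#' @return Tibble, one row per ROI x group, with baseline/week-4 summaries,
#'   change mean + 95% CI, within-group p (+ q), and the between-group
#'   statistic, p (+ q) and effect size on the first row of each ROI.
#' @export
roi_tests <- function(contrasts, montage = default_montage()) {
  m <- validate_montage(montage)
  roi_subj <- contrasts |>
    dplyr::filter(is.finite(.data$contrast)) |>
    dplyr::group_by(.data$subject, .data$group, .data$timepoint,
                    .data$roi) |>
    dplyr::summarise(contrast = mean(.data$contrast), .groups = "drop")
  wide <- tidyr::pivot_wider(roi_subj, names_from = "timepoint",
                             values_from = "contrast")
  wide <- wide[stats::complete.cases(wide[, c("pre", "post")]), ]

  groups_present <- intersect(c("intervention", "control"),
                              unique(wide$group))
  rows <- list()
  for (roi in roi_names()) {
    dwide <- wide[wide$roi == roi, ]
    if (!nrow(dwide)) rlang::abort(paste0("empty ROI: ", roi))
    per_group <- purrr::map_dfr(groups_present, function(g) {
      dg <- dwide[dwide$group == g, ]
      pc <- paired_change(dg$pre, dg$post)
      tibble::tibble(
        roi = roi, group = g, n = nrow(dg),
        baseline_mean = mean(dg$pre), baseline_sd = stats::sd(dg$pre),
        week4_mean = mean(dg$post), week4_sd = stats::sd(dg$post),
        change_mean = pc$estimate, change_low = pc$conf.low,
        change_high = pc$conf.high, within_method = pc$method,
        within_statistic = pc$statistic, within_p = pc$p)
    })
    d1 <- dwide[dwide$group == "intervention", ]
    d2 <- dwide[dwide$group == "control", ]
    bg <- if (nrow(d1) >= 2 && nrow(d2) >= 2)
      between_group_change(d1$post - d1$pre, d2$post - d2$pre)
    else tibble::tibble(method = NA_character_, statistic = NA_real_,
                        p = NA_real_, effect = NA_real_,
                        effect_low = NA_real_, effect_high = NA_real_)
    pad <- rep(NA, nrow(per_group) - 1L)
    per_group$between_method <- c(bg$method, pad)
    per_group$between_statistic <- c(bg$statistic, pad)
    per_group$between_p <- c(bg$p, pad)
    per_group$effect <- c(bg$effect, pad)
    per_group$effect_low <- c(bg$effect_low, pad)
    per_group$effect_high <- c(bg$effect_high, pad)
    rows[[roi]] <- per_group
  }
  out <- dplyr::bind_rows(rows)
  # BH within the 9-test families, reported alongside the raw p-values
  out$within_q <- NA_real_
  for (g in c("intervention", "control")) {
    sel <- out$group == g
    out$within_q[sel] <- benjamini_hochberg(out$within_p[sel])
  }
  sel <- !is.na(out$between_p)
  out$between_q <- NA_real_
  out$between_q[sel] <- benjamini_hochberg(out$between_p[sel])
  out
}
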