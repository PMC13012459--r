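#' Label a baseline-out-of-range user as responder or non-responder
#'
#' A user responds when either (a) their follow-up zone moved at least one
#' step toward optimal (zone-shift rule), or (b) their value changed by at
#' least `pct` of baseline in the preferential direction — downward for
#' above-optimal baselines, upward for below-optimal ones — regardless of
#' zone movement. The percent rule lets users with extreme baselines count
#' even when the change does not cross a zone boundary.
#'
#' @param x1,x2 Baseline and follow-up values (x1 out-of-optimal).
#' @param spec A [zone_spec()].
#' @param pct Relative-change threshold on baseline (default 0.10).
#' @return A list: `responder` (logical), `basis` ("zone_shift",
#'   "pct_change", "both", or "none"), `pct_defined` (FALSE when x1 = 0).
#' @export
label_responder <- function(x1, x2, spec, pct = 0.10) {
  tr <- score_transition(x1, x2, spec)
  side <- zone_side(tr$zone1)
  pct_defined <- x1 != 0
  rel <- if (pct_defined) (x2 - x1) / x1 else NA_real_
  pct_hit <- pct_defined &
    ((side == "above" & rel <= -pct) | (side == "below" & rel >= pct))
  basis <- dplyr::case_when(
    tr$improved & pct_hit ~ "both",
    tr$improved ~ "zone_shift",
    pct_hit ~ "pct_change",
    TRUE ~ "none"
  )
  list(responder = tr$improved | pct_hit, basis = basis,
       pct_defined = pct_defined)
}

#' Welch two-sample comparison of a wearable metric between groups
#'
#' Two-tailed Welch's t-test, with the deliberately relaxed default
#' significance level alpha = 0.1 used for wearable contrasts (small
#' subgroups, noisy daily measures; the cost of a false negative is judged
#' higher than that of a false positive, and findings are exploratory).
#'
#' @param responders,nonresponders Numeric metric values per subject.
#' @param alpha Significance level for the flag.
#' @param metric Optional metric name carried through.
#' @return A one-row tibble: `metric`, `mean_responders`,
#'   `mean_nonresponders`, `n_responders`, `n_nonresponders`, `t_statistic`,
#'   `p_value`, `significant`, `small_sample`.
#' @export
compare_groups <- function(responders, nonresponders, alpha = 0.1,
                           metric = NA_character_) {
  a <- responders[is.finite(responders)]
  b <- nonresponders[is.finite(nonresponders)]
  if (length(a) < 2 || length(b) < 2) {
    stop_biotraj("input_error", "each group needs at least 2 finite values")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    tstat <- 0
    p <- 1
  } else {
    tt <- stats::t.test(a, b)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(metric = metric,
                 mean_responders = mean(a), mean_nonresponders = mean(b),
                 n_responders = length(a), n_nonresponders = length(b),
                 t_statistic = tstat, p_value = p,
                 significant = p <= alpha,
                 small_sample = length(a) == 2 || length(b) == 2)
}

#' Monthly wearable averages after a start date
#'
#' Months are fixed 30-day blocks from the start date: month m covers days
#' `[start + 30 (m - 1), start + 30 m)`. Metrics with no observation in a
#' month are missing for that month.
#'
#' @param wearables Wearable-day rows (one subject, or pre-averaged rows).
#' @param start_date Block origin, typically the baseline draw date.
#' @param months Number of 30-day blocks.
#' @return A tibble: `month` (1-based), one column per metric.
#' @export
monthly_series <- function(wearables, start_date, months = 12) {
  stopifnot(months >= 1)
  start_date <- as.Date(start_date)
  out <- lapply(seq_len(months), function(m) {
    from <- start_date + 30 * (m - 1)
    wm <- window_mean(wearables, from, from + 30)
    row <- tibble::as_tibble(as.list(stats::setNames(wm$mean, wm$metric)))
    row$month <- m
    row
  })
  dplyr::bind_rows(out)[, c("month", wearable_metrics())]
}

#' Characterize wearable profiles of responders vs non-responders
#'
#' For one marker's out-of-range-at-baseline paired users with wearable
#' coverage: labels each as responder/non-responder (zone shift or >= 10%
#' preferential change), then compares each wearable metric between groups
#' (two-tailed Welch, alpha = 0.1) in the baseline window (default 30 days
#' pre-baseline) and as between-tests change (mean over days strictly
#' between the draws minus the baseline-window mean), and aggregates
#' 12-month monthly series per group. All findings are exploratory.
#'
#' @param dataset A `biotraj_dataset`.
#' @param marker_id Marker (the motivating use is high total cholesterol).
#' @param zone_table Zone table.
#' @param side Baseline stratum (default `"above_optimal"`).
#' @param config A [validate_config()] list.
#' @return A list: `labels` (tibble subject_id, responder, basis),
#'   `baseline` and `change` (GroupComparison tibbles), `monthly` (tibble
#'   group, month, metric columns), `diagnostic` (NULL or string).
#' @export
responder_characterization <- function(dataset, marker_id,
                                       zone_table = demo_zone_table(),
                                       side = c("above_optimal", "below_optimal"),
                                       config = validate_config()) {
  side <- match.arg(side)
  want <- if (side == "above_optimal") "above" else "below"
  pairs <- pair_draws(dataset, marker_id, min_gap_days = config$min_gap_days,
                      zone_table = zone_table)
  pairs <- pairs[zone_side(pairs$zone1) == want, ]
  covered <- intersect(pairs$subject_id, unique(dataset$wearables$subject_id))
  pairs <- pairs[pairs$subject_id %in% covered, ]
  if (nrow(pairs) == 0) {
    return(list(labels = tibble::tibble(), baseline = tibble::tibble(),
                change = tibble::tibble(), monthly = tibble::tibble(),
                diagnostic = "no wearable-covered out-of-range pairs"))
  }
  subj <- dataset$subjects
  labels <- vector("list", nrow(pairs))
  base_means <- vector("list", nrow(pairs))
  change_means <- vector("list", nrow(pairs))
  monthly_rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$subject_id[i]
    spec <- resolve_zone_spec(marker_id, subj[subj$subject_id == sid, ], zone_table)
    lab <- label_responder(pairs$x1[i], pairs$x2[i], spec,
                           pct = config$responder_pct)
    labels[[i]] <- tibble::tibble(subject_id = sid, marker_id = marker_id,
                                  responder = lab$responder, basis = lab$basis)
    w <- dataset$wearables[dataset$wearables$subject_id == sid, ]
    bw <- attach_wearable_window(pairs$date1[i], w,
                                 window_days = config$responder_baseline_window_days)
    # between tests: days strictly between the two draw dates
    bt <- window_mean(w, pairs$date1[i] + 1, pairs$date2[i])
    base_means[[i]] <- stats::setNames(bw$mean, bw$metric)
    change_means[[i]] <- stats::setNames(bt$mean - bw$mean, bw$metric)
    ms <- monthly_series(w, pairs$date1[i], months = 12)
    ms$subject_id <- sid
    monthly_rows[[i]] <- ms
  }
  labels <- dplyr::bind_rows(labels)
  base_mat <- do.call(rbind, base_means)
  change_mat <- do.call(rbind, change_means)
  resp <- labels$responder

  run_comparisons <- function(mat) {
    rows <- lapply(wearable_metrics(), function(m) {
      a <- mat[resp, m]
      b <- mat[!resp, m]
      if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) return(NULL)
      compare_groups(a, b, alpha = config$alpha_wearable, metric = m)
    })
    dplyr::bind_rows(rows)
  }
  monthly <- dplyr::bind_rows(monthly_rows)
  monthly$group <- ifelse(monthly$subject_id %in% labels$subject_id[resp],
                          "responder", "nonresponder")
  monthly_avg <- monthly |>
    dplyr::group_by(.data$group, .data$month) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(wearable_metrics()),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  diagnostic <- if (sum(resp) == 0) "no wearable-covered responders" else NULL
  list(labels = labels, baseline = run_comparisons(base_mat),
       change = run_comparisons(change_mat), monthly = monthly_avg,
       diagnostic = diagnostic)
}
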