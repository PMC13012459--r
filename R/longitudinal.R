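#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test for paired samples, the primary test for
#' baseline-to-follow-up change. Zero differences are dropped before
#' ranking; tied absolute differences receive mid-ranks. For up to
#' `exact_limit` non-zero pairs the p-value comes from the exact null
#' distribution of the positive-rank sum (computed by dynamic programming,
#' valid under mid-ranks); beyond that a normal approximation with tie
#' correction is used, without continuity correction.
#'
#' @param x1,x2 Equal-length numeric vectors (baseline, follow-up).
#' @param exact_limit Largest number of non-zero pairs for which the exact
#'   distribution is used (default 25).
#' @return A list: `statistic` (positive-rank sum V), `p_value` (two-sided),
#'   `n_used` (non-zero pairs), `method` ("exact" or "normal"), `degenerate`
#'   (TRUE when every pair is tied, in which case p = 1).
#' @examples
#' paired_signed_rank_test(c(1, 2, 3, 4), c(2, 3, 4, 6))
#' @export
paired_signed_rank_test <- function(x1, x2, exact_limit = 25) {
  if (length(x1) != length(x2) || length(x1) < 1) {
    stop_biotraj("input_error", "x1 and x2 must be equal-length, non-empty")
  }
  d <- x2 - x1
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = v, p_value = p, n_used = n, method = method,
       degenerate = FALSE)
}

# Exact two-sided p for the positive-rank sum under random sign flips.
# Ranks (possibly mid-ranks) are doubled to integers; the distribution of
# the doubled positive-rank sum is built by convolution over pairs.
signed_rank_exact_p <- function(ranks, v) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  counts <- numeric(total + 1)  # index i holds count of doubled-sum == i - 1
  counts[1] <- 1
  for (si in s) {
    shifted <- c(rep(0, si), counts[seq_len(total + 1 - si)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(s)
  w <- round(2 * v)
  p_le <- sum(probs[seq_len(w + 1)])
  p_ge <- sum(probs[seq.int(w + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test (unpaired comparator)
#'
#' Thin wrapper over [stats::wilcox.test()] on two independent samples,
#' provided alongside the paired signed-rank test so both can be reported
#' for the same contrast.
#'
#' @param x,y Numeric samples.
#' @return A list: `statistic` (U), `p_value`.
#' @export
mann_whitney_u_test <- function(x, y) {
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Summarize baseline-to-follow-up improvement for one marker and side
#'
#' Medians and inter-quartile ranges at both draws, percent of users who
#' improved by at least one zone toward optimal, percent who reached the
#' optimal zone at follow-up, and the paired signed-rank p-value. Summaries
#' from cohorts smaller than `min_cohort` out-of-range pairs are flagged as
#' suppressed (computed but not to be reported).
#'
#' @param pairs Paired observations carrying `x1`, `x2`, `zone1`, `zone2`
#'   (see [pair_draws()] with a zone table).
#' @param side `"above_optimal"` or `"below_optimal"`; every baseline zone
#'   must be out-of-optimal on this side.
#' @param min_cohort Minimum out-of-range pairs for an unsuppressed summary.
#' @return A one-row tibble: `marker_id`, `stratum`, `n_pairs`, `median1`,
#'   `iqr1`, `median2`, `iqr2`, `pct_improved`, `pct_optimized`,
#'   `test_statistic`, `p_value`, `suppressed`.
#' @export
summarize_baseline_followup <- function(pairs, side = c("above_optimal", "below_optimal"),
                                        min_cohort = 200) {
  side <- match.arg(side)
  stopifnot(all(c("x1", "x2", "zone1", "zone2") %in% names(pairs)))
  if (nrow(pairs) == 0) stop_biotraj("input_error", "no pairs supplied")
  want <- if (side == "above_optimal") "above" else "below"
  sides <- zone_side(pairs$zone1)
  if (any(sides == "at")) {
    stop_biotraj("input_error", "baseline zones must be out-of-optimal")
  }
  if (!all(sides == want)) {
    stop_biotraj("input_error", "pairs mix baseline sides; split by side first")
  }
  d1 <- zone_distance(pairs$zone1)
  d2 <- zone_distance(pairs$zone2)
  test <- paired_signed_rank_test(pairs$x1, pairs$x2)
  marker <- if ("marker_id" %in% names(pairs) && nrow(pairs) > 0)
    pairs$marker_id[1] else NA_character_
  tibble::tibble(
    marker_id = marker,
    stratum = side,
    n_pairs = nrow(pairs),
    median1 = stats::median(pairs$x1),
    iqr1 = stats::IQR(pairs$x1, type = 7),
    median2 = stats::median(pairs$x2),
    iqr2 = stats::IQR(pairs$x2, type = 7),
    pct_improved = 100 * mean(d2 < d1),
    pct_optimized = 100 * mean(d2 == 0),
    test_statistic = test$statistic,
    p_value = test$p_value,
    suppressed = nrow(pairs) < min_cohort
  )
}

#' Per-draw trajectory summary of a matched panel
#'
#' Per-draw means, standard errors and n, with paired signed-rank tests of
#' each later draw against draw 1 and (from draw 3 on) against draw 2, and
#' significance flags at `alpha`. One asterisk-equivalent flag
#' (`sig_vs_draw1`) marks a draw different from baseline; `sig_vs_both`
#' additionally requires difference from the first follow-up draw.
#'
#' @param panel A [build_matched_panel()] result, or a complete numeric
#'   matrix (subjects x draws).
#' @param alpha Significance level for the flags.
#' @return A tibble with one row per draw: `draw`, `mean`, `se`, `n`,
#'   `p_vs_draw1`, `p_vs_draw2`, `sig_vs_draw1`, `sig_vs_both`.
#' @export
trajectory_analysis <- function(panel, alpha = 0.05) {
  values <- if (inherits(panel, "matched_panel")) panel$values else as.matrix(panel)
  if (ncol(values) < 2) stop_biotraj("input_error", "panel needs at least 2 draws")
  if (anyNA(values)) stop_biotraj("input_error", "panel must be complete (no NA)")
  k <- ncol(values)
  n <- nrow(values)
  means <- colMeans(values)
  ses <- apply(values, 2, stats::sd) / sqrt(n)
  p1 <- rep(NA_real_, k)
  p2 <- rep(NA_real_, k)
  for (j in 2:k) {
    p1[j] <- paired_signed_rank_test(values[, 1], values[, j])$p_value
    if (j >= 3) p2[j] <- paired_signed_rank_test(values[, 2], values[, j])$p_value
  }
  tibble::tibble(
    draw = seq_len(k), mean = means, se = ses, n = n,
    p_vs_draw1 = p1, p_vs_draw2 = p2,
    sig_vs_draw1 = !is.na(p1) & p1 <= alpha,
    sig_vs_both = !is.na(p1) & p1 <= alpha & !is.na(p2) & p2 <= alpha
  )
}

#' Expected regression-to-the-mean change for an individual
#'
#' For a baseline value `x1` drawn from a reference population with mean
#' `mu` and test-retest correlation `rho` between draws, the expected change
#' attributable purely to regression to the mean is
#' `(1 - rho) * (mu - x1)`: zero under perfect test-retest correlation, the
#' full distance to the mean under none.
#'
#' @param x1 Baseline value(s).
#' @param mu Reference-population baseline mean.
#' @param rho Test-retest correlation in \[-1, 1\].
#' @return Expected RTM-attributable change, same length as `x1`.
#' @examples
#' expected_rtm_individual(150, mu = 100, rho = 0.6)  # -20
#' @export
expected_rtm_individual <- function(x1, mu, rho) {
  if (!is.finite(rho) || rho < -1 || rho > 1) {
    stop_biotraj("input_error", "rho must lie in [-1, 1]")
  }
  (1 - rho) * (mu - x1)
}

#' Cohort-level regression-to-the-mean estimate for one marker
#'
#' Estimates the reference-population baseline mean `mu` and the draw-1 to
#' draw-2 test-retest correlation `rho` from *all* paired users of the
#' marker (not only out-of-range ones, which would bias `rho`), then
#' averages [expected_rtm_individual()] over the analysis subcohort — the
#' out-of-range users actually followed longitudinally.
#'
#' @param reference_pairs Tibble with columns `x1`, `x2`: all baseline /
#'   first-follow-up pairs for the marker.
#' @param subcohort_x1 Baseline values of the analysis subcohort over which
#'   the expected RTM change is averaged. Defaults to the full reference
#'   population.
#' @param marker_id Optional marker id carried through.
#' @return A list of class `rtm_estimate`: `marker_id`, `mu`, `rho`,
#'   `mean_delta_rtm`, `n_reference`, `n_subcohort`, `degenerate`.
#' @export
estimate_rtm_cohort <- function(reference_pairs, subcohort_x1 = NULL,
                                marker_id = NA_character_) {
  stopifnot(all(c("x1", "x2") %in% names(reference_pairs)))
  ok <- is.finite(reference_pairs$x1) & is.finite(reference_pairs$x2)
  ref <- reference_pairs[ok, ]
  if (nrow(ref) < 10) {
    stop_biotraj("input_error", "reference population needs at least 10 pairs")
  }
  if (is.null(subcohort_x1)) subcohort_x1 <- ref$x1
  mu <- mean(ref$x1)
  degenerate <- stats::sd(ref$x1) == 0 || stats::sd(ref$x2) == 0
  rho <- if (degenerate) NA_real_ else stats::cor(ref$x1, ref$x2)
  mean_delta <- if (degenerate) NA_real_ else
    mean(expected_rtm_individual(subcohort_x1, mu, rho))
  structure(list(marker_id = marker_id, mu = mu, rho = rho,
                 mean_delta_rtm = mean_delta,
                 n_reference = nrow(ref), n_subcohort = length(subcohort_x1),
                 degenerate = degenerate),
            class = "rtm_estimate")
}

#' @export
print.rtm_estimate <- function(x, ...) {
  cat(sprintf("<rtm_estimate %s: mu=%.4g rho=%.4g mean_delta_rtm=%.4g (n_ref=%d, n_sub=%d)>\n",
              x$marker_id, x$mu, x$rho, x$mean_delta_rtm,
              x$n_reference, x$n_subcohort))
  invisible(x)
}

#' Natural-history comparator: trajectories of optimal-at-baseline users
#'
#' Users whose baseline value sits in the optimal zone received no
#' biomarker-targeted guidance; their long-term trajectory provides
#' natural-history context for the out-of-range trajectories. The same
#' matched-panel and trajectory machinery is applied to that subcohort.
#'
#' @inheritParams build_matched_panel
#' @return A list: `panel` (matrix, may have zero rows) and `trajectory`
#'   (tibble, empty when no subjects qualify).
#' @export
natural_history_comparator <- function(dataset, marker_id, zone_table = demo_zone_table(),
                                       n_draws = 5, min_gap_days = 90, alpha = 0.05) {
  values <- collect_panel_values(dataset, marker_id, want_side = "at",
                                 n_draws = n_draws, zone_table = zone_table,
                                 min_gap_days = min_gap_days)
  trajectory <- if (nrow(values) == 0) tibble::tibble() else
    trajectory_analysis(values, alpha = alpha)
  list(panel = values, trajectory = trajectory)
}

# Shared greedy panel collection; want_side in {"above","below","at"}.
collect_panel_values <- function(dataset, marker_id, want_side, n_draws,
                                 zone_table, min_gap_days) {
  draws <- dataset$draws
  md <- draws[draws$marker_id == marker_id & is.finite(draws$value), ]
  md <- md[order(md$subject_id, md$draw_date), ]
  subj <- dataset$subjects
  rows <- list()
  for (sid in unique(md$subject_id)) {
    g <- md[md$subject_id == sid, ]
    if (nrow(g) < n_draws) next
    spec <- resolve_zone_spec(marker_id, subj[subj$subject_id == sid, ], zone_table)
    if (zone_side(classify_zone(g$value[1], spec)) != want_side) next
    keep <- 1L
    last <- g$draw_date[1]
    i <- 2L
    while (length(keep) < n_draws && i <= nrow(g)) {
      if (as.numeric(g$draw_date[i] - last) >= min_gap_days) {
        keep <- c(keep, i)
        last <- g$draw_date[i]
      }
      i <- i + 1L
    }
    if (length(keep) == n_draws) rows[[sid]] <- g$value[keep]
  }
  values <- if (length(rows) > 0) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = n_draws)
  rownames(values) <- names(rows)
  colnames(values) <- paste0("draw", seq_len(n_draws))
  values
}

#' Cross-sectional age profile of baseline levels
#'
#' Bins subjects' earliest draw of a marker into fixed-width age bins
#' starting at 18 ( \[18, 23), \[23, 28), ... for the 5-year default) and
#' reports mean, standard error and n per bin; bins with fewer than `min_n`
#' subjects are suppressed.
#'
#' @param dataset A `biotraj_dataset`.
#' @param marker_id Marker.
#' @param bin_width_years Bin width (default 5).
#' @param min_n Minimum subjects for a reported bin.
#' @return A tibble: `age_lo`, `age_hi`, `mean`, `se`, `n`.
#' @export
age_cross_section <- function(dataset, marker_id, bin_width_years = 5, min_n = 5) {
  draws <- dataset$draws
  md <- draws[draws$marker_id == marker_id & is.finite(draws$value), ]
  md <- md[order(md$subject_id, md$draw_date), ]
  baseline <- md[!duplicated(md$subject_id), ]
  idx <- match(baseline$subject_id, dataset$subjects$subject_id)
  age <- dataset$subjects$age[idx]
  bin <- floor((age - 18) / bin_width_years)
  out <- tibble::tibble(bin = bin, value = baseline$value) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n >= min_n) |>
    dplyr::arrange(.data$bin)
  tibble::tibble(age_lo = 18 + out$bin * bin_width_years,
                 age_hi = 18 + (out$bin + 1) * bin_width_years,
                 mean = out$mean, se = out$se, n = out$n)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment by default, applied across markers
#' within one analysis family; raw p-values should always be reported
#' alongside.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_biotraj("input_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}
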