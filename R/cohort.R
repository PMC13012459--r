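#' Apply the longitudinal inclusion filter
#'
#' A subject is eligible when they have at least two draws whose dates are
#' at least `min_gap_days` apart (equivalently, the span between their first
#' and last draw reaches the gap). The marker measured does not matter at
#' this stage; marker-level pairing happens in [pair_draws()].
#'
#' @param dataset A `biotraj_dataset` (or a draws tibble).
#' @param min_gap_days Minimum baseline-to-follow-up interval in whole days
#'   (inclusive).
#' @return Character vector of eligible subject ids, sorted.
#' @export
filter_inclusion <- function(dataset, min_gap_days = 90) {
  draws <- if (inherits(dataset, "biotraj_dataset")) dataset$draws else dataset
  if (nrow(draws) == 0) return(character(0))
  span <- tapply(as.numeric(draws$draw_date), draws$subject_id,
                 function(d) if (length(d) < 2) 0 else diff(range(d)))
  sort(names(span)[span >= min_gap_days])
}

#' Remove outliers with inter-quartile-range fences
#'
#' Fences are computed once from the input series: values strictly below
#' `Q1 - k * IQR` or strictly above `Q3 + k * IQR` are removed in a single
#' pass. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Series with fewer than four finite values are
#' returned unchanged with a note.
#'
#' @param values Numeric series.
#' @param k Fence multiplier (default 2; `Inf` disables removal).
#' @return A list with `values` (retained), `removed_idx` (positions in the
#'   input), `fences` (named numeric), and `note` (NULL or a string).
#' @export
remove_outliers_iqr <- function(values, k = 2) {
  finite <- is.finite(values)
  if (sum(finite) < 4) {
    return(list(values = values, removed_idx = integer(0),
                fences = c(lower = -Inf, upper = Inf),
                note = "fewer than 4 finite values; series returned unchanged"))
  }
  q <- stats::quantile(values[finite], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  # k = Inf gives fences (-Inf, Inf) unless iqr is 0, where 0 * Inf is NaN.
  if (is.nan(lower)) lower <- -Inf
  if (is.nan(upper)) upper <- Inf
  out <- which(finite & (values < lower | values > upper))
  keep <- if (length(out) > 0) values[-out] else values
  list(values = keep, removed_idx = out,
       fences = c(lower = lower, upper = upper), note = NULL)
}

#' Remove per-marker outliers across the whole cohort
#'
#' Fences are computed per marker over all draw values for that marker in a
#' single pass, and flagged rows are dropped from the draws table.
#'
#' @param dataset A `biotraj_dataset`.
#' @param k Fence multiplier.
#' @return A list with `dataset` (draws filtered) and `report` (one row per
#'   removed draw: subject_id, draw_date, marker_id, value, lower, upper).
#' @export
remove_draw_outliers <- function(dataset, k = 2) {
  draws <- dataset$draws
  drop <- rep(FALSE, nrow(draws))
  report <- list()
  for (m in unique(draws$marker_id)) {
    idx <- which(draws$marker_id == m)
    res <- remove_outliers_iqr(draws$value[idx], k = k)
    if (length(res$removed_idx) > 0) {
      rows <- idx[res$removed_idx]
      drop[rows] <- TRUE
      rep_m <- draws[rows, ]
      rep_m$lower <- res$fences[["lower"]]
      rep_m$upper <- res$fences[["upper"]]
      report[[m]] <- rep_m
    }
  }
  dataset$draws <- draws[!drop, ]
  report <- if (length(report) > 0) dplyr::bind_rows(report) else
    tibble::tibble(subject_id = character(0), draw_date = as.Date(character(0)),
                   marker_id = character(0), value = numeric(0),
                   lower = numeric(0), upper = numeric(0))
  list(dataset = dataset, report = report)
}

#' Pair baseline and follow-up draws for one marker
#'
#' Baseline is the earliest draw measuring the marker; follow-up is the
#' earliest subsequent draw at least `min_gap_days` later that also measures
#' it. Subjects without a qualifying follow-up are omitted.
#'
#' @param dataset A `biotraj_dataset` (or draws tibble).
#' @param marker_id Marker to pair.
#' @param min_gap_days Minimum interval in days (inclusive).
#' @param zone_table Optional zone table; when supplied, baseline and
#'   follow-up zone labels are attached per subject stratum.
#' @return A tibble of paired observations: `subject_id`, `marker_id`,
#'   `date1`, `date2`, `x1`, `x2`, `interval_days`, and (with a zone table)
#'   `zone1`, `zone2`.
#' @export
pair_draws <- function(dataset, marker_id, min_gap_days = 90, zone_table = NULL) {
  draws <- if (inherits(dataset, "biotraj_dataset")) dataset$draws else dataset
  md <- draws[draws$marker_id == marker_id & is.finite(draws$value), ]
  if (nrow(md) == 0) {
    return(empty_pairs(marker_id, with_zones = !is.null(zone_table)))
  }
  md <- md[order(md$subject_id, md$draw_date), ]
  pairs <- md |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(g, key) {
      d1 <- g$draw_date[1]
      gap <- as.numeric(g$draw_date - d1)
      j <- which(gap >= min_gap_days)
      if (length(j) == 0) return(tibble::tibble())
      j <- j[1]
      tibble::tibble(marker_id = marker_id, date1 = d1, date2 = g$draw_date[j],
                     x1 = g$value[1], x2 = g$value[j],
                     interval_days = as.integer(gap[j]))
    }) |>
    dplyr::ungroup()
  if (nrow(pairs) == 0) {
    return(empty_pairs(marker_id, with_zones = !is.null(zone_table)))
  }
  if (!is.null(zone_table)) {
    pairs <- attach_zones(pairs, dataset, zone_table)
  }
  pairs
}

empty_pairs <- function(marker_id, with_zones = FALSE) {
  out <- tibble::tibble(subject_id = character(0), marker_id = character(0),
                        date1 = as.Date(character(0)), date2 = as.Date(character(0)),
                        x1 = numeric(0), x2 = numeric(0), interval_days = integer(0))
  if (with_zones) {
    out$zone1 <- character(0)
    out$zone2 <- character(0)
  }
  out
}

attach_zones <- function(pairs, dataset, zone_table) {
  stopifnot(inherits(dataset, "biotraj_dataset"))
  subj <- dataset$subjects
  idx <- match(pairs$subject_id, subj$subject_id)
  z1 <- character(nrow(pairs))
  z2 <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    spec <- resolve_zone_spec(pairs$marker_id[i], subj[idx[i], ], zone_table)
    z1[i] <- classify_zone(pairs$x1[i], spec)
    z2[i] <- classify_zone(pairs$x2[i], spec)
  }
  pairs$zone1 <- z1
  pairs$zone2 <- z2
  pairs
}

#' Build a matched multi-draw panel for one marker
#'
#' Restricts to subjects whose baseline zone is out-of-optimal on the stated
#' side and who have at least `n_draws` qualifying draws of the marker, with
#' every successive retained draw at least `min_gap_days` after the previous
#' retained one (greedy forward selection from baseline). Exactly the first
#' `n_draws` qualifying draws per subject enter the panel, so the same users
#' contribute to every draw column.
#'
#' @param dataset A `biotraj_dataset`.
#' @param marker_id Marker.
#' @param side `"above_optimal"` or `"below_optimal"` baseline stratum.
#' @param n_draws Number of draws per subject (>= 2).
#' @param zone_table Zone table for baseline classification.
#' @param min_gap_days Minimum gap between successive retained draws.
#' @param min_subjects Below this panel size a warning is emitted (not an
#'   error).
#' @return A list of class `matched_panel`: `marker_id`, `side`, `subjects`,
#'   and `values`, an n_subjects x n_draws matrix with no missing cells.
#' @export
build_matched_panel <- function(dataset, marker_id, side = c("above_optimal", "below_optimal"),
                                n_draws = 5, zone_table = demo_zone_table(),
                                min_gap_days = 90, min_subjects = 10) {
  side <- match.arg(side)
  stopifnot(n_draws >= 2)
  want_side <- if (side == "above_optimal") "above" else "below"
  values <- collect_panel_values(dataset, marker_id, want_side = want_side,
                                 n_draws = n_draws, zone_table = zone_table,
                                 min_gap_days = min_gap_days)
  if (nrow(values) < min_subjects) {
    warning(sprintf("matched panel for %s (%s) has only %d subjects",
                    marker_id, side, nrow(values)), call. = FALSE)
  }
  structure(list(marker_id = marker_id, side = side,
                 subjects = rownames(values), values = values),
            class = "matched_panel")
}

#' @export
print.matched_panel <- function(x, ...) {
  cat(sprintf("<matched_panel %s, %s: %d subjects x %d draws>\n",
              x$marker_id, x$side, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Average wearable metrics over a window before a draw
#'
#' For each metric, the mean over days in `[draw_date - window_days,
#' draw_date)` with at least one observation; `coverage` counts the
#' contributing days per metric. Zero coverage yields NA, not an error.
#'
#' @param draw_date Date of the blood draw.
#' @param wearables Wearable-day rows for one subject.
#' @param window_days Positive window length in days.
#' @return A tibble with one row per metric: `metric`, `mean`, `coverage`.
#' @export
attach_wearable_window <- function(draw_date, wearables, window_days = 90) {
  stopifnot(window_days > 0)
  window_mean(wearables, draw_date - window_days, draw_date)
}

# Mean per metric over [from, to) (dates), with coverage counts.
window_mean <- function(wearables, from, to) {
  sel <- wearables[wearables$date >= from & wearables$date < to, , drop = FALSE]
  metrics <- wearable_metrics()
  means <- vapply(metrics, function(m) {
    v <- sel[[m]]
    if (sum(!is.na(v)) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  coverage <- vapply(metrics, function(m) sum(!is.na(sel[[m]])), integer(1))
  tibble::tibble(metric = metrics, mean = unname(means),
                 coverage = unname(coverage))
}
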