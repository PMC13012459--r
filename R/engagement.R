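#' Form the Action-Plan engagement contrast cohorts for one marker
#'
#' The targeting cohort holds users with at least one Action Plan created
#' in the closed interval `[baseline, follow-up]` whose targeted markers
#' include the focal marker. The no-AP cohort holds users with zero Action
#' Plans of any kind in that window. Users with APs only for other markers
#' are excluded from the contrast, as are users missing a baseline or
#' follow-up zone.
#'
#' @param dataset A `biotraj_dataset`.
#' @param marker_id Focal marker.
#' @param pairs Paired observations for the marker carrying `zone1`,
#'   `zone2` (see [pair_draws()] with a zone table).
#' @return A list of subject-id vectors: `targeting`, `no_ap`, `excluded`.
#' @export
build_ap_contrast <- function(dataset, marker_id, pairs) {
  stopifnot(all(c("zone1", "zone2") %in% names(pairs)))
  ok <- !is.na(pairs$zone1) & !is.na(pairs$zone2)
  dropped_zone <- pairs$subject_id[!ok]
  pairs <- pairs[ok, ]
  ap <- dataset$action_plans
  targets <- split_targets(ap$targeted_markers)

  targeting <- character(0)
  no_ap <- character(0)
  excluded <- dropped_zone
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$subject_id[i]
    in_window <- ap$subject_id == sid &
      ap$created_date >= pairs$date1[i] & ap$created_date <= pairs$date2[i]
    if (!any(in_window)) {
      no_ap <- c(no_ap, sid)
    } else if (any(vapply(targets[in_window], function(v) marker_id %in% v,
                          logical(1)))) {
      targeting <- c(targeting, sid)
    } else {
      excluded <- c(excluded, sid)
    }
  }
  list(targeting = targeting, no_ap = no_ap, excluded = excluded)
}

#' Zone-shift contingency test for Action-Plan engagement
#'
#' Builds the 2x2 table (rows = AP-targeting vs no-AP cohort; columns =
#' improved >= 1 zone yes/no, with "improved" the same strict
#' distance-decrease rule used throughout) and applies Pearson's chi-squared
#' test without continuity correction. Results with any expected cell below
#' 1 are flagged but still reported. No causal reading is implied: the
#' contrast is associational.
#'
#' @param contrast A [build_ap_contrast()] result.
#' @param pairs Paired observations with `zone1`, `zone2` for the marker.
#' @param marker_id Marker id carried through.
#' @param stratum Baseline stratum label carried through
#'   (e.g. "high_at_baseline").
#' @return A one-row tibble: `marker_id`, `stratum`, counts
#'   `ap_improved`, `ap_not`, `noap_improved`, `noap_not`, `chi_squared`,
#'   `p_value`, `low_expected`, `n_excluded`.
#' @export
zone_shift_contingency <- function(contrast, pairs, marker_id = NA_character_,
                                   stratum = NA_character_) {
  if (length(contrast$targeting) == 0 || length(contrast$no_ap) == 0) {
    stop_biotraj("input_error", "both cohorts must be non-empty")
  }
  d1 <- zone_distance(pairs$zone1)
  d2 <- zone_distance(pairs$zone2)
  improved <- stats::setNames(d2 < d1, pairs$subject_id)
  tab <- rbind(
    ap = c(yes = sum(improved[contrast$targeting]),
           no = sum(!improved[contrast$targeting])),
    no_ap = c(yes = sum(improved[contrast$no_ap]),
              no = sum(!improved[contrast$no_ap]))
  )
  res <- chi_squared_2x2(tab)
  tibble::tibble(marker_id = marker_id, stratum = stratum,
                 ap_improved = tab["ap", "yes"], ap_not = tab["ap", "no"],
                 noap_improved = tab["no_ap", "yes"], noap_not = tab["no_ap", "no"],
                 chi_squared = res$statistic, p_value = res$p_value,
                 low_expected = res$low_expected,
                 n_excluded = length(contrast$excluded))
}

#' Pearson chi-squared test on a 2x2 table, no continuity correction
#'
#' @param tab A 2x2 count matrix.
#' @return A list: `statistic`, `p_value`, `low_expected` (TRUE when any
#'   expected cell is below 1).
#' @export
chi_squared_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       low_expected = any(expected < 1))
}

#' Run the engagement contrast across markers with multiple-testing control
#'
#' One contingency test per marker and baseline stratum, with
#' Benjamini-Hochberg adjustment across markers within each stratum family.
#'
#' @param dataset A `biotraj_dataset`.
#' @param marker_ids Markers to test.
#' @param zone_table Zone table.
#' @param min_gap_days Pairing gap.
#' @return A tibble of [zone_shift_contingency()] rows plus `p_adjusted`.
#' @export
engagement_analysis <- function(dataset, marker_ids,
                                zone_table = demo_zone_table(),
                                min_gap_days = 90) {
  rows <- list()
  for (m in marker_ids) {
    pairs <- pair_draws(dataset, m, min_gap_days = min_gap_days,
                        zone_table = zone_table)
    for (stratum in c("high_at_baseline", "low_at_baseline")) {
      want <- if (stratum == "high_at_baseline") "above" else "below"
      sub <- pairs[zone_side(pairs$zone1) == want, ]
      if (nrow(sub) == 0) next
      contrast <- build_ap_contrast(dataset, m, sub)
      if (length(contrast$targeting) == 0 || length(contrast$no_ap) == 0) next
      rows[[paste(m, stratum)]] <-
        zone_shift_contingency(contrast, sub, marker_id = m, stratum = stratum)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out |>
      dplyr::group_by(.data$stratum) |>
      dplyr::mutate(p_adjusted = adjust_pvalues(.data$p_value)) |>
      dplyr::ungroup()
  }
  out
}
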