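#' @keywords internal
zone_levels <- function() c("low", "normal_low", "optimal", "normal_high", "high")

#' Ordinal distance of a zone label from the optimal zone
#'
#' Distances are 2 (low, high), 1 (normal_low, normal_high) and 0 (optimal).
#'
#' @param label Character vector of zone labels.
#' @return Integer vector of distances in {0, 1, 2}.
#' @export
zone_distance <- function(label) {
  map <- c(low = 2L, normal_low = 1L, optimal = 0L, normal_high = 1L, high = 2L)
  unname(map[label])
}

#' Side of the optimal zone a label falls on
#' @param label Character vector of zone labels.
#' @return Character vector in {"below", "at", "above"}.
#' @export
zone_side <- function(label) {
  map <- c(low = "below", normal_low = "below", optimal = "at",
           normal_high = "above", high = "above")
  unname(map[label])
}

#' Construct a reference-zone specification
#'
#' Four cut-points partition the real line into five ordinal zones:
#' low = (-Inf, c1), normal_low = \[c1, c2), optimal = \[c2, c3),
#' normal_high = \[c3, c4), high = \[c4, Inf). All intervals are
#' lower-inclusive / upper-exclusive. One-sided markers set c1 = c2 = -Inf
#' (no below-optimal zones) and/or c3 = c4 = Inf.
#'
#' @param c1,c2,c3,c4 Cut-points with c1 <= c2 < c3 <= c4 (c2 < c3 keeps the
#'   optimal zone non-empty); infinities permitted at the ends.
#' @param marker_id Optional marker id carried for provenance.
#' @return A list of class `zone_spec`.
#' @export
zone_spec <- function(c1, c2, c3, c4, marker_id = NA_character_) {
  cuts <- c(c1, c2, c3, c4)
  if (any(is.na(cuts))) stop_biotraj("zone_error", "zone cut-points must not be NA")
  if (!(c1 <= c2 && c2 < c3 && c3 <= c4)) {
    stop_biotraj("zone_error",
                 "zone cut-points must satisfy c1 <= c2 < c3 <= c4, got: ",
                 paste(cuts, collapse = ", "))
  }
  finite <- cuts[is.finite(cuts)]
  if (anyDuplicated(finite)) {
    stop_biotraj("zone_error", "finite zone cut-points must be strictly ordered")
  }
  structure(list(marker_id = marker_id, c1 = c1, c2 = c2, c3 = c3, c4 = c4),
            class = "zone_spec")
}

#' @export
print.zone_spec <- function(x, ...) {
  cat(sprintf("<zone_spec %s: (%s | %s | %s | %s)>\n",
              x$marker_id, x$c1, x$c2, x$c3, x$c4))
  invisible(x)
}

#' Resolve the reference-zone stratum for a subject
#'
#' Zone tables carry one row per (marker, stratum); strata are defined by
#' any combination of sex, an age interval, and optionally ethnicity, with
#' empty cells meaning "any". The most specific matching row wins:
#' ethnicity+age+sex over age+sex over sex over the default row. Ties at
#' equal specificity go to the first matching row, deterministically.
#'
#' @param marker_id Marker to resolve.
#' @param subject A one-row data frame (or list) with `sex`, `age`, and
#'   optionally `ethnicity`.
#' @param zone_table Data frame with columns `marker_id`, `sex`, `age_min`,
#'   `age_max`, `ethnicity`, `c1`, `c2`, `c3`, `c4`; NA means "any" for the
#'   stratum columns and +/-Inf for the outer cut-points. Age intervals are
#'   closed below, open above: `age_min <= age < age_max`.
#' @return A `zone_spec`.
#' @export
resolve_zone_spec <- function(marker_id, subject, zone_table) {
  rows <- zone_table[zone_table$marker_id == marker_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_biotraj("missing_spec_error", "no zone strata for marker '", marker_id, "'")
  }
  age <- subject$age
  sex <- subject$sex
  eth <- if (!is.null(subject$ethnicity)) subject$ethnicity else NA_character_

  sex_spec <- !is.na(rows$sex)
  age_spec <- !is.na(rows$age_min) | !is.na(rows$age_max)
  eth_spec <- !is.na(rows$ethnicity)
  lo <- ifelse(is.na(rows$age_min), -Inf, rows$age_min)
  hi <- ifelse(is.na(rows$age_max), Inf, rows$age_max)

  match_ok <- (!sex_spec | rows$sex == sex) &
    (age >= lo & age < hi) &
    (!eth_spec | (!is.na(eth) & rows$ethnicity == eth))
  if (!any(match_ok)) {
    stop_biotraj("missing_spec_error",
                 sprintf("no zone stratum for marker '%s' matching sex=%s age=%s ethnicity=%s",
                         marker_id, sex, age, eth))
  }
  specificity <- 4L * eth_spec + 2L * age_spec + 1L * sex_spec
  specificity[!match_ok] <- -1L
  best <- which.max(specificity)
  row <- rows[best, ]
  zone_spec(ifelse(is.na(row$c1), -Inf, row$c1),
            ifelse(is.na(row$c2), -Inf, row$c2),
            ifelse(is.na(row$c3), Inf, row$c3),
            ifelse(is.na(row$c4), Inf, row$c4),
            marker_id = marker_id)
}

#' Classify biomarker values into the five ordinal zones
#'
#' @param value Numeric vector of finite marker values.
#' @param spec A [zone_spec()].
#' @return Character vector of zone labels.
#' @examples
#' spec <- zone_spec(40, 50, 71, 91)
#' classify_zone(c(35, 45, 50, 80, 95), spec)
#' @export
classify_zone <- function(value, spec) {
  stopifnot(inherits(spec, "zone_spec"))
  if (any(!is.finite(value))) {
    stop_biotraj("input_error", "classify_zone requires finite values")
  }
  cuts <- c(spec$c1, spec$c2, spec$c3, spec$c4)
  # number of cut-points at or below the value; -Inf cuts always count,
  # +Inf cuts never do, which collapses the degenerate one-sided zones.
  idx <- vapply(value, function(v) sum(v >= cuts), integer(1))
  zone_levels()[idx + 1L]
}

#' Score a baseline-to-follow-up zone transition
#'
#' "Improved" means the follow-up zone is strictly closer to optimal than
#' the baseline zone (a crossing to an equally bad opposite zone does not
#' count); "optimized" means the follow-up value lands in the optimal zone.
#' Callers must filter to out-of-optimal baselines first.
#'
#' @param x1,x2 Baseline and follow-up values (finite scalars or equal-length
#'   vectors).
#' @param spec A [zone_spec()].
#' @return A tibble with columns `zone1`, `zone2`, `improved`, `optimized`.
#' @export
score_transition <- function(x1, x2, spec) {
  zone1 <- classify_zone(x1, spec)
  zone2 <- classify_zone(x2, spec)
  d1 <- zone_distance(zone1)
  d2 <- zone_distance(zone2)
  if (any(d1 == 0)) {
    stop_biotraj("precondition_error",
                 "score_transition requires out-of-optimal baselines; filter first")
  }
  tibble::tibble(zone1 = zone1, zone2 = zone2,
                 improved = d2 < d1, optimized = d2 == 0L)
}

#' Read a zone table from CSV
#'
#' The file mirrors the structure of a published optimal-range table:
#' `marker_id,sex,age_min,age_max,ethnicity,c1,c2,c3,c4` with empty cells
#' meaning "any" (stratum columns) or infinite (outer cut-points).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_zone_table <- function(path) {
  zt <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          marker_id = readr::col_character(),
                          sex = readr::col_character(),
                          ethnicity = readr::col_character(),
                          .default = readr::col_double()
                        ))
  require_columns(zt, c("marker_id", "sex", "age_min", "age_max", "ethnicity",
                        "c1", "c2", "c3", "c4"), "zone table")
  zt
}

#' Demonstration zone table for the registry markers
#'
#' Cut-points follow conventional US clinical reference and optimal ranges
#' for each marker; LDL and total cholesterol are one-sided (no below-optimal
#' zones), vitamin D and HDL carry no above-optimal penalty, glucose and
#' ferritin are two-sided. Ferritin and HDL strata differ by sex.
#'
#' @return A tibble suitable for [resolve_zone_spec()].
#' @export
demo_zone_table <- function() {
  tibble::tribble(
    ~marker_id,          ~sex,     ~age_min, ~age_max, ~ethnicity, ~c1, ~c2, ~c3, ~c4,
    "ldl",               NA,       NA,       NA,       NA,         NA,  NA,  100, 130,
    "total_cholesterol", NA,       NA,       NA,       NA,         NA,  NA,  200, 240,
    "fasting_glucose",   NA,       NA,       NA,       NA,         65,  75,  90,  100,
    "vitamin_d",         NA,       NA,       NA,       NA,         20,  30,  NA,  NA,
    "ferritin",          "female", NA,       NA,       NA,         12,  30,  150, 200,
    "ferritin",          "male",   NA,       NA,       NA,         20,  50,  250, 300,
    "hdl",               "female", NA,       NA,       NA,         40,  50,  NA,  NA,
    "hdl",               "male",   NA,       NA,       NA,         35,  45,  NA,  NA
  )
}
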