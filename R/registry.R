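#' Build a marker registry
#'
#' The registry is the closed vocabulary of biomarkers a run knows about.
#' Every marker referenced by any input table must exist here. `direction`
#' states which way is healthier: `"lower_better"`, `"higher_better"`, or
#' `"interior_optimal"` (both tails unfavourable, e.g. fasting glucose).
#'
#' @param markers A data frame with columns `marker_id` (lower-snake token),
#'   `display`, `units`, `direction`, and logical `non_negative`.
#' @return A tibble of class `biotraj_registry`.
#' @examples
#' demo_registry()
#' @export
marker_registry <- function(markers) {
  markers <- tibble::as_tibble(markers)
  required <- c("marker_id", "display", "units", "direction", "non_negative")
  missing <- setdiff(required, names(markers))
  if (length(missing) > 0) {
    stop_biotraj("schema_error", "registry is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  bad_dir <- setdiff(unique(markers$direction),
                     c("lower_better", "higher_better", "interior_optimal"))
  if (length(bad_dir) > 0) {
    stop_biotraj("registry_error", "unknown direction(s): ",
                 paste(bad_dir, collapse = ", "))
  }
  if (anyDuplicated(markers$marker_id)) {
    stop_biotraj("registry_error", "duplicate marker_id in registry")
  }
  class(markers) <- c("biotraj_registry", class(markers))
  markers
}

#' Demonstration marker registry
#'
#' A small registry of clinically familiar markers used by the synthetic
#' cohort generator, the examples, and the test-suite. Units follow the
#' conventional US clinical-laboratory reporting units for each marker.
#'
#' @return A `biotraj_registry` tibble.
#' @export
demo_registry <- function() {
  marker_registry(tibble::tribble(
    ~marker_id,          ~display,                ~units,    ~direction,          ~non_negative,
    "ldl",               "LDL cholesterol",       "mg/dL",   "lower_better",      TRUE,
    "total_cholesterol", "Total cholesterol",     "mg/dL",   "lower_better",      TRUE,
    "fasting_glucose",   "Fasting glucose",       "mg/dL",   "interior_optimal",  TRUE,
    "vitamin_d",         "25-OH vitamin D",       "ng/mL",   "higher_better",     TRUE,
    "ferritin",          "Ferritin",              "ng/mL",   "interior_optimal",  TRUE,
    "hdl",               "HDL cholesterol",       "mg/dL",   "higher_better",     TRUE
  ))
}

#' Check that marker ids are registered
#' @param marker_ids Character vector of marker ids to check.
#' @param registry A `biotraj_registry`.
#' @return Invisibly `TRUE`; errors if any marker is unknown.
#' @keywords internal
assert_markers_known <- function(marker_ids, registry) {
  unknown <- setdiff(unique(marker_ids), registry$marker_id)
  if (length(unknown) > 0) {
    stop_biotraj("registry_error", "marker(s) absent from registry: ",
                 paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# Condition helper: all package errors carry a subclass so callers and the
# test-suite can distinguish schema, registry, config and input failures.
stop_biotraj <- function(class, ...) {
  rlang::abort(paste0(...), class = c(paste0("biotraj_", class), "biotraj_error"))
}
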