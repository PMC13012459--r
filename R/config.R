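#' Validate and normalize an analysis configuration
#'
#' Fills omitted keys with the study defaults and rejects contradictory
#' values. Defaults: a follow-up counts only when drawn at least 90 days
#' after baseline (`min_gap_days = 90`); outliers are fenced at two
#' inter-quartile ranges beyond the quartiles (`iqr_multiplier = 2`); a
#' 10% preferential change qualifies as a response (`responder_pct = 0.10`);
#' main analyses use `alpha_main = 0.05` while wearable contrasts use the
#' deliberately relaxed `alpha_wearable = 0.1`; polygenic-score strata are
#' the lowest 10%, middle 80% and top 10% (`strata = c(0.10, 0.80, 0.10)`);
#' improvement summaries require `min_cohort = 200` out-of-range users;
#' wearable windows are 90 days before a draw (`wearable_window_days`) and
#' 30 days before baseline for responder baselines
#' (`responder_baseline_window_days`).
#'
#' @param config A named list (possibly empty) of configuration overrides,
#'   or a path to a JSON/YAML file holding one.
#' @return A named list with every key filled, classed `biotraj_config`.
#' @examples
#' validate_config(list())$min_gap_days
#' validate_config(list(responder_pct = 0.15))$responder_pct
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_file(config)
  }
  if (!is.list(config)) {
    stop_biotraj("config_error", "config must be a named list or a file path")
  }
  defaults <- list(
    min_gap_days = 90,
    iqr_multiplier = 2,
    responder_pct = 0.10,
    alpha_main = 0.05,
    alpha_wearable = 0.1,
    strata = c(0.10, 0.80, 0.10),
    min_cohort = 200,
    wearable_window_days = 90,
    responder_baseline_window_days = 30,
    panel_min_subjects = 10,
    age_bin_width = 5,
    age_bin_min_n = 5,
    pgs_r2_min = 0.8,
    pgs_threshold_grid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1),
    n_draws_panel = 5,
    p_adjust_method = "BH"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop_biotraj("config_error", "unknown config key(s): ",
                 paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, config)
  out$strata <- as.numeric(unlist(out$strata))
  out$pgs_threshold_grid <- sort(as.numeric(unlist(out$pgs_threshold_grid)))

  scalars <- c("min_gap_days", "iqr_multiplier", "responder_pct",
               "wearable_window_days", "responder_baseline_window_days",
               "min_cohort", "age_bin_width")
  for (key in scalars) {
    if (!is.numeric(out[[key]]) || length(out[[key]]) != 1 || is.na(out[[key]]) ||
        out[[key]] < 0) {
      stop_biotraj("config_error", "config key '", key,
                   "' must be a single non-negative number")
    }
  }
  for (key in c("alpha_main", "alpha_wearable")) {
    if (!is.numeric(out[[key]]) || out[[key]] <= 0 || out[[key]] > 1) {
      stop_biotraj("config_error", "config key '", key, "' must lie in (0, 1]")
    }
  }
  if (length(out$strata) != 3 || any(out$strata <= 0) ||
      abs(sum(out$strata) - 1) > 1e-8) {
    stop_biotraj("config_error",
                 "strata fractions must be three positive numbers summing to 1")
  }
  structure(out, class = c("biotraj_config", "list"))
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop_biotraj("config_error", "config file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_biotraj("config_error", "yaml package required to read ", path)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
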