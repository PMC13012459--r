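#' Assemble a validated cohort dataset from in-memory tables
#'
#' The dataset is the common currency of the pipeline: demographics, blood
#' draws in long format, daily wearable rows, genotype dosages, and
#' Action-Plan records, all cross-validated against the marker registry.
#' Tables other than `subjects` may be omitted (`NULL`), in which case an
#' empty table with the right columns is substituted.
#'
#' @param subjects Data frame: `subject_id`, `sex` ("female"/"male"),
#'   `age` (years at baseline, 18--85), `ethnicity`, `bmi` (kg/m^2, may be NA).
#' @param draws Data frame: `subject_id`, `draw_date` (Date or ISO-8601
#'   string), `marker_id`, `value`.
#' @param wearables Data frame: `subject_id`, `date`, `steps`, `rem_pct`,
#'   `deep_pct`, `total_sleep_min`, `rhr`, `vo2max_est` (any metric may be NA).
#' @param genotypes Data frame: `subject_id`, `variant_id`, `dose` in {0,1,2}.
#' @param action_plans Data frame: `subject_id`, `created_date`,
#'   `targeted_markers` (semicolon-joined marker ids; may be empty).
#' @param registry A [marker_registry()].
#' @return A list of class `biotraj_dataset`.
#' @export
cohort_dataset <- function(subjects, draws = NULL, wearables = NULL,
                           genotypes = NULL, action_plans = NULL,
                           registry = demo_registry()) {
  subjects <- validate_subjects(subjects)
  draws <- validate_draws(draws, registry)
  wearables <- validate_wearables(wearables)
  genotypes <- validate_genotypes(genotypes)
  action_plans <- validate_action_plans(action_plans, registry)

  for (tab in list(draws, wearables, genotypes, action_plans)) {
    orphan <- setdiff(unique(tab$subject_id), subjects$subject_id)
    if (length(orphan) > 0) {
      stop_biotraj("crossref_error", "subject_id not present in subjects table: ",
                   paste(utils::head(orphan, 5), collapse = ", "))
    }
  }
  structure(list(subjects = subjects, draws = draws, wearables = wearables,
                 genotypes = genotypes, action_plans = action_plans,
                 registry = registry),
            class = "biotraj_dataset")
}

#' @export
print.biotraj_dataset <- function(x, ...) {
  cat("<biotraj_dataset>\n")
  cat("  subjects:     ", nrow(x$subjects), "\n")
  cat("  draws:        ", nrow(x$draws), " (",
      length(unique(x$draws$marker_id)), " markers)\n", sep = "")
  cat("  wearable days:", nrow(x$wearables), "\n")
  cat("  genotypes:    ", nrow(x$genotypes), " dosage records\n", sep = "")
  cat("  action plans: ", nrow(x$action_plans), "\n", sep = "")
  invisible(x)
}

#' Read cohort tables from a directory of CSV files
#'
#' Expects `subjects.csv`, and optionally `draws.csv`, `wearables.csv`,
#' `genotypes.csv`, `action_plans.csv`, following the column contracts of
#' [cohort_dataset()]. Rows violating type constraints raise errors with
#' row-level diagnostics; an empty file with a valid header yields an empty
#' table.
#'
#' @param dir Directory containing the CSV files.
#' @param registry A [marker_registry()].
#' @return A `biotraj_dataset`.
#' @export
read_cohort_tables <- function(dir, registry = demo_registry()) {
  read_tab <- function(name, required = FALSE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop_biotraj("schema_error", "required file missing: ", path)
      return(NULL)
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  cohort_dataset(
    subjects = read_tab("subjects.csv", required = TRUE),
    draws = read_tab("draws.csv"),
    wearables = read_tab("wearables.csv"),
    genotypes = read_tab("genotypes.csv"),
    action_plans = read_tab("action_plans.csv"),
    registry = registry
  )
}

#' Write a cohort dataset to a directory of CSV files
#'
#' Inverse of [read_cohort_tables()]: the write/read round trip preserves
#' every field of every table.
#'
#' @param dataset A `biotraj_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_tables <- function(dataset, dir) {
  stopifnot(inherits(dataset, "biotraj_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("subjects", "draws", "wearables", "genotypes", "action_plans")
  paths <- character(0)
  for (tab in tabs) {
    path <- file.path(dir, paste0(tab, ".csv"))
    readr::write_csv(dataset[[tab]], path, progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# ---- per-table validators -------------------------------------------------

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_biotraj("schema_error", table, " is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
}

as_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_biotraj("schema_error", "invalid ISO-8601 date in ", what,
                 " at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

validate_subjects <- function(subjects) {
  if (is.null(subjects)) stop_biotraj("schema_error", "subjects table is required")
  subjects <- tibble::as_tibble(subjects)
  require_columns(subjects, c("subject_id", "sex", "age", "ethnicity"), "subjects")
  if (!"bmi" %in% names(subjects)) subjects$bmi <- NA_real_
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    stop_biotraj("duplication_error", "duplicate subject_id in subjects")
  }
  bad_sex <- which(!subjects$sex %in% c("female", "male"))
  if (length(bad_sex) > 0) {
    stop_biotraj("schema_error", "subjects$sex outside {female, male} at row(s): ",
                 paste(utils::head(bad_sex, 5), collapse = ", "))
  }
  bad_age <- which(is.na(subjects$age) | subjects$age < 18 | subjects$age > 85)
  if (length(bad_age) > 0) {
    stop_biotraj("schema_error", "subjects$age outside [18, 85] at row(s): ",
                 paste(utils::head(bad_age, 5), collapse = ", "))
  }
  subjects[c("subject_id", "sex", "age", "ethnicity", "bmi")]
}

empty_draws <- function() {
  tibble::tibble(subject_id = character(0), draw_date = as.Date(character(0)),
                 marker_id = character(0), value = numeric(0))
}

validate_draws <- function(draws, registry) {
  if (is.null(draws) || nrow(tibble::as_tibble(draws)) == 0) return(empty_draws())
  draws <- tibble::as_tibble(draws)
  require_columns(draws, c("subject_id", "draw_date", "marker_id", "value"), "draws")
  draws$subject_id <- as.character(draws$subject_id)
  draws$draw_date <- as_iso_date(draws$draw_date, "draws$draw_date")
  assert_markers_known(draws$marker_id, registry)
  key <- paste(draws$subject_id, draws$draw_date, draws$marker_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_biotraj("duplication_error",
                 "duplicate (subject_id, draw_date, marker_id) in draws: ", dup)
  }
  nn <- registry$marker_id[registry$non_negative]
  bad <- which(draws$marker_id %in% nn & !is.na(draws$value) & draws$value < 0)
  if (length(bad) > 0) {
    stop_biotraj("schema_error", "negative value for non-negative marker at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", "))
  }
  draws[c("subject_id", "draw_date", "marker_id", "value")]
}

wearable_metrics <- function() {
  c("steps", "rem_pct", "deep_pct", "total_sleep_min", "rhr", "vo2max_est")
}

validate_wearables <- function(wearables) {
  if (is.null(wearables) || nrow(tibble::as_tibble(wearables)) == 0) {
    out <- tibble::tibble(subject_id = character(0), date = as.Date(character(0)))
    for (m in wearable_metrics()) out[[m]] <- numeric(0)
    return(out)
  }
  wearables <- tibble::as_tibble(wearables)
  require_columns(wearables, c("subject_id", "date"), "wearables")
  for (m in wearable_metrics()) {
    if (!m %in% names(wearables)) wearables[[m]] <- NA_real_
  }
  wearables$subject_id <- as.character(wearables$subject_id)
  wearables$date <- as_iso_date(wearables$date, "wearables$date")
  if (any(wearables$steps < 0, na.rm = TRUE)) {
    stop_biotraj("schema_error", "wearables$steps must be non-negative")
  }
  for (m in c("rem_pct", "deep_pct")) {
    if (any(wearables[[m]] < 0 | wearables[[m]] > 100, na.rm = TRUE)) {
      stop_biotraj("schema_error", "wearables$", m, " must lie in [0, 100]")
    }
  }
  wearables[c("subject_id", "date", wearable_metrics())]
}

validate_genotypes <- function(genotypes) {
  if (is.null(genotypes) || nrow(tibble::as_tibble(genotypes)) == 0) {
    return(tibble::tibble(subject_id = character(0), variant_id = character(0),
                          dose = numeric(0)))
  }
  genotypes <- tibble::as_tibble(genotypes)
  require_columns(genotypes, c("subject_id", "variant_id", "dose"), "genotypes")
  genotypes$subject_id <- as.character(genotypes$subject_id)
  bad <- which(!is.na(genotypes$dose) & !genotypes$dose %in% c(0, 1, 2))
  if (length(bad) > 0) {
    stop_biotraj("schema_error", "genotypes$dose outside {0, 1, 2} at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", "))
  }
  genotypes[c("subject_id", "variant_id", "dose")]
}

validate_action_plans <- function(action_plans, registry) {
  if (is.null(action_plans) || nrow(tibble::as_tibble(action_plans)) == 0) {
    return(tibble::tibble(subject_id = character(0),
                          created_date = as.Date(character(0)),
                          targeted_markers = character(0)))
  }
  action_plans <- tibble::as_tibble(action_plans)
  require_columns(action_plans, c("subject_id", "created_date", "targeted_markers"),
                  "action_plans")
  action_plans$subject_id <- as.character(action_plans$subject_id)
  action_plans$created_date <- as_iso_date(action_plans$created_date,
                                           "action_plans$created_date")
  action_plans$targeted_markers <- ifelse(is.na(action_plans$targeted_markers),
                                          "", as.character(action_plans$targeted_markers))
  targeted <- unlist(strsplit(action_plans$targeted_markers, ";", fixed = TRUE))
  targeted <- targeted[nzchar(targeted)]
  assert_markers_known(targeted, registry)
  action_plans[c("subject_id", "created_date", "targeted_markers")]
}

# Split a semicolon-joined marker list into a character vector.
split_targets <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
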