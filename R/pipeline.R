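#' Run pipeline stages end-to-end
#'
#' Stages: `simulate` writes a synthetic cohort's input CSVs (plus
#' `zones.csv`, `pgs_weights.csv`, `truth.csv`) into `in_dir`; `prepare`
#' reads the cohort, removes per-marker IQR outliers, applies the inclusion
#' filter and pairs draws; `improve`, `rtm` consume the prepared pairs;
#' `trajectory`, `pgs`, `responders`, `engagement` run their analyses from
#' the cohort tables; `all` runs every analysis stage in dependency order.
#' Each run writes a `manifest.json` with the seed, configuration, and MD5
#' digests of inputs and outputs; identical inputs and seed reproduce
#' byte-identical outputs.
#'
#' @param command One of simulate, prepare, improve, trajectory, rtm, pgs,
#'   responders, engagement, all.
#' @param in_dir Directory of input CSV tables (created by `simulate`).
#' @param out_dir Directory for stage outputs (created if absent).
#' @param config A [validate_config()] list, overrides list, or file path.
#' @param seed Integer seed used by `simulate`.
#' @param sim_config Optional [simulation_config()] for `simulate`
#'   (otherwise built from `seed`).
#' @param markers Optional marker subset to restrict analysis stages to.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(command = c("all", "simulate", "prepare", "improve",
                                     "trajectory", "rtm", "pgs", "responders",
                                     "engagement"),
                         in_dir, out_dir, config = list(), seed = 20342,
                         sim_config = NULL, markers = NULL) {
  command <- match.arg(command)
  config <- if (inherits(config, "biotraj_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (command == "simulate") {
    if (is.null(sim_config)) sim_config <- simulation_config(seed = seed)
    sim <- generate_cohort(sim_config)
    dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_tables(sim$dataset, in_dir)
    readr::write_csv(sim$zone_table, file.path(in_dir, "zones.csv"), progress = FALSE)
    readr::write_csv(sim$pgs_weights, file.path(in_dir, "pgs_weights.csv"),
                     progress = FALSE)
    readr::write_csv(sim$truth, file.path(in_dir, "truth.csv"), progress = FALSE)
    return(invisible(write_manifest(out_dir, command, config, seed, in_dir,
                                    character(0))))
  }

  dataset <- read_cohort_tables(in_dir)
  zone_path <- file.path(in_dir, "zones.csv")
  zone_table <- if (file.exists(zone_path)) read_zone_table(zone_path) else
    demo_zone_table()
  marker_ids <- sort(unique(dataset$draws$marker_id))
  if (!is.null(markers)) marker_ids <- intersect(marker_ids, markers)
  outputs <- character(0)

  stage_prepare <- function() {
    cleaned <- remove_draw_outliers(dataset, k = config$iqr_multiplier)
    eligible <- filter_inclusion(cleaned$dataset, config$min_gap_days)
    ds <- cleaned$dataset
    ds$draws <- ds$draws[ds$draws$subject_id %in% eligible, ]
    paired <- dplyr::bind_rows(lapply(marker_ids, function(m) {
      pair_draws(ds, m, min_gap_days = config$min_gap_days,
                 zone_table = zone_table)
    }))
    readr::write_csv(paired, file.path(out_dir, "prepared_paired.csv"),
                     progress = FALSE)
    readr::write_csv(cleaned$report, file.path(out_dir, "prepared_outliers.csv"),
                     progress = FALSE)
    message(sprintf("prepare: %d eligible subjects, %d pairs, %d outliers removed",
                    length(eligible), nrow(paired), nrow(cleaned$report)))
    c("prepared_paired.csv", "prepared_outliers.csv")
  }

  read_paired <- function() {
    path <- file.path(out_dir, "prepared_paired.csv")
    if (!file.exists(path)) {
      stop_biotraj("dependency_error",
                   "missing prepared_paired.csv; run the 'prepare' stage first")
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }

  stage_improve <- function() {
    paired <- read_paired()
    rows <- list()
    for (m in intersect(marker_ids, unique(paired$marker_id))) {
      mp <- paired[paired$marker_id == m, ]
      for (side in c("above_optimal", "below_optimal")) {
        want <- if (side == "above_optimal") "above" else "below"
        sub <- mp[zone_side(mp$zone1) == want, ]
        if (nrow(sub) < 5) next
        rows[[paste(m, side)]] <-
          summarize_baseline_followup(sub, side, min_cohort = config$min_cohort)
      }
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) > 0) out$p_adjusted <- adjust_pvalues(out$p_value,
                                                        config$p_adjust_method)
    readr::write_csv(out, file.path(out_dir, "improve_summary.csv"),
                     progress = FALSE)
    "improve_summary.csv"
  }

  stage_trajectory <- function() {
    rows <- list()
    for (m in marker_ids) {
      for (side in c("above_optimal", "below_optimal")) {
        panel <- suppressWarnings(
          build_matched_panel(dataset, m, side, n_draws = config$n_draws_panel,
                              zone_table = zone_table,
                              min_gap_days = config$min_gap_days,
                              min_subjects = config$panel_min_subjects))
        if (nrow(panel$values) < 2) next
        tr <- trajectory_analysis(panel, alpha = config$alpha_main)
        tr$marker_id <- m
        tr$stratum <- side
        rows[[paste(m, side)]] <- tr
      }
    }
    out <- dplyr::bind_rows(rows)
    readr::write_csv(out, file.path(out_dir, "trajectory.csv"), progress = FALSE)
    "trajectory.csv"
  }

  stage_rtm <- function() {
    paired <- read_paired()
    rows <- list()
    for (m in intersect(marker_ids, unique(paired$marker_id))) {
      mp <- paired[paired$marker_id == m, ]
      if (nrow(mp) < 10) next
      for (side in c("above_optimal", "below_optimal")) {
        want <- if (side == "above_optimal") "above" else "below"
        sub <- mp[zone_side(mp$zone1) == want, ]
        if (nrow(sub) < 5) next
        est <- estimate_rtm_cohort(mp, subcohort_x1 = sub$x1, marker_id = m)
        obs <- mean(sub$x2 - sub$x1)
        rows[[paste(m, side)]] <- tibble::tibble(
          marker_id = m, stratum = side, mu = est$mu, rho = est$rho,
          mean_delta_rtm = est$mean_delta_rtm, mean_observed_change = obs,
          n_reference = est$n_reference, n_subcohort = est$n_subcohort)
      }
    }
    out <- dplyr::bind_rows(rows)
    readr::write_csv(out, file.path(out_dir, "rtm.csv"), progress = FALSE)
    "rtm.csv"
  }

  stage_pgs <- function() {
    wpath <- file.path(in_dir, "pgs_weights.csv")
    if (!file.exists(wpath) || nrow(dataset$genotypes) == 0) {
      message("pgs: no weights or genotypes available; stage skipped")
      return(character(0))
    }
    defs <- read_pgs_weights(wpath)
    paired <- read_paired()
    files <- character(0)
    scores_all <- list()
    strata_all <- list()
    tests_all <- list()
    for (trait in names(defs)) {
      def <- defs[[trait]]
      if (!trait %in% marker_ids) next
      mp <- paired[paired$marker_id == trait, ]
      phenotype <- stats::setNames(mp$x1, mp$subject_id)
      resolved <- resolve_variants(def, unique(dataset$genotypes$variant_id),
                                   r2_min = config$pgs_r2_min)
      sel <- select_threshold(dataset$genotypes, resolved$pgs, phenotype,
                              thresholds = config$pgs_threshold_grid)
      sc <- compute_pgs(dataset$genotypes, resolved$pgs, threshold = sel$threshold)
      sc$trait <- trait
      scores_all[[trait]] <- sc
      ve <- variance_explained(sc$score[match(names(phenotype), sc$subject_id)],
                               unname(phenotype))
      strata <- stratify_scores(stats::setNames(sc$score, sc$subject_id),
                                fractions = config$strata)
      strata$trait <- trait
      strata_all[[trait]] <- strata
      sub <- mp[zone_side(mp$zone1) == "above" &
                  mp$subject_id %in% strata$subject_id, ]
      test_row <- tibble::tibble(trait = trait, threshold = sel$threshold,
                                 r_squared = ve$r_squared,
                                 regression_p = ve$p_value,
                                 anova_f = NA_real_, anova_p = NA_real_)
      if (nrow(sub) >= 6) {
        change <- stats::setNames(sub$x2 - sub$x1, sub$subject_id)
        sub_assign <- strata[strata$subject_id %in% names(change), ]
        counts <- table(sub_assign$stratum)
        if (sum(counts >= 2) >= 2) {
          sct <- strata_change_test(sub_assign, change)
          test_row$anova_f <- sct$anova$f
          test_row$anova_p <- sct$anova$p
        }
      }
      tests_all[[trait]] <- test_row
    }
    readr::write_csv(dplyr::bind_rows(scores_all),
                     file.path(out_dir, "pgs_scores.csv"), progress = FALSE)
    readr::write_csv(dplyr::bind_rows(strata_all),
                     file.path(out_dir, "pgs_strata.csv"), progress = FALSE)
    readr::write_csv(dplyr::bind_rows(tests_all),
                     file.path(out_dir, "pgs_tests.csv"), progress = FALSE)
    c("pgs_scores.csv", "pgs_strata.csv", "pgs_tests.csv")
  }

  stage_responders <- function() {
    if (nrow(dataset$wearables) == 0) {
      message("responders: no wearable data; stage skipped")
      return(character(0))
    }
    wm <- intersect(marker_ids, unique(dataset$draws$marker_id))
    # exploratory by design: analyses labelled as such in the outputs
    rows_cmp <- list()
    rows_lab <- list()
    rows_month <- list()
    for (m in wm) {
      rc <- responder_characterization(dataset, m, zone_table = zone_table,
                                       side = "above_optimal", config = config)
      if (nrow(rc$labels) == 0) next
      rows_lab[[m]] <- rc$labels
      if (nrow(rc$baseline) > 0) {
        rc$baseline$window <- "baseline"
        rc$baseline$marker_id <- m
        rows_cmp[[paste(m, "b")]] <- rc$baseline
      }
      if (nrow(rc$change) > 0) {
        rc$change$window <- "between_tests_change"
        rc$change$marker_id <- m
        rows_cmp[[paste(m, "c")]] <- rc$change
      }
      if (nrow(rc$monthly) > 0) {
        rc$monthly$marker_id <- m
        rows_month[[m]] <- rc$monthly
      }
    }
    cmp <- dplyr::bind_rows(rows_cmp)
    if (nrow(cmp) > 0) cmp$note <- "exploratory"
    readr::write_csv(dplyr::bind_rows(rows_lab),
                     file.path(out_dir, "responder_labels.csv"), progress = FALSE)
    readr::write_csv(cmp, file.path(out_dir, "group_comparisons.csv"),
                     progress = FALSE)
    readr::write_csv(dplyr::bind_rows(rows_month),
                     file.path(out_dir, "monthly_series.csv"), progress = FALSE)
    c("responder_labels.csv", "group_comparisons.csv", "monthly_series.csv")
  }

  stage_engagement <- function() {
    out <- engagement_analysis(dataset, marker_ids, zone_table = zone_table,
                               min_gap_days = config$min_gap_days)
    if (nrow(out) > 0) out$note <- "associational"
    readr::write_csv(out, file.path(out_dir, "engagement_results.csv"),
                     progress = FALSE)
    "engagement_results.csv"
  }

  stages <- switch(command,
    prepare = list(stage_prepare),
    improve = list(stage_improve),
    trajectory = list(stage_trajectory),
    rtm = list(stage_rtm),
    pgs = list(stage_pgs),
    responders = list(stage_responders),
    engagement = list(stage_engagement),
    all = list(stage_prepare, stage_improve, stage_trajectory, stage_rtm,
               stage_pgs, stage_responders, stage_engagement)
  )
  for (stage in stages) outputs <- c(outputs, stage())
  invisible(write_manifest(out_dir, command, config, seed, in_dir, outputs))
}

write_manifest <- function(out_dir, command, config, seed, in_dir, outputs) {
  digest_files <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0) return(stats::setNames(list(), character(0)))
    as.list(tools::md5sum(paths))
  }
  inputs <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    command = command,
    seed = seed,
    config_hash = unname(tools::md5sum(local({
      tmp <- tempfile()
      writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
      tmp
    }))),
    inputs = digest_files(sort(inputs)),
    outputs = digest_files(file.path(out_dir, outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
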