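#' Per-marker generative parameters for the synthetic cohort
#'
#' @param mu,sigma Baseline population mean and SD (marker units).
#' @param rho Test-retest correlation between successive draws.
#' @param zones Numeric c(c1, c2, c3, c4) zone cut-points (NA = open side).
#' @param effect_above Additive intervention effect per draw applied when
#'   the previous value sat above optimal (negative = toward optimal).
#' @param effect_below Effect applied below optimal (positive).
#' @param decay Multiplicative decay of the effect at each later draw, so
#'   the largest improvement falls between baseline and first follow-up.
#' @param drift Per-draw drift applied while a value sits in the optimal
#'   zone (natural-history movement away from optimal).
#' @return A list.
#' @export
marker_sim <- function(mu, sigma, rho, zones, effect_above = 0,
                       effect_below = 0, decay = 0.5, drift = 0) {
  stopifnot(sigma > 0, rho >= -1, rho <= 1, length(zones) == 4)
  list(mu = mu, sigma = sigma, rho = rho, zones = zones,
       effect_above = effect_above, effect_below = effect_below,
       decay = decay, drift = drift)
}

default_sim_markers <- function() {
  list(
    # effect scales mirror the magnitude of observed median shifts on each
    # marker (e.g. LDL 149 -> 141, glucose 95 -> 91, vitamin D 26 -> 35)
    ldl = marker_sim(mu = 120, sigma = 30, rho = 0.75,
                     zones = c(NA, NA, 100, 130),
                     effect_above = -8, drift = 1),
    total_cholesterol = marker_sim(mu = 200, sigma = 35, rho = 0.75,
                                   zones = c(NA, NA, 200, 240),
                                   effect_above = -12, drift = 1.5),
    fasting_glucose = marker_sim(mu = 90, sigma = 10, rho = 0.6,
                                 zones = c(65, 75, 90, 100),
                                 effect_above = -4, effect_below = 2,
                                 drift = 0.5),
    vitamin_d = marker_sim(mu = 32, sigma = 10, rho = 0.7,
                           zones = c(20, 30, NA, NA),
                           effect_below = 9, drift = -0.3)
  )
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the study conditions: 64.2% male, mean age ~47 (SD 12)
#' truncated to 18--85, the published ethnicity mix, ~38% genotyped, a
#' polygenic block explaining h^2 = 10% of baseline variance of its linked
#' marker (the published trait-level estimates run ~5--13%), a wearable
#' subgroup whose biomarker responders walk ~950 steps/day more after
#' baseline on an 8700-step base and show 22% vs 18% REM sleep, 72% AP
#' uptake among out-of-range users, and a draw schedule whose first
#' follow-up lands ~260 days after baseline.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed; the generator is deterministic given the seed,
#'   and per-subject streams are derived from it so adding subjects never
#'   perturbs existing ones.
#' @param markers Named list of [marker_sim()] blocks.
#' @param n_draws Draws per subject.
#' @param gap_days,gap_jitter_days Gap between successive draws is
#'   `gap_days` plus a uniform 0..`gap_jitter_days` jitter.
#' @param p_genotyped Fraction of subjects with genotypes.
#' @param pgs Polygenic block: `marker` (linked marker id), `m_variants`,
#'   `h2`, `stratum_mult` (intervention-effect multiplier per true stratum,
#'   T1 improving most).
#' @param p_wearable Fraction with wearable data.
#' @param wearable Wearable block: `marker` (linked marker), `p_responder`,
#'   `steps_base_mean`, `steps_base_sd`, `steps_daily_sd`,
#'   `responder_step_delta`, `rem_responder`, `rem_nonresponder`,
#'   `rem_daily_sd`, `responder_effect_mult`, `nonresponder_effect_mult`.
#' @param ap Action-Plan block: `p_target` (probability an out-of-range user
#'   creates an AP targeting that marker), `uplift_mult` (intervention-effect
#'   multiplier when they do).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 2000,
                              seed = 20342,
                              markers = default_sim_markers(),
                              n_draws = 5,
                              gap_days = 200,
                              gap_jitter_days = 120,
                              p_genotyped = 0.38,
                              pgs = list(marker = "ldl", m_variants = 100,
                                         h2 = 0.10,
                                         stratum_mult = c(T1 = 1.5, T2 = 1.0,
                                                          T3 = 0.5)),
                              p_wearable = 0.35,
                              wearable = list(marker = "total_cholesterol",
                                              p_responder = 0.5,
                                              steps_base_mean = 8700,
                                              steps_base_sd = 1500,
                                              steps_daily_sd = 2500,
                                              responder_step_delta = 950,
                                              rem_responder = 22,
                                              rem_nonresponder = 18,
                                              rem_daily_sd = 3,
                                              responder_effect_mult = 1.8,
                                              nonresponder_effect_mult = 0.2),
                              ap = list(p_target = 0.72, uplift_mult = 1.6)) {
  cfg <- list(n_subjects = n_subjects, seed = as.integer(seed),
              markers = markers, n_draws = n_draws, gap_days = gap_days,
              gap_jitter_days = gap_jitter_days, p_genotyped = p_genotyped,
              pgs = pgs, p_wearable = p_wearable, wearable = wearable, ap = ap)
  for (p in c("p_genotyped", "p_wearable")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop_biotraj("config_error", p, " must lie in [0, 1]")
    }
  }
  if (pgs$h2 < 0 || pgs$h2 >= 1) {
    stop_biotraj("config_error", "pgs$h2 must lie in [0, 1)")
  }
  if (!pgs$marker %in% names(markers) || !wearable$marker %in% names(markers)) {
    stop_biotraj("config_error", "pgs and wearable blocks must link to a configured marker")
  }
  if (ap$p_target < 0 || ap$p_target > 1 || wearable$p_responder < 0 ||
      wearable$p_responder > 1) {
    stop_biotraj("config_error", "probabilities must lie in [0, 1]")
  }
  structure(cfg, class = c("simulation_config", "list"))
}

# Deterministic sub-stream seed below 2^31 for subject i, stream k.
seed_for <- function(seed, i, k) {
  as.integer((as.double(seed) * 48271 + i * 7919 + k * 104729) %% 2147483647)
}

sim_zone_spec <- function(zones, marker_id) {
  zone_spec(ifelse(is.na(zones[1]), -Inf, zones[1]),
            ifelse(is.na(zones[2]), -Inf, zones[2]),
            ifelse(is.na(zones[3]), Inf, zones[3]),
            ifelse(is.na(zones[4]), Inf, zones[4]),
            marker_id = marker_id)
}

#' Generate a synthetic cohort
#'
#' Emits a full [cohort_dataset()] (subjects, draws, wearables, genotypes,
#' action plans), the PGS weight table used, and a per-subject truth table
#' of the latent quantities (true stratum, responder flag, applied
#' multipliers). Baselines are Normal(mu, sigma^2); later draws follow
#' `x[t+1] = mu + rho (x[t] - mu) + effect + noise` with noise SD
#' `sigma * sqrt(1 - rho^2)`, the stationary test-retest structure the
#' regression-to-the-mean analysis assumes. Intervention effects push
#' out-of-optimal values toward optimal, decay over draws, and are scaled
#' by the subject's PGS-stratum, responder, and Action-Plan multipliers on
#' the linked markers; optimal-at-baseline users instead drift slowly.
#'
#' @param config A [simulation_config()].
#' @return A list: `dataset` (a `biotraj_dataset`), `truth` (tibble),
#'   `pgs_weights` (tibble), `zone_table` (tibble used for zone sides).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  n <- config$n_subjects
  markers <- config$markers
  specs <- lapply(names(markers), function(m) sim_zone_spec(markers[[m]]$zones, m))
  names(specs) <- names(markers)

  # global PGS block
  set.seed(seed_for(seed, 0, 1))
  m_var <- config$pgs$m_variants
  freqs <- stats::runif(m_var, 0.1, 0.9)
  raw_beta <- stats::rnorm(m_var)
  beta <- raw_beta / sqrt(sum(raw_beta^2 * 2 * freqs * (1 - freqs)))
  g_mean <- sum(beta * 2 * freqs)
  variant_ids <- sprintf("v%04d", seq_len(m_var))
  gwas_p <- 10^stats::runif(m_var, -12, -2)
  pgs_weights <- tibble::tibble(trait = config$pgs$marker,
                                variant_id = variant_ids,
                                effect_allele = "A", beta = beta,
                                gwas_p = gwas_p)

  ethnicities <- c("White", "Asian", "Hispanic", "Black", "South Asian",
                   "Native American")
  eth_probs <- c(0.843, 0.054, 0.0555, 0.0216, 0.0245, 0.0018)
  eth_probs <- eth_probs / sum(eth_probs)

  subjects <- vector("list", n)
  draws <- vector("list", n)
  wearables <- vector("list", n)
  genotypes <- vector("list", n)
  aps <- vector("list", n)
  truth <- vector("list", n)
  h2 <- config$pgs$h2
  wb <- config$wearable

  for (i in seq_len(n)) {
    set.seed(seed_for(seed, i, 2))
    sid <- sprintf("s%05d", i)
    sex <- if (stats::runif(1) < 0.642) "male" else "female"
    age <- min(85, max(18, round(stats::rnorm(1, 47, 12))))
    eth <- sample(ethnicities, 1, prob = eth_probs)
    bmi <- if (sex == "female") stats::rnorm(1, 23.2, 3.8) else
      stats::rnorm(1, 25.3, 3.3)
    subjects[[i]] <- tibble::tibble(subject_id = sid, sex = sex, age = age,
                                    ethnicity = eth, bmi = round(bmi, 1))

    date1 <- as.Date("2020-01-01") + floor(stats::runif(1, 0, 365))
    gaps <- config$gap_days + floor(stats::runif(config$n_draws - 1, 0,
                                                 config$gap_jitter_days + 1))
    dates <- date1 + c(0, cumsum(gaps))

    genotyped <- stats::runif(1) < config$p_genotyped
    g_std <- NA_real_
    stratum <- NA_character_
    if (genotyped) {
      doses <- stats::rbinom(m_var, 2, freqs)
      g_std <- sum(doses * beta) - g_mean
      stratum <- if (g_std <= stats::qnorm(0.1)) "T1"
        else if (g_std >= stats::qnorm(0.9)) "T3" else "T2"
      genotypes[[i]] <- tibble::tibble(subject_id = sid,
                                       variant_id = variant_ids, dose = doses)
    }
    has_wear <- stats::runif(1) < config$p_wearable

    # baselines
    x1 <- vapply(names(markers), function(m) {
      blk <- markers[[m]]
      if (genotyped && m == config$pgs$marker) {
        blk$mu + blk$sigma * (sqrt(h2) * g_std +
                                sqrt(1 - h2) * stats::rnorm(1))
      } else {
        stats::rnorm(1, blk$mu, blk$sigma)
      }
    }, numeric(1))

    responder <- NA
    if (has_wear) {
      wside <- zone_side(classify_zone(max(x1[[wb$marker]], 0),
                                       specs[[wb$marker]]))
      if (wside != "at") responder <- stats::runif(1) < wb$p_responder
    }

    # Action Plans: out-of-range markers may get a targeting AP
    ap_markers <- character(0)
    for (m in names(markers)) {
      side_m <- zone_side(classify_zone(max(x1[[m]], 0), specs[[m]]))
      if (side_m != "at" && stats::runif(1) < config$ap$p_target) {
        ap_markers <- c(ap_markers, m)
      }
    }
    if (length(ap_markers) > 0) {
      offset <- floor(stats::runif(1, 1, min(60, gaps[1])))
      aps[[i]] <- tibble::tibble(subject_id = sid,
                                 created_date = date1 + offset,
                                 targeted_markers = paste(ap_markers,
                                                          collapse = ";"))
    }

    # trajectories
    subj_draws <- vector("list", length(markers))
    for (mi in seq_along(markers)) {
      m <- names(markers)[mi]
      blk <- markers[[m]]
      mult <- 1
      if (genotyped && m == config$pgs$marker && !is.na(stratum)) {
        mult <- mult * config$pgs$stratum_mult[[stratum]]
      }
      if (m == wb$marker && !is.na(responder)) {
        mult <- mult * if (responder) wb$responder_effect_mult else
          wb$nonresponder_effect_mult
      }
      if (m %in% ap_markers) mult <- mult * config$ap$uplift_mult
      x <- numeric(config$n_draws)
      x[1] <- max(x1[[m]], 0)
      for (t in 2:config$n_draws) {
        side_t <- zone_side(classify_zone(x[t - 1], specs[[m]]))
        eff <- switch(side_t,
                      above = blk$effect_above * blk$decay^(t - 2) * mult,
                      below = blk$effect_below * blk$decay^(t - 2) * mult,
                      at = blk$drift)
        x[t] <- blk$mu + blk$rho * (x[t - 1] - blk$mu) + eff +
          stats::rnorm(1, 0, blk$sigma * sqrt(1 - blk$rho^2))
        x[t] <- max(x[t], 0)
      }
      subj_draws[[mi]] <- tibble::tibble(subject_id = sid, draw_date = dates,
                                         marker_id = m, value = round(x, 3))
    }
    draws[[i]] <- dplyr::bind_rows(subj_draws)

    if (has_wear) {
      wdates <- seq(date1 - 45, date1 + 360, by = "day")
      nd <- length(wdates)
      post <- wdates > date1
      steps_base <- stats::rnorm(1, wb$steps_base_mean, wb$steps_base_sd)
      delta <- if (isTRUE(responder)) wb$responder_step_delta else 0
      steps <- pmax(0, round(stats::rnorm(nd, steps_base + delta * post,
                                          wb$steps_daily_sd)))
      rem_mean <- if (isTRUE(responder)) wb$rem_responder else wb$rem_nonresponder
      rem <- pmin(100, pmax(0, stats::rnorm(nd, rem_mean, wb$rem_daily_sd)))
      deep <- pmin(100, pmax(0, stats::rnorm(nd, 15, 3)))
      sleep <- pmax(0, stats::rnorm(nd, 420, 40))
      rhr <- pmax(30, stats::rnorm(nd, 60, 5))
      vo2 <- pmax(10, stats::rnorm(nd, 40, 4))
      wearables[[i]] <- tibble::tibble(subject_id = sid, date = wdates,
                                       steps = steps, rem_pct = round(rem, 1),
                                       deep_pct = round(deep, 1),
                                       total_sleep_min = round(sleep),
                                       rhr = round(rhr, 1),
                                       vo2max_est = round(vo2, 1))
    }
    truth[[i]] <- tibble::tibble(
      subject_id = sid, genotyped = genotyped, g_std = g_std,
      pgs_stratum_true = stratum, has_wearable = has_wear,
      responder = responder,
      ap_markers = paste(ap_markers, collapse = ";"))
  }

  registry <- demo_registry()
  dataset <- cohort_dataset(
    subjects = dplyr::bind_rows(subjects),
    draws = dplyr::bind_rows(draws),
    wearables = dplyr::bind_rows(wearables),
    genotypes = dplyr::bind_rows(genotypes),
    action_plans = dplyr::bind_rows(aps),
    registry = registry
  )
  zone_table <- dplyr::bind_rows(lapply(names(markers), function(m) {
    z <- markers[[m]]$zones
    tibble::tibble(marker_id = m, sex = NA_character_, age_min = NA_real_,
                   age_max = NA_real_, ethnicity = NA_character_,
                   c1 = z[1], c2 = z[2], c3 = z[3], c4 = z[4])
  }))
  list(dataset = dataset, truth = dplyr::bind_rows(truth),
       pgs_weights = pgs_weights, zone_table = zone_table)
}

#' Simulate baseline/follow-up pairs for a single marker
#'
#' Vectorized single-marker view of the generative model: baselines are
#' Normal(mu, sigma^2) and follow-ups are
#' `x2 = mu + rho (x1 - mu) + effect + noise`, noise SD
#' `sigma sqrt(1 - rho^2)`, with an optional constant additive effect.
#' Useful for theory-level checks (regression to the mean, test power)
#' without the full cohort machinery.
#'
#' @param n Number of pairs.
#' @param mu,sigma,rho Population mean, SD, test-retest correlation.
#' @param effect Constant additive effect applied to every follow-up.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x1`, `x2`.
#' @export
simulate_marker_pairs <- function(n, mu, sigma, rho, effect = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x1 <- stats::rnorm(n, mu, sigma)
  x2 <- mu + rho * (x1 - mu) + effect +
    stats::rnorm(n, 0, sigma * sqrt(1 - rho^2))
  tibble::tibble(x1 = x1, x2 = x2)
}

#' Simulate a genotype block with a polygenic phenotype
#'
#' Vectorized view of the generator's polygenic block: doses are
#' Binomial(2, f_j) with uniform allele frequencies, betas are scaled so the
#' raw score has unit variance, and the phenotype is
#' `mu + sigma (sqrt(h2) g + sqrt(1 - h2) e)` with `g` the standardized
#' score and `e` independent standard normal, so the score explains a
#' fraction h2 of phenotypic variance in expectation.
#'
#' @param n Subjects.
#' @param m Variants.
#' @param h2 Target fraction of phenotypic variance explained.
#' @param mu,sigma Phenotype scale.
#' @param seed Optional integer seed.
#' @return A list: `genotypes` (long tibble), `pgs` (a [pgs_definition()]),
#'   `phenotype` (named numeric), `g_std` (named numeric latent score).
#' @export
simulate_pgs_cohort <- function(n, m = 100, h2 = 0.10, mu = 120, sigma = 30,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- stats::runif(m, 0.1, 0.9)
  raw_beta <- stats::rnorm(m)
  beta <- raw_beta / sqrt(sum(raw_beta^2 * 2 * freqs * (1 - freqs)))
  ids <- sprintf("s%05d", seq_len(n))
  variant_ids <- sprintf("v%04d", seq_len(m))
  doses <- matrix(stats::rbinom(n * m, 2, rep(freqs, each = n)), nrow = n)
  g_std <- as.numeric(doses %*% beta) - sum(beta * 2 * freqs)
  phenotype <- mu + sigma * (sqrt(h2) * g_std +
                               sqrt(1 - h2) * stats::rnorm(n))
  genotypes <- tibble::tibble(
    subject_id = rep(ids, times = m),
    variant_id = rep(variant_ids, each = n),
    dose = as.numeric(doses)
  )
  pgs <- pgs_definition("sim_trait", tibble::tibble(
    variant_id = variant_ids, effect_allele = "A", beta = beta,
    gwas_p = 10^stats::runif(m, -12, -2)))
  list(genotypes = genotypes, pgs = pgs,
       phenotype = stats::setNames(phenotype, ids),
       g_std = stats::setNames(g_std, ids))
}

#' Closed-form expectations for the Normal generative blocks
#'
#' Analytic oracle values used to validate the generator and the
#' regression-to-the-mean machinery against theory: the truncated-normal
#' mean of the selected baselines, the expected cohort RTM change for that
#' selection, the probability the follow-up crosses back over the selection
#' cut under zero intervention effect (bivariate-normal, by numeric
#' integration), and the configured responder step-count gap.
#'
#' @param config A [simulation_config()].
#' @param marker_id Marker whose block to evaluate.
#' @param cut Selection cut-point; defaults to the marker's optimal-zone
#'   boundary on the chosen side.
#' @param side `"above"` (select x1 > cut) or `"below"` (x1 < cut).
#' @return A list: `truncated_mean`, `expected_mean_delta_rtm`,
#'   `crossback_prob_zero_effect`, `expected_step_delta`.
#' @export
closed_form_expectations <- function(config, marker_id, cut = NULL,
                                     side = c("above", "below")) {
  side <- match.arg(side)
  blk <- config$markers[[marker_id]]
  if (is.null(blk)) stop_biotraj("input_error", "unknown marker: ", marker_id)
  mu <- blk$mu; sigma <- blk$sigma; rho <- blk$rho
  if (is.null(cut)) {
    cut <- if (side == "above") blk$zones[3] else blk$zones[2]
  }
  a <- (cut - mu) / sigma
  trunc_mean <- if (side == "above") {
    mu + sigma * stats::dnorm(a) / (1 - stats::pnorm(a))
  } else {
    mu - sigma * stats::dnorm(a) / stats::pnorm(a)
  }
  exp_rtm <- (1 - rho) * (mu - trunc_mean)
  # P(x2 on the favourable side of the cut | selection), zero effect:
  # integrate the conditional normal of x2 given x1 over the selected tail
  cond_prob <- function(x) {
    z2 <- (cut - mu - rho * (x - mu)) / (sigma * sqrt(1 - rho^2))
    if (side == "above") stats::pnorm(z2) else 1 - stats::pnorm(z2)
  }
  dens <- function(x) stats::dnorm(x, mu, sigma)
  if (rho == 1) {
    cross <- 0
  } else if (side == "above") {
    num <- stats::integrate(function(x) cond_prob(x) * dens(x), cut, Inf,
                            rel.tol = 1e-9)$value
    cross <- num / (1 - stats::pnorm(a))
  } else {
    num <- stats::integrate(function(x) cond_prob(x) * dens(x), -Inf, cut,
                            rel.tol = 1e-9)$value
    cross <- num / stats::pnorm(a)
  }
  list(truncated_mean = trunc_mean,
       expected_mean_delta_rtm = exp_rtm,
       crossback_prob_zero_effect = cross,
       expected_step_delta = config$wearable$responder_step_delta)
}
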