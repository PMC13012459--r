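test_that("signed-rank p matches the exhaustive sign-flip oracle on small fixtures", {
  fixtures <- list(
    list(x1 = c(10, 12, 9, 14, 11, 13, 8, 15),
         x2 = c(12, 11, 13, 13, 16, 12, 10, 18)),
    list(x1 = c(1, 2, 3, 4, 5, 6),
         x2 = c(1.5, 1.1, 4.2, 3.1, 7.0, 6.4)),
    # ties in |d| exercise the mid-rank handling
    list(x1 = c(5, 5, 5, 5, 5, 5, 5),
         x2 = c(6, 4, 7, 3, 6, 8, 4)),
    list(x1 = c(0, 0, 0, 0, 0), x2 = c(1, 2, 3, 4, 5))
  )
  for (fx in fixtures) {
    res <- paired_signed_rank_test(fx$x1, fx$x2)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, signflip_oracle_p(fx$x1, fx$x2), tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with stats::wilcox.test on tie-free data", {
  set.seed(14)
  for (n in c(6, 10, 20)) {
    x1 <- stats::rnorm(n)
    x2 <- x1 + stats::rnorm(n, 0.3)
    res <- paired_signed_rank_test(x1, x2)
    ref <- stats::wilcox.test(x2, x1, paired = TRUE, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank handles degenerate and shifted inputs", {
  x <- c(1, 2, 3, 4, 5)
  res <- paired_signed_rank_test(x, x)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  set.seed(2)
  y <- stats::rnorm(30, 100, 5)
  shifted <- paired_signed_rank_test(y, y + 3)
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$method, "normal")
})

test_that("improvement summary reproduces hand-enumerated transitions", {
  # spec (40,50,71,91); 5 above-optimal baselines:
  # 95->80 improved; 95->85 improved; 80->60 improved+optimized;
  # 95->95 unchanged; 80->92 worsened  => 60% improved, 20% optimized
  spec <- demo_spec()
  x1 <- c(95, 95, 80, 95, 80)
  x2 <- c(80, 85, 60, 95, 92)
  pairs <- tibble::tibble(subject_id = letters[1:5], marker_id = "demo",
                          x1 = x1, x2 = x2,
                          zone1 = classify_zone(x1, spec),
                          zone2 = classify_zone(x2, spec))
  sm <- summarize_baseline_followup(pairs, "above_optimal", min_cohort = 5)
  expect_equal(sm$pct_improved, 60)
  expect_equal(sm$pct_optimized, 20)
  expect_false(sm$suppressed)
  expect_equal(sm$median1, 95)
  expect_equal(sm$n_pairs, 5)

  sm2 <- summarize_baseline_followup(pairs, "above_optimal", min_cohort = 200)
  expect_true(sm2$suppressed)

  all_tied <- dplyr::mutate(pairs, x2 = x1, zone2 = zone1)
  sm3 <- summarize_baseline_followup(all_tied, "above_optimal", min_cohort = 5)
  expect_equal(sm3$pct_improved, 0)
  expect_equal(sm3$p_value, 1)

  mixed <- pairs
  mixed$zone1[1] <- "normal_low"
  expect_error(summarize_baseline_followup(mixed, "above_optimal", 5),
               class = "biotraj_input_error")
})

test_that("pct_optimized never exceeds pct_improved on simulated cohorts", {
  for (seed in 1:5) {
    sim <- generate_cohort(simulation_config(n_subjects = 80, seed = seed))
    pairs <- pair_draws(sim$dataset, "ldl", zone_table = sim$zone_table)
    sub <- pairs[zone_side(pairs$zone1) == "above", ]
    if (nrow(sub) < 5) next
    sm <- summarize_baseline_followup(sub, "above_optimal", min_cohort = 5)
    expect_lte(sm$pct_optimized, sm$pct_improved)
    expect_gte(sm$pct_optimized, 0)
    expect_lte(sm$pct_improved, 100)
  }
})

test_that("trajectory flags separate draw-1 effects from later drift", {
  # uniform shift at draw 2 maintained thereafter: draws 2..4 differ from
  # draw 1 but not from draw 2
  set.seed(8)
  n <- 40
  base <- stats::rnorm(n, 150, 10)
  panel <- cbind(base, base - 12, base - 12, base - 12) +
    matrix(stats::rnorm(n * 4, 0, 0.5), n)
  tr <- trajectory_analysis(panel)
  expect_false(tr$sig_vs_draw1[1])
  expect_true(all(tr$sig_vs_draw1[2:4]))
  expect_false(any(tr$sig_vs_both[2:4], na.rm = TRUE))

  # continued improvement: later draws differ from draw 1 AND draw 2
  panel2 <- cbind(base, base - 12, base - 24, base - 36) +
    matrix(stats::rnorm(n * 4, 0, 0.5), n)
  tr2 <- trajectory_analysis(panel2)
  expect_true(all(tr2$sig_vs_both[3:4]))

  const <- matrix(rep(stats::rnorm(10), 3), ncol = 3)
  tr3 <- trajectory_analysis(const)
  expect_false(any(tr3$sig_vs_draw1))
  expect_error(trajectory_analysis(const[, 1, drop = FALSE]),
               class = "biotraj_input_error")
})

test_that("individual RTM formula is exact, linear, and antisymmetric", {
  expect_identical(expected_rtm_individual(150, 100, 1), 0)
  expect_identical(expected_rtm_individual(150, 100, 0), -50)
  expect_identical(expected_rtm_individual(150, 100, 0.6), -20)
  # linear in x1 and mu; antisymmetric under swapping x1 <-> mu
  set.seed(31)
  for (i in 1:20) {
    x1 <- stats::runif(1, 0, 200); mu <- stats::runif(1, 0, 200)
    rho <- stats::runif(1, -1, 1); dx <- stats::rnorm(1)
    f <- expected_rtm_individual
    expect_equal(f(x1 + dx, mu, rho) - f(x1, mu, rho), -(1 - rho) * dx)
    expect_equal(f(x1, mu + dx, rho) - f(x1, mu, rho), (1 - rho) * dx)
    expect_equal(f(mu, x1, rho), -f(x1, mu, rho))
  }
  expect_error(expected_rtm_individual(1, 0, 1.2),
               class = "biotraj_input_error")
})

test_that("cohort RTM estimate matches the truncated-normal oracle", {
  mu <- 100; sigma <- 15; rho <- 0.6; cut <- 115
  # closed form: E[x1 | x1 > 115] = mu + sigma * phi(1)/(1 - Phi(1))
  trunc_mean <- mu + sigma * stats::dnorm(1) / (1 - stats::pnorm(1))
  oracle <- (1 - rho) * (mu - trunc_mean)
  expect_equal(oracle, -9.1504, tolerance = 1e-4)

  deltas <- rhos <- obs <- numeric(5)
  for (s in 1:5) {
    pairs <- simulate_marker_pairs(5000, mu, sigma, rho, seed = 100 + s)
    sel <- pairs$x1 > cut
    est <- estimate_rtm_cohort(pairs, subcohort_x1 = pairs$x1[sel])
    deltas[s] <- est$mean_delta_rtm
    rhos[s] <- est$rho
    obs[s] <- mean(pairs$x2[sel] - pairs$x1[sel])
  }
  expect_equal(mean(deltas), oracle, tolerance = 0.5 / abs(oracle))
  expect_true(all(abs(rhos - rho) < 0.03))
  # with zero intervention effect the observed change IS the RTM change
  expect_lt(max(abs(obs - deltas)), 0.75)
})

test_that("degenerate RTM reference populations are flagged", {
  pairs <- tibble::tibble(x1 = rep(5, 12), x2 = rep(5, 12))
  est <- estimate_rtm_cohort(pairs)
  expect_true(est$degenerate)
  exact <- tibble::tibble(x1 = stats::rnorm(12), x2 = NA_real_)
  exact$x2 <- exact$x1
  est2 <- estimate_rtm_cohort(exact)
  expect_equal(est2$rho, 1)
  expect_equal(est2$mean_delta_rtm, 0)
  expect_error(estimate_rtm_cohort(tibble::tibble(x1 = 1:5, x2 = 1:5)),
               class = "biotraj_input_error")
})

test_that("natural-history comparator recovers drift in optimal users", {
  cfg <- simulation_config(n_subjects = 250, seed = 77, n_draws = 5)
  cfg$markers$ldl$drift <- 6
  cfg$markers$ldl$rho <- 0.95
  sim <- generate_cohort(cfg)
  nh <- natural_history_comparator(sim$dataset, "ldl",
                                   zone_table = sim$zone_table, n_draws = 5)
  expect_gt(nrow(nh$panel), 10)
  means <- nh$trajectory$mean
  # drifting upward from optimal: fitted slope positive
  slope <- stats::coef(stats::lm(means ~ seq_along(means)))[2]
  expect_gt(slope, 0)
  expect_true(any(nh$trajectory$sig_vs_draw1[-1]))
})

test_that("age cross-section recovers a linear age trend within SE", {
  set.seed(55)
  n <- 600
  age <- stats::runif(n, 18, 78)
  value <- 100 + 0.8 * age + stats::rnorm(n, 0, 5)
  subjects <- tibble::tibble(subject_id = sprintf("s%03d", 1:n), sex = "male",
                             age = age, ethnicity = "White", bmi = 25)
  draws <- tibble::tibble(subject_id = subjects$subject_id,
                          draw_date = as.Date("2020-01-01"),
                          marker_id = "ldl", value = value)
  ds <- cohort_dataset(subjects, draws = draws)
  xs <- age_cross_section(ds, "ldl", bin_width_years = 5, min_n = 5)
  mid <- (xs$age_lo + xs$age_hi) / 2
  expect_true(all(abs(xs$mean - (100 + 0.8 * mid)) <= 3 * xs$se + 2))
  # constant cohort: one bin, zero SE
  ds2 <- cohort_dataset(dplyr::mutate(subjects[1:20, ], age = 30),
                        draws = dplyr::mutate(draws[1:20, ], value = 100))
  xs2 <- age_cross_section(ds2, "ldl")
  expect_equal(nrow(xs2), 1)
  expect_equal(xs2$mean, 100)
  expect_equal(xs2$se, 0)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  # hand step-up: p_(i) * m / i, cumulative minimum from the largest
  hand <- rev(cummin(rev(sort(p) * 6 / seq_len(6))))
  expect_equal(adjust_pvalues(sort(p)), hand)
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "biotraj_input_error")
})
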