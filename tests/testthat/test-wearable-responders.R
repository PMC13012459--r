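test_that("responder labelling applies the zone-shift-or-10% rule", {
  # cholesterol-like one-sided spec: optimal below 160, high from 200 up
  spec <- zone_spec(-Inf, -Inf, 160, 200)
  r1 <- label_responder(260, 230, spec)          # -11.5%, still high
  expect_true(r1$responder)
  expect_equal(r1$basis, "pct_change")
  r2 <- label_responder(205, 195, spec)          # high -> normal_high
  expect_true(r2$responder)
  expect_equal(r2$basis, "zone_shift")
  r3 <- label_responder(260, 255, spec)          # -1.9%, same zone
  expect_false(r3$responder)
  expect_equal(r3$basis, "none")
  r4 <- label_responder(260, 190, spec)          # both bases
  expect_equal(r4$basis, "both")
  # below-optimal marker: preferential direction is upward
  spec_lo <- zone_spec(20, 30, Inf, Inf)
  r5 <- label_responder(25, 28, spec_lo)         # +12%, same zone
  expect_true(r5$responder)
  r6 <- label_responder(25, 26, spec_lo)
  expect_false(r6$responder)
  # x1 = 0: percent basis undefined, zone basis only
  r7 <- label_responder(0, 25, spec_lo)
  expect_false(r7$pct_defined)
  expect_true(r7$responder)   # low -> normal_low is a zone shift
})

test_that("responder labelling is monotone in the preferential direction", {
  spec <- zone_spec(-Inf, -Inf, 200, 240)
  x2_grid <- seq(250, 150, by = -5)
  flags <- vapply(x2_grid, function(x2) label_responder(260, x2, spec)$responder,
                  logical(1))
  expect_true(all(diff(flags) >= 0))   # once responder, stays responder
})

test_that("group comparison is Welch, symmetric, and guards small groups", {
  set.seed(19)
  a <- stats::rnorm(30, 10); b <- stats::rnorm(25, 9)
  cmp <- compare_groups(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(cmp$t_statistic, unname(ref$statistic))
  expect_equal(cmp$p_value, ref$p.value)
  swapped <- compare_groups(b, a)
  expect_equal(swapped$t_statistic, -cmp$t_statistic)
  expect_equal(swapped$p_value, cmp$p_value)
  same <- compare_groups(rep(3, 5), rep(3, 7))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), class = "biotraj_input_error")
  tiny <- compare_groups(c(1, 2), c(4, 5, 6))
  expect_true(tiny$small_sample)
})

test_that("step-count contrast at the study effect size is well powered", {
  # the test operates on per-subject step-count *changes* (between-tests
  # window mean minus 30-day baseline mean), daily noise SD 2500
  set.seed(23)
  subject_change <- function(n, delta) {
    base <- stats::rnorm(n, 8700, 1500)
    pre <- base + stats::rnorm(n, 0, 2500 / sqrt(30))
    post <- base + delta + stats::rnorm(n, 0, 2500 / sqrt(90))
    post - pre
  }
  hits <- 0
  reps <- 100
  for (r in 1:reps) {
    a <- subject_change(60, 950)
    b <- subject_change(60, 0)
    hits <- hits + (compare_groups(a, b, alpha = 0.1)$p_value <= 0.1)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("monthly series uses fixed 30-day blocks", {
  start <- as.Date("2021-03-01")
  days <- seq(start, start + 359, by = "day")
  w <- tibble::tibble(subject_id = "a", date = days, steps = 10000,
                      rem_pct = 20, deep_pct = NA_real_,
                      total_sleep_min = NA_real_, rhr = NA_real_,
                      vo2max_est = NA_real_)
  ms <- monthly_series(w, start, months = 12)
  expect_equal(nrow(ms), 12)
  expect_equal(ms$steps, rep(10000, 12))
  # data only in month 3
  w3 <- w[w$date >= start + 60 & w$date < start + 90, ]
  ms3 <- monthly_series(w3, start, months = 12)
  expect_true(all(is.na(ms3$steps[-3])))
  expect_equal(ms3$steps[3], 10000)
  # arithmetic ramp: +100/day -> monthly means step by 3000
  wr <- dplyr::mutate(w, steps = 100 * as.numeric(date - start))
  msr <- monthly_series(wr, start, months = 12)
  expect_equal(diff(msr$steps), rep(3000, 11))
  expect_equal(msr$steps[1], 100 * mean(0:29))
})

test_that("characterization recovers generated step and REM differences", {
  cfg <- simulation_config(n_subjects = 260, seed = 42, p_wearable = 0.9)
  sim <- generate_cohort(cfg)
  rc <- responder_characterization(sim$dataset, "total_cholesterol",
                                   zone_table = sim$zone_table)
  expect_gt(nrow(rc$labels), 20)
  # generated latent responders got stronger intervention effects, so the
  # observed labels should align with truth more often than chance
  truth <- sim$truth
  joined <- dplyr::inner_join(rc$labels, truth, by = "subject_id")
  joined <- joined[!is.na(joined$responder.y), ]
  expect_gt(mean(joined$responder.x == joined$responder.y), 0.6)
  # step-count change differs between groups; baseline steps do not
  chg <- rc$change[rc$change$metric == "steps", ]
  expect_true(chg$significant)
  expect_gt(chg$mean_responders - chg$mean_nonresponders, 300)
  base_rem <- rc$baseline[rc$baseline$metric == "rem_pct", ]
  expect_true(base_rem$significant)
  expect_gt(base_rem$mean_responders, base_rem$mean_nonresponders)
  # monthly output has both groups over 12 months
  expect_setequal(unique(rc$monthly$group), c("responder", "nonresponder"))
})

test_that("characterization reports a diagnostic when nothing is covered", {
  draws <- draw_rows("a", "total_cholesterol", c(0, 100), c(260, 250))
  ds <- make_dataset(draws)
  rc <- responder_characterization(ds, "total_cholesterol")
  expect_match(rc$diagnostic, "no wearable-covered")
})
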