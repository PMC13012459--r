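test_that("inclusion filter requires two draws at least 90 days apart", {
  draws <- dplyr::bind_rows(
    draw_rows("close", "ldl", c(0, 30), c(150, 150)),
    draw_rows("spread", "ldl", c(0, 30, 100), c(150, 150, 150)),
    draw_rows("single", "ldl", 0, 150),
    draw_rows("exact", "ldl", c(0, 90), c(150, 150))
  )
  ds <- make_dataset(draws)
  expect_equal(filter_inclusion(ds), c("exact", "spread"))
  expect_equal(filter_inclusion(ds, min_gap_days = 91), "spread")
  expect_equal(filter_inclusion(make_dataset(draw_rows("a", "ldl", 0, 1))),
               character(0))
})

test_that("IQR fences reproduce brute-force quantile arithmetic", {
  x <- c(1:11, 1000)
  res <- remove_outliers_iqr(x, k = 2)
  # oracle: type-7 quartiles of the 12 sorted values
  q1 <- 3 + 0.75 * (4 - 3)   # h = (12-1)*0.25 + 1 = 3.75
  q3 <- 9 + 0.25 * (10 - 9)  # h = (12-1)*0.75 + 1 = 9.25
  expect_equal(unname(res$fences),
               c(q1 - 2 * (q3 - q1), q3 + 2 * (q3 - q1)))
  expect_equal(res$removed_idx, 12L)
  expect_equal(res$values, 1:11)
})

test_that("IQR removal handles degenerate and limit cases", {
  const <- rep(5, 10)
  expect_equal(remove_outliers_iqr(const)$values, const)
  x <- c(1:11, 1000)
  expect_equal(remove_outliers_iqr(x, k = Inf)$values, x)
  short <- c(1, 2, 1000)
  res <- remove_outliers_iqr(short)
  expect_equal(res$values, short)
  expect_match(res$note, "fewer than 4")
})

test_that("IQR removal never drops the median and is monotone in k", {
  set.seed(99)
  for (rep in 1:20) {
    x <- stats::rcauchy(31)  # heavy tails guarantee removals at small k
    med <- stats::median(x)
    removed <- vapply(c(0.5, 1, 2, 4, 8),
                      function(k) length(remove_outliers_iqr(x, k)$removed_idx),
                      numeric(1))
    expect_false(med %in% x[remove_outliers_iqr(x, 1)$removed_idx])
    expect_true(all(diff(removed) <= 0))
  }
})

test_that("pairing picks the earliest qualifying follow-up", {
  draws <- dplyr::bind_rows(
    draw_rows("a", "ldl", c(0, 100), c(150, 140)),
    draw_rows("b", "ldl", c(0, 50, 95, 200), c(160, 158, 150, 145)),
    draw_rows("c", "ldl", 0, 150)
  )
  pairs <- pair_draws(make_dataset(draws), "ldl")
  expect_equal(sort(pairs$subject_id), c("a", "b"))
  a <- pairs[pairs$subject_id == "a", ]
  expect_equal(c(a$x1, a$x2, a$interval_days), c(150, 140, 100))
  b <- pairs[pairs$subject_id == "b", ]
  expect_equal(c(b$x1, b$x2, b$interval_days), c(160, 150, 95))
})

test_that("pairing and inclusion are insensitive to row order", {
  set.seed(3)
  sim <- generate_cohort(simulation_config(n_subjects = 30, seed = 5))
  ds <- sim$dataset
  shuffled <- ds
  shuffled$draws <- ds$draws[sample(nrow(ds$draws)), ]
  expect_equal(filter_inclusion(shuffled), filter_inclusion(ds))
  p1 <- pair_draws(ds, "ldl")
  p2 <- pair_draws(shuffled, "ldl")
  expect_equal(p2[order(p2$subject_id), ], p1[order(p1$subject_id), ])
})

test_that("matched panels enforce draw counts, baseline side, and gaps", {
  draws <- dplyr::bind_rows(
    draw_rows("p1", "ldl", c(0, 100, 200, 300, 400), c(150, 145, 140, 138, 136)),
    draw_rows("p2", "ldl", c(0, 100, 200, 300, 400), c(160, 150, 148, 146, 150)),
    draw_rows("few", "ldl", c(0, 100, 200, 300), c(150, 145, 140, 138)),
    draw_rows("opt", "ldl", c(0, 100, 200, 300, 400), c(90, 92, 91, 95, 90)),
    # second draw too close: day-50 draw skipped, fifth qualifying missing
    draw_rows("tight", "ldl", c(0, 50, 140, 230, 320), c(150, 149, 148, 147, 146))
  )
  ds <- make_dataset(draws)
  zt <- demo_zone_table()
  panel <- suppressWarnings(
    build_matched_panel(ds, "ldl", "above_optimal", n_draws = 5, zone_table = zt))
  expect_setequal(panel$subjects, c("p1", "p2"))
  expect_equal(dim(panel$values), c(2, 5))
  expect_false(anyNA(panel$values))
  expect_warning(
    build_matched_panel(ds, "ldl", "above_optimal", n_draws = 5,
                        zone_table = zt, min_subjects = 10),
    "only 2 subjects")
})

test_that("two-draw panels agree with pair_draws on shared subjects", {
  sim <- generate_cohort(simulation_config(n_subjects = 60, seed = 21))
  ds <- sim$dataset
  panel <- suppressWarnings(
    build_matched_panel(ds, "ldl", "above_optimal", n_draws = 2,
                        zone_table = sim$zone_table))
  pairs <- pair_draws(ds, "ldl", zone_table = sim$zone_table)
  pairs <- pairs[zone_side(pairs$zone1) == "above", ]
  shared <- intersect(panel$subjects, pairs$subject_id)
  expect_gt(length(shared), 0)
  for (sid in shared) {
    expect_equal(unname(panel$values[sid, ]),
                 unlist(pairs[pairs$subject_id == sid, c("x1", "x2")],
                        use.names = FALSE))
  }
})

test_that("wearable windows average the days before the draw", {
  base <- as.Date("2020-06-01")
  w <- tibble::tibble(subject_id = "a",
                      date = base - c(1, 30, 91),
                      steps = c(8000, 12000, 99999),
                      rem_pct = NA_real_, deep_pct = NA_real_,
                      total_sleep_min = NA_real_, rhr = NA_real_,
                      vo2max_est = NA_real_)
  res <- attach_wearable_window(base, w, window_days = 90)
  steps <- res[res$metric == "steps", ]
  expect_equal(steps$mean, 10000)   # day -91 outside [base-90, base)
  expect_equal(steps$coverage, 2L)
  rem <- res[res$metric == "rem_pct", ]
  expect_true(is.na(rem$mean))
  expect_equal(rem$coverage, 0L)
  none <- attach_wearable_window(base, w[0, ], window_days = 90)
  expect_true(all(is.na(none$mean)))
  expect_true(all(none$coverage == 0))
})
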