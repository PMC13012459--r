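# Small handcrafted fixtures used across test files.

# A dataset with explicitly scripted draws; subjects auto-generated.
make_dataset <- function(draws, wearables = NULL, genotypes = NULL,
                         action_plans = NULL, sex = "male", age = 46) {
  ids <- unique(c(draws$subject_id,
                  if (!is.null(wearables)) wearables$subject_id,
                  if (!is.null(genotypes)) genotypes$subject_id,
                  if (!is.null(action_plans)) action_plans$subject_id))
  subjects <- tibble::tibble(subject_id = ids, sex = sex, age = age,
                             ethnicity = "White", bmi = 25)
  cohort_dataset(subjects, draws = draws, wearables = wearables,
                 genotypes = genotypes, action_plans = action_plans)
}

# Draw rows for one subject at given day offsets from 2020-01-01.
draw_rows <- function(subject_id, marker_id, days, values) {
  tibble::tibble(subject_id = subject_id,
                 draw_date = as.Date("2020-01-01") + days,
                 marker_id = marker_id, value = values)
}

# Canonical two-sided demonstration spec used in zone tests.
demo_spec <- function() zone_spec(40, 50, 71, 91, marker_id = "demo")

# Exhaustive sign-flip oracle for the paired signed-rank test: enumerate
# all 2^n sign assignments of the non-zero differences, build the exact
# distribution of the positive-rank sum, and return the two-sided p for
# the observed statistic. Independent of the package's DP implementation.
signflip_oracle_p <- function(x1, x2) {
  d <- x2 - x1
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(pos) sum(r[unlist(pos)]))
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
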