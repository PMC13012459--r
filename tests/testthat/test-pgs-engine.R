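toy_pgs <- function() {
  pgs_definition("toy", tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    effect_allele = "A",
    beta = c(0.3, -0.2, 0.5),
    gwas_p = c(1e-9, 1e-4, 0.04)))
}

long_geno <- function(doses) {
  # doses: named list subject -> numeric vector over v1..vk (NA = missing)
  dplyr::bind_rows(lapply(names(doses), function(sid) {
    d <- doses[[sid]]
    tibble::tibble(subject_id = sid,
                   variant_id = paste0("v", seq_along(d)), dose = d)
  }))
}

test_that("scores are dose-weighted sums with missing-dose skipping", {
  g <- long_geno(list(a = c(2, 1, 0), b = c(0, 0, 0), c = c(NA, NA, NA),
                      d = c(2, NA, 1)))
  sc <- compute_pgs(g, toy_pgs(), threshold = 1)
  sc <- sc[order(sc$subject_id), ]
  expect_equal(sc$score, c(2 * 0.3 + 1 * -0.2, 0, NA, 2 * 0.3 + 1 * 0.5))
  expect_equal(sc$n_variants_missing, c(0L, 0L, 3L, 1L))
  # thresholding excludes v3 (gwas_p = 0.04 > 0.01): brute-force reduced sum
  sc2 <- compute_pgs(g, toy_pgs(), threshold = 0.01)
  sc2 <- sc2[order(sc2$subject_id), ]
  expect_equal(sc2$score, c(0.4, 0, NA, 0.6))
  expect_error(compute_pgs(g, toy_pgs(), threshold = 0),
               class = "biotraj_input_error")
})

test_that("zero-beta variants and beta scaling behave as invariants require", {
  set.seed(61)
  sim <- simulate_pgs_cohort(80, m = 20, h2 = 0.2, seed = 61)
  base <- compute_pgs(sim$genotypes, sim$pgs)
  with_zero <- sim$pgs
  with_zero$variants <- dplyr::bind_rows(
    with_zero$variants,
    tibble::tibble(variant_id = "vzero", effect_allele = "A", beta = 0,
                   gwas_p = 1e-8))
  g2 <- dplyr::bind_rows(sim$genotypes,
                         tibble::tibble(subject_id = unique(sim$genotypes$subject_id),
                                        variant_id = "vzero", dose = 2))
  expect_equal(compute_pgs(g2, with_zero)$score, base$score)
  scaled <- sim$pgs
  scaled$variants$beta <- scaled$variants$beta * 3
  expect_equal(compute_pgs(sim$genotypes, scaled)$score, 3 * base$score)
})

test_that("proxy resolution honours the LD r-squared cut-off", {
  pm <- tibble::tibble(variant_id = c("v1", "v2"),
                       proxy_id = c("p1", "p2"),
                       r2 = c(0.9, 0.7))
  res <- resolve_variants(toy_pgs(), available = c("p1", "p2", "v3"),
                          proxy_map = pm, r2_min = 0.8)
  expect_equal(res$report$status, c("proxied", "dropped", "kept"))
  expect_equal(sort(res$pgs$variants$variant_id), c("p1", "v3"))
  # proxy inherits the original beta
  expect_equal(res$pgs$variants$beta[res$pgs$variants$variant_id == "p1"], 0.3)
  # all available -> identity
  res2 <- resolve_variants(toy_pgs(), available = c("v1", "v2", "v3"))
  expect_true(all(res2$report$status == "kept"))
  expect_equal(res2$pgs$variants, toy_pgs()$variants)
})

test_that("threshold selection maximizes |correlation| with stringent ties", {
  set.seed(9)
  n <- 200
  # one informative variant only passing the loosest threshold
  g <- tibble::tibble(subject_id = rep(sprintf("s%03d", 1:n), 2),
                      variant_id = rep(c("v1", "v2"), each = n),
                      dose = c(stats::rbinom(n, 2, 0.5), stats::rbinom(n, 2, 0.5)))
  pgs <- pgs_definition("t", tibble::tibble(
    variant_id = c("v1", "v2"), effect_allele = "A",
    beta = c(0, 1), gwas_p = c(1e-9, 0.4)))
  dose_v2 <- g$dose[g$variant_id == "v2"]
  phen <- stats::setNames(2 * dose_v2 + stats::rnorm(n, 0, 0.1),
                          sprintf("s%03d", 1:n))
  sel <- select_threshold(g, pgs, phen, thresholds = c(1e-6, 0.05, 1))
  expect_equal(sel$threshold, 1)
  # identical variant sets across two thresholds -> stringent one wins
  pgs2 <- pgs_definition("t", tibble::tibble(
    variant_id = c("v1", "v2"), effect_allele = "A",
    beta = c(0.5, 1), gwas_p = c(1e-9, 1e-9)))
  sel2 <- select_threshold(g, pgs2, phen, thresholds = c(1e-6, 0.05, 1))
  expect_equal(sel2$threshold, 1e-6)
  expect_equal(length(unique(round(sel2$profile$correlation, 12))), 1)
})

test_that("variance explained is exact on noiseless data and near zero on noise", {
  s <- stats::rnorm(50)
  ve <- suppressWarnings(variance_explained(s, 2 * s + 1))
  expect_equal(ve$r_squared, 1)
  expect_equal(ve$slope, 2)
  set.seed(17)
  ve0 <- variance_explained(stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(ve0$r_squared, 0.01)
  const <- variance_explained(rep(1, 10), stats::rnorm(10))
  expect_true(const$degenerate)
  # invariance under affine transforms of the score
  set.seed(18)
  x <- stats::rnorm(100); y <- x + stats::rnorm(100)
  expect_equal(variance_explained(3 * x - 7, y)$r_squared,
               variance_explained(x, y)$r_squared)
})

test_that("generator heritability is recovered by the regression", {
  r2 <- vapply(1:3, function(s) {
    sim <- simulate_pgs_cohort(2000, m = 100, h2 = 0.10, seed = 400 + s)
    sc <- compute_pgs(sim$genotypes, sim$pgs)
    variance_explained(sc$score[match(names(sim$phenotype), sc$subject_id)],
                       unname(sim$phenotype))$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.10), 0.03)
})

test_that("stratification yields 10/80/10 with boundary ties going outward", {
  st <- stratify_scores(stats::setNames(1:100, paste0("s", 1:100)))
  expect_equal(sum(st$stratum == "T1"), 10)
  expect_equal(sum(st$stratum == "T3"), 10)
  expect_setequal(st$subject_id[st$stratum == "T1"], paste0("s", 1:10))
  expect_setequal(st$subject_id[st$stratum == "T3"], paste0("s", 91:100))
  # brute-force percentile check at n = 20
  st20 <- stratify_scores(stats::setNames(sort(stats::rnorm(20)), paste0("s", 1:20)))
  expect_equal(sum(st20$stratum == "T1"), 2)
  expect_equal(sum(st20$stratum == "T3"), 2)
  # partition property
  expect_equal(nrow(st), 100)
  expect_true(max(st$score[st$stratum == "T1"]) <=
                min(st$score[st$stratum == "T2"]))
  expect_true(max(st$score[st$stratum == "T2"]) <=
                min(st$score[st$stratum == "T3"]))
  expect_warning(stratify_scores(rep(1, 20)), "degenerate")
})

test_that("strata change ANOVA separates unequal stratum effects", {
  set.seed(12)
  n <- 50
  assignments <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:(3 * n)),
    stratum = rep(c("T1", "T2", "T3"), each = n))
  change <- stats::setNames(
    c(stats::rnorm(n, -30, 15), stats::rnorm(n, -20, 15), stats::rnorm(n, -10, 15)),
    assignments$subject_id)
  res <- strata_change_test(assignments, change)
  expect_lt(res$anova$p, 0.005)
  expect_equal(nrow(res$pairwise), 3)
  expect_lt(res$pairwise$p[res$pairwise$contrast == "T1-T3"], 0.005)
  expect_equal(res$strata$n, rep(n, 3))

  flat <- stats::setNames(rep(c(-5, 5), length.out = 3 * n),
                          assignments$subject_id)
  res0 <- strata_change_test(assignments, flat)
  expect_gt(res0$anova$p, 0.9)
})

test_that("two-stratum ANOVA reduces to the squared pooled t statistic", {
  set.seed(13)
  a <- stats::rnorm(30, 0, 1); b <- stats::rnorm(25, 0.7, 1)
  assignments <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:55),
    stratum = rep(c("T1", "T3"), c(30, 25)))
  change <- stats::setNames(c(a, b), assignments$subject_id)
  res <- strata_change_test(assignments, change)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$anova$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$anova$p, tt$p.value, tolerance = 1e-10)
})
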