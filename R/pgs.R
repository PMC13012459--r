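#' Define a polygenic score
#'
#' A PGS is a list of variants with effect alleles, per-allele weights
#' (betas) from GWAS summary statistics, and the source GWAS p-value used
#' for threshold selection.
#'
#' @param trait Trait name.
#' @param variants Data frame: `variant_id`, `effect_allele`, `beta`,
#'   `gwas_p`.
#' @param selected_threshold Optional p-value cut-off already chosen.
#' @return A list of class `pgs_definition`.
#' @export
pgs_definition <- function(trait, variants, selected_threshold = NA_real_) {
  variants <- tibble::as_tibble(variants)
  require_columns(variants, c("variant_id", "effect_allele", "beta", "gwas_p"),
                  "pgs variants")
  if (anyDuplicated(variants$variant_id)) {
    stop_biotraj("input_error", "duplicate variant_id in PGS definition")
  }
  if (any(!is.finite(variants$beta))) {
    stop_biotraj("input_error", "betas must be finite")
  }
  if (any(variants$gwas_p <= 0 | variants$gwas_p > 1)) {
    stop_biotraj("input_error", "gwas_p must lie in (0, 1]")
  }
  structure(list(trait = trait, variants = variants,
                 selected_threshold = selected_threshold),
            class = "pgs_definition")
}

#' @export
print.pgs_definition <- function(x, ...) {
  cat(sprintf("<pgs_definition %s: %d variants, threshold=%s>\n",
              x$trait, nrow(x$variants), format(x$selected_threshold)))
  invisible(x)
}

#' Read PGS weight tables from CSV
#'
#' Expects columns `trait,variant_id,effect_allele,beta,gwas_p`; one
#' [pgs_definition()] is returned per trait.
#'
#' @param path CSV path.
#' @return A named list of `pgs_definition` objects.
#' @export
read_pgs_weights <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(w, c("trait", "variant_id", "effect_allele", "beta", "gwas_p"),
                  "pgs weights")
  traits <- unique(w$trait)
  out <- lapply(traits, function(tr) {
    pgs_definition(tr, w[w$trait == tr,
                         c("variant_id", "effect_allele", "beta", "gwas_p")])
  })
  names(out) <- traits
  out
}

#' Resolve PGS variants against the genotyped variant set
#'
#' Variants absent from the genotyping arrays are replaced by their
#' linkage-disequilibrium proxy when the proxy is itself genotyped and in
#' strong LD (`r_squared > r2_min`, default 0.8); the proxy inherits the
#' original beta. Variants with no adequate proxy are dropped.
#'
#' @param pgs A [pgs_definition()].
#' @param available Character vector of genotyped variant ids.
#' @param proxy_map Data frame `variant_id`, `proxy_id`, `r2` (may be empty
#'   or NULL).
#' @param r2_min LD threshold for accepting a proxy.
#' @return A list: `pgs` (resolved definition) and `report` (tibble with
#'   per-variant `status` in kept/proxied/dropped and `proxy_id`).
#' @export
resolve_variants <- function(pgs, available, proxy_map = NULL, r2_min = 0.8) {
  v <- pgs$variants
  status <- ifelse(v$variant_id %in% available, "kept", "dropped")
  proxy_id <- rep(NA_character_, nrow(v))
  if (!is.null(proxy_map) && nrow(proxy_map) > 0) {
    for (i in which(status == "dropped")) {
      hit <- proxy_map[proxy_map$variant_id == v$variant_id[i] &
                         proxy_map$r2 > r2_min &
                         proxy_map$proxy_id %in% available, , drop = FALSE]
      if (nrow(hit) > 0) {
        best <- hit[which.max(hit$r2), ]
        status[i] <- "proxied"
        proxy_id[i] <- best$proxy_id
      }
    }
  }
  report <- tibble::tibble(variant_id = v$variant_id, status = status,
                           proxy_id = proxy_id)
  resolved <- v[status != "dropped", ]
  swap <- which(status[status != "dropped"] == "proxied")
  resolved$variant_id[swap] <- proxy_id[status != "dropped"][swap]
  list(pgs = pgs_definition(pgs$trait, resolved, pgs$selected_threshold),
       report = report)
}

#' Compute polygenic scores
#'
#' The score is the sum over included variants of effect-allele dose times
#' beta. Variants whose source GWAS p-value exceeds `threshold` are
#' excluded; variants with a missing dose for a subject are skipped (and
#' counted), and a subject with no scored variant gets a missing score, not
#' zero.
#'
#' @param genotypes Long tibble `subject_id`, `variant_id`, `dose`.
#' @param pgs A resolved [pgs_definition()].
#' @param threshold GWAS p-value inclusion threshold in (0, 1].
#' @return A tibble: `subject_id`, `score`, `n_variants_used`,
#'   `n_variants_missing`.
#' @export
compute_pgs <- function(genotypes, pgs, threshold = 1) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_biotraj("input_error", "threshold must lie in (0, 1]")
  }
  v <- pgs$variants[pgs$variants$gwas_p <= threshold, ]
  subjects <- unique(genotypes$subject_id)
  if (nrow(v) == 0) {
    return(tibble::tibble(subject_id = subjects, score = NA_real_,
                          n_variants_used = 0L, n_variants_missing = 0L))
  }
  g <- genotypes[genotypes$variant_id %in% v$variant_id & !is.na(genotypes$dose), ]
  beta <- v$beta[match(g$variant_id, v$variant_id)]
  contrib <- g$dose * beta
  score <- tapply(contrib, g$subject_id, sum)
  used <- tapply(contrib, g$subject_id, length)
  used_n <- as.integer(used[subjects])
  used_n[is.na(used_n)] <- 0L
  out <- tibble::tibble(
    subject_id = subjects,
    score = as.numeric(score[subjects]),
    n_variants_used = used_n,
    n_variants_missing = as.integer(nrow(v)) - used_n
  )
  out$score[out$n_variants_used == 0] <- NA_real_
  out
}

#' Choose the GWAS p-value threshold maximizing PGS-phenotype correlation
#'
#' For each candidate threshold the Pearson correlation between the
#' resulting scores and the baseline phenotype is computed over subjects
#' with both; the candidate with the largest absolute correlation wins,
#' with ties broken toward the more stringent (smaller) threshold.
#' Candidates producing constant scores are skipped.
#'
#' @param genotypes Long genotype tibble.
#' @param pgs A [pgs_definition()].
#' @param phenotype Named numeric vector of baseline phenotype values,
#'   names = subject ids.
#' @param thresholds Candidate grid (>= 2 values).
#' @param min_n Minimum subjects with score and phenotype (default 30).
#' @return A list: `threshold` (winner), `profile` (tibble threshold,
#'   correlation, n).
#' @export
select_threshold <- function(genotypes, pgs, phenotype,
                             thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01,
                                            0.05, 0.1, 0.5, 1),
                             min_n = 30) {
  if (length(thresholds) < 2) {
    stop_biotraj("input_error", "need at least 2 candidate thresholds")
  }
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(th) {
    sc <- compute_pgs(genotypes, pgs, threshold = th)
    ph <- phenotype[sc$subject_id]
    ok <- !is.na(sc$score) & !is.na(ph)
    n <- sum(ok)
    r <- if (n < 2 || stats::sd(sc$score[ok]) == 0 || stats::sd(ph[ok]) == 0)
      NA_real_ else stats::cor(sc$score[ok], ph[ok])
    tibble::tibble(threshold = th, correlation = r, n = n)
  })
  profile <- dplyr::bind_rows(rows)
  usable <- profile[!is.na(profile$correlation) & profile$n >= min_n, ]
  if (nrow(usable) == 0) {
    stop_biotraj("input_error",
                 "no candidate threshold yields a defined correlation on >= ",
                 min_n, " subjects")
  }
  best_abs <- max(abs(usable$correlation))
  winner <- usable$threshold[abs(usable$correlation) >= best_abs - 1e-12][1]
  list(threshold = winner, profile = profile)
}

#' Variance in baseline phenotype explained by a PGS
#'
#' Simple least-squares regression of the phenotype on the score; reports
#' the coefficient of determination and the two-sided slope p-value.
#'
#' @param scores Numeric vector of PGS values.
#' @param phenotype Numeric vector, same length.
#' @return A list: `r_squared`, `p_value`, `slope`, `n`, `degenerate`.
#' @export
variance_explained <- function(scores, phenotype) {
  ok <- is.finite(scores) & is.finite(phenotype)
  if (sum(ok) < 3) stop_biotraj("input_error", "need >= 3 paired observations")
  x <- scores[ok]
  y <- phenotype[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r_squared = NA_real_, p_value = NA_real_, slope = NA_real_,
                n = sum(ok), degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       slope = sm$coefficients["x", "Estimate"],
       n = sum(ok), degenerate = FALSE)
}

#' Stratify polygenic scores into 10/80/10 risk strata
#'
#' Thresholds sit at the 10th and 90th percentiles of the continuous scores
#' (linear-interpolation quantiles). Scores at or below the lower threshold
#' go to T1, at or above the upper threshold to T3, the rest to T2 — ties at
#' a boundary resolve toward the extreme stratum. The strata are commonly
#' labeled "tertiles" in the field despite the 10/80/10 split; the labels
#' T1 (lowest risk) through T3 (highest risk) are kept.
#'
#' @param scores Named numeric vector (names = subject ids) or plain vector.
#' @param fractions Stratum fractions (lowest, middle, highest), summing
#'   to 1.
#' @return A tibble: `subject_id`, `score`, `stratum`; attribute
#'   `degenerate` is TRUE when the two percentile thresholds coincide.
#' @export
stratify_scores <- function(scores, fractions = c(0.10, 0.80, 0.10)) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop_biotraj("config_error", "fractions must be three values summing to 1")
  }
  ok <- is.finite(scores)
  if (sum(ok) < 10) stop_biotraj("input_error", "need at least 10 scores")
  ids <- if (!is.null(names(scores))) names(scores) else
    as.character(seq_along(scores))
  s <- scores[ok]
  lo <- stats::quantile(s, fractions[1], names = FALSE, type = 7)
  hi <- stats::quantile(s, 1 - fractions[3], names = FALSE, type = 7)
  stratum <- ifelse(s <= lo, "T1", ifelse(s >= hi, "T3", "T2"))
  out <- tibble::tibble(subject_id = ids[ok], score = unname(s),
                        stratum = stratum)
  attr(out, "degenerate") <- lo >= hi
  if (lo >= hi) {
    warning("degenerate stratification: the 10th and 90th percentile thresholds coincide",
            call. = FALSE)
  }
  out
}

#' Test biomarker change across PGS strata
#'
#' One-way analysis of variance of per-subject longitudinal change across
#' the T1/T2/T3 strata, with pairwise two-tailed Welch t-tests and
#' per-stratum means and standard errors. Intended for the out-of-range-at-
#' baseline subcohort (change = follow-up minus baseline).
#'
#' @param assignments Tibble from [stratify_scores()] (`subject_id`,
#'   `stratum`).
#' @param change Named numeric vector of per-subject change values, names =
#'   subject ids.
#' @return A list: `anova` (`f`, `p`), `strata` (tibble stratum, mean, se,
#'   n), `pairwise` (tibble contrast, t, p), `skipped` (character, strata
#'   with < 2 subjects).
#' @export
strata_change_test <- function(assignments, change) {
  df <- tibble::tibble(stratum = assignments$stratum,
                       change = as.numeric(change[assignments$subject_id]))
  df <- df[is.finite(df$change), ]
  counts <- table(df$stratum)
  skipped <- names(counts)[counts < 2]
  keep <- setdiff(names(counts), skipped)
  df <- df[df$stratum %in% keep, ]
  if (length(keep) < 2) {
    stop_biotraj("input_error",
                 "need at least 2 strata with >= 2 change values each")
  }
  fit <- stats::aov(change ~ factor(stratum), data = df)
  tab <- summary(fit)[[1]]
  strata_summary <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(mean = mean(.data$change),
                     se = stats::sd(.data$change) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  combos <- utils::combn(sort(keep), 2, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(combos, function(pr) {
    a <- df$change[df$stratum == pr[1]]
    b <- df$change[df$stratum == pr[2]]
    tt <- stats::t.test(a, b)  # Welch by default
    tibble::tibble(contrast = paste(pr[1], pr[2], sep = "-"),
                   t = unname(tt$statistic), p = tt$p.value)
  }))
  list(anova = list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1]),
       strata = strata_summary, pairwise = pairwise, skipped = skipped)
}
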