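## Built-in simulation studies. These are the package's validation
## experiments: they exercise the full generator -> distance -> filtration ->
## inference path on replicate synthetic cohorts and return per-replicate
## summaries. Problem sizes default to values that keep each study in the
## low minutes on a single core; the methods vignette discusses the choices.

study_seeds <- function(seed, n) with_seed(seed, sample.int(2147483646L, n))

#' Type-I calibration study on null cohorts
#'
#' Generates replicate null cohorts (identical data-generating distribution
#' in both groups: two latent blocks, no planted edges) and runs the SLD
#' permutation test and the barcode-slope t test on each. On null data the
#' edge-wise rejection rate should match `alpha` and the slope test should
#' reject at its nominal level.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param n_per_group subjects per group in each cohort.
#' @param n_rois,n_trials cohort dimensions.
#' @param n_permutations permutations per test.
#' @param alpha edge-wise (and slope-test) significance level.
#' @param window barcode-slope component-count window.
#' @param seed master seed; each cohort gets an independent derived seed.
#' @return list with `edge_rejection_rates` (per-cohort fraction of edges
#'   with `p < alpha`), `slope_p` (per-cohort slope-test p-values), `alpha`,
#'   and `n_edges`.
#' @export
calibration_study <- function(n_cohorts = 200L, n_per_group = c(10L, 10L),
                              n_rois = 20L, n_trials = 100L,
                              n_permutations = 500L, alpha = 0.05,
                              window = c(11L, 66L), seed = 1L) {
  seeds <- study_seeds(seed, 2L * n_cohorts)
  rates <- numeric(n_cohorts)
  slope_p <- numeric(n_cohorts)
  n_edges <- n_rois * (n_rois - 1L) / 2L
  for (r in seq_len(n_cohorts)) {
    spec <- cohort_spec(
      n_per_group = n_per_group, n_trials = n_trials, n_rois = n_rois,
      blocks = list(list(rois = 1:5, r_within = 0.6),
                    list(rois = 6:10, r_within = 0.6)),
      r_between = 0.2, seed = seeds[r])
    cohort <- generate_cohort(spec)
    g1 <- cohort$group == "group1"
    sl <- lapply(cohort$power, function(pm) single_linkage(pearson_distance(pm)))
    slms <- lapply(sl, `[[`, "slm")
    pt <- slm_permutation_test(slms[g1], slms[!g1],
                               n_permutations = n_permutations, alpha = alpha,
                               seed = seeds[n_cohorts + r])
    rates[r] <- mean(pt$edges$p_value < alpha)
    slopes <- vapply(cohort$power, function(pm)
      barcode_slope(barcode(pearson_distance(pm)), window = window)$slope,
      numeric(1))
    slope_p[r] <- compare_barcode_slopes(slopes[g1], slopes[!g1])$p_value
  }
  list(edge_rejection_rates = rates, slope_p = slope_p, alpha = alpha,
       n_edges = n_edges, n_cohorts = n_cohorts)
}

#' Planted-effect recovery study
#'
#' Generates replicate cohorts in which one within-block edge of group 2 is
#' attenuated, and checks whether the permutation test recovers it: the
#' planted edge should show a longer mean SLD in group 2 (positive observed
#' difference) and should attain the smallest p-value among all edges (ties
#' at the attainable minimum count as attaining it).
#'
#' @param n_cohorts number of replicate cohorts.
#' @param n_per_group subjects per group.
#' @param n_rois block size; the single latent block spans all ROIs and the
#'   planted edge is (1, 2).
#' @param n_trials trials per subject.
#' @param r_within within-block latent correlation.
#' @param attenuation planted attenuation on edge (1, 2) in group 2.
#' @param n_permutations permutations per cohort.
#' @param seed master seed.
#' @return data frame with one row per cohort: `observed_diff` (planted
#'   edge), `longer` (diff > 0), `p_planted`, `smallest_p`.
#' @export
recovery_study <- function(n_cohorts = 100L, n_per_group = c(15L, 15L),
                           n_rois = 6L, n_trials = 200L, r_within = 0.8,
                           attenuation = 0.9, n_permutations = 1000L,
                           seed = 1L) {
  seeds <- study_seeds(seed, 2L * n_cohorts)
  out <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    spec <- cohort_spec(
      n_per_group = n_per_group, n_trials = n_trials, n_rois = n_rois,
      blocks = list(list(rois = seq_len(n_rois), r_within = r_within)),
      planted_edges = data.frame(i = 1L, j = 2L, attenuation = attenuation),
      seed = seeds[r])
    cohort <- generate_cohort(spec)
    g1 <- cohort$group == "group1"
    slms <- lapply(cohort$power, function(pm)
      single_linkage(pearson_distance(pm))$slm)
    pt <- slm_permutation_test(slms[g1], slms[!g1],
                               n_permutations = n_permutations,
                               seed = seeds[n_cohorts + r])
    planted <- which(pt$edges$i == 1L & pt$edges$j == 2L)
    out[[r]] <- data.frame(
      observed_diff = pt$edges$observed_diff[planted],
      longer = pt$edges$observed_diff[planted] > 0,
      p_planted = pt$edges$p_value[planted],
      smallest_p = pt$edges$p_value[planted] == min(pt$edges$p_value))
  }
  do.call(rbind, out)
}

#' Clinical-coupling recovery study
#'
#' Generates replicate cohorts whose group-2 subjects carry heterogeneous
#' planted effects coupled to a synthetic disease-duration covariate
#' (`duration = U(baseline) + coefficient * effect`), and computes the
#' Pearson correlation between the planted edge's SLD and duration across
#' group-2 subjects. With positive coupling the correlation should be
#' positive in the large majority of replicates.
#'
#' @inheritParams recovery_study
#' @param coefficient coupling slope between the effect scalar and duration.
#' @param baseline uniform baseline range of the duration covariate (years).
#' @return data frame with one row per cohort: `r` (SLD-duration Pearson
#'   correlation in group 2) and `positive`.
#' @export
clinical_study <- function(n_cohorts = 100L, n_per_group = c(10L, 30L),
                           n_rois = 6L, n_trials = 200L, r_within = 0.8,
                           attenuation = 0.9, coefficient = 8,
                           baseline = c(0.25, 2), seed = 1L) {
  seeds <- study_seeds(seed, n_cohorts)
  out <- vector("list", n_cohorts)
  for (r in seq_len(n_cohorts)) {
    spec <- cohort_spec(
      n_per_group = n_per_group, n_trials = n_trials, n_rois = n_rois,
      blocks = list(list(rois = seq_len(n_rois), r_within = r_within)),
      planted_edges = data.frame(i = 1L, j = 2L, attenuation = attenuation),
      clinical = list(covariate = "duration", coefficient = coefficient,
                      baseline = baseline),
      seed = seeds[r])
    cohort <- generate_cohort(spec)
    g2 <- cohort$group == "group2"
    slms <- lapply(cohort$power[g2], function(pm)
      single_linkage(pearson_distance(pm))$slm)
    cc <- clinical_correlations(slms, data.frame(i = 1L, j = 2L),
                                cohort$covariates[g2, , drop = FALSE],
                                alpha = 0.05, family_size = 1L)
    rec <- cc$records[cc$records$covariate == "duration", ]
    out[[r]] <- data.frame(r = rec$r, positive = rec$r > 0)
  }
  do.call(rbind, out)
}
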