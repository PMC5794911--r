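test_that("slope comparison matches the textbook pooled-variance t test", {
  a <- c(-10, -12, -11); b <- c(-6, -7, -8)
  res <- compare_barcode_slopes(a, b)
  oracle <- oracle_pooled_t(a, b)
  expect_equal(res$t_statistic, oracle$t)
  expect_equal(res$degrees_of_freedom, oracle$df)
  expect_equal(res$p_value, oracle$p)
  expect_equal(res$group_means, c(-11, -7))

  ## identical groups: t = 0, p = 1
  same <- compare_barcode_slopes(c(-5, -6, -7), c(-5, -6, -7))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_barcode_slopes(c(0, 0), c(1, 1)), "pooled variance")
  expect_error(compare_barcode_slopes(-1, c(1, 2)), "at least 2")

  ## Welch variant is exposed
  w <- compare_barcode_slopes(a, c(b, -20), var_equal = FALSE)
  expect_false(w$var_equal)
  expect_lt(w$degrees_of_freedom, 5)
})

make_slm <- function(d) single_linkage(d)$slm

test_that("permutation test is exchangeable-null safe and respects bounds", {
  set.seed(14)
  slms <- lapply(1:4, function(i) make_slm(rand_dist(5)))
  ## both groups the same multiset: zero differences, p = 1 everywhere
  res <- slm_permutation_test(slms, slms, n_permutations = 100, alpha = 0.05,
                              seed = 1)
  expect_true(all(res$edges$observed_diff == 0))
  expect_true(all(res$edges$p_value == 1))
  expect_true(all(res$edges$p_value > 0 & res$edges$p_value <= 1))
  expect_identical(res$edges$significant, res$edges$p_value < res$alpha)
  expect_equal(nrow(res$edges), choose(5, 2))

  ## mismatched ROI labels abort
  bad <- make_slm(rand_dist(5) * 1)
  colnames(bad) <- rownames(bad) <- letters[1:5]
  expect_error(slm_permutation_test(slms, list(bad), n_permutations = 10),
               "labels")
})

test_that("permutation observed statistics are invariant to within-group order", {
  set.seed(15)
  slms_a <- lapply(1:5, function(i) make_slm(rand_dist(6)))
  slms_b <- lapply(1:5, function(i) make_slm(rand_dist(6)))
  r1 <- slm_permutation_test(slms_a, slms_b, n_permutations = 4000, seed = 2)
  r2 <- slm_permutation_test(slms_a[c(3, 1, 5, 2, 4)], slms_b[c(2, 5, 1, 4, 3)],
                             n_permutations = 4000, seed = 2)
  expect_equal(r1$edges$observed_diff, r2$edges$observed_diff)
  ## Monte-Carlo p-values agree within sampling error of each other
  se <- sqrt(r1$edges$p_value * (1 - r1$edges$p_value) / 4000)
  expect_true(all(abs(r1$edges$p_value - r2$edges$p_value) <=
                    4 * se + 2 / 4001))
})

test_that("Monte-Carlo p agrees with the exhaustive relabelling distribution", {
  ## 3 vs 3 subjects, strong separation on the planted edge
  spec <- cohort_spec(n_per_group = c(3, 3), n_trials = 200, n_rois = 4,
                      blocks = list(list(rois = 1:4, r_within = 0.8)),
                      planted_edges = data.frame(i = 1, j = 2,
                                                 attenuation = 0.95),
                      seed = 4)
  co <- generate_cohort(spec)
  slms <- cohort_slms(co)
  g1 <- co$group == "group1"
  S <- rbind(t(vapply(slms[g1], function(m) m[upper.tri(m)], numeric(6))),
             t(vapply(slms[!g1], function(m) m[upper.tri(m)], numeric(6))))
  exhaustive <- oracle_exhaustive_perm(S, nA = 3)
  expect_length(exhaustive, 6)

  res <- slm_permutation_test(slms[g1], slms[!g1], n_permutations = 10000,
                              seed = 6)
  se <- sqrt(exhaustive * (1 - exhaustive) / 10000)
  expect_true(all(abs(res$edges$p_value - exhaustive) <= 3 * se + 2 / 10001))
})

test_that("edgewise shuffling variant is available for sensitivity analysis", {
  set.seed(16)
  slms_a <- lapply(1:4, function(i) make_slm(rand_dist(4)))
  slms_b <- lapply(1:4, function(i) make_slm(rand_dist(4)))
  res <- slm_permutation_test(slms_a, slms_b, n_permutations = 200, seed = 3,
                              method = "edgewise")
  expect_true(all(res$edges$p_value > 0 & res$edges$p_value <= 1))
  expect_identical(res$method, "edgewise")
})

test_that("clinical correlations recover exact and hand-computed relations", {
  ## build ultrametric SLMs whose (1,2) SLD is an affine map of the covariate
  slds <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  slms <- lapply(slds, function(s) {
    d <- matrix(0.9, 3, 3); d[1, 2] <- d[2, 1] <- s; diag(d) <- 0
    dimnames(d) <- list(c("x", "y", "z"), c("x", "y", "z"))
    make_slm(d)
  })
  covs <- data.frame(subject_id = sprintf("S%d", 1:5),
                     affine = 10 + 3 * slds,
                     ranked = c(1, 3, 2, 5, 4),
                     flat = rep(2, 5))
  res <- clinical_correlations(slms, data.frame(i = 1, j = 2), covs,
                               alpha = 0.05, family_size = 36)
  expect_equal(res$corrected_alpha, 0.05 / 36)
  rec <- res$records
  expect_equal(rec$r[rec$covariate == "affine"], 1)
  ## SLDs (0.1..0.5) against (1,3,2,5,4): r = 0.8 by the Pearson formula
  expect_equal(rec$r[rec$covariate == "ranked"], 0.8)
  ## degenerate covariate is flagged, not dropped
  expect_true(rec$degenerate[rec$covariate == "flat"])
  expect_true(is.na(rec$r[rec$covariate == "flat"]))
  expect_equal(nrow(rec), 3)

  expect_error(clinical_correlations(slms, data.frame(i = 1, j = 2), covs,
                                     alpha = 0.05), "family_size")
  expect_error(clinical_correlations(slms[1:2], data.frame(i = 1, j = 2),
                                     covs[1:2, ], alpha = 0.05,
                                     family_size = 1), "at least 3")
})
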