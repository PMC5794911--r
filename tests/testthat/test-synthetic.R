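test_that("block latent correlation matches direct construction and planting", {
  spec <- cohort_spec(n_per_group = c(3, 3), n_trials = 10, n_rois = 4,
                      blocks = list(list(rois = 1:4, r_within = 0.6)),
                      planted_edges = data.frame(i = 1, j = 2, attenuation = 1),
                      seed = 1)
  C1 <- build_latent_correlation(spec, group = 1)
  expect_false(attr(C1, "psd_repaired"))
  expect_equal(unname(diag(C1)), rep(1, 4))
  expect_true(all(C1[upper.tri(C1)] == 0.6))

  C2 <- build_latent_correlation(spec, group = 2)
  expect_false(attr(C2, "psd_repaired"))
  expect_identical(C2[1, 2], 0)
  keep <- upper.tri(C2); keep[1, 2] <- FALSE
  expect_true(all(C2[keep] == C1[keep]))
})

test_that("two-block latent structure is positive definite", {
  spec <- cohort_spec(n_per_group = c(2, 2), n_trials = 10, n_rois = 6,
                      blocks = list(list(rois = 1:3, r_within = 0.7),
                                    list(rois = 4:6, r_within = 0.7)),
                      r_between = 0.2, seed = 1)
  C <- build_latent_correlation(spec)
  expect_false(attr(C, "psd_repaired"))
  expect_gt(min(eigen(C, symmetric = TRUE)$values), 0)
})

test_that("infeasible planting triggers a reported PSD repair", {
  ## a 0.08 correlation inside an otherwise 0.8-coupled block cannot be PSD
  spec <- cohort_spec(n_per_group = c(2, 2), n_trials = 10, n_rois = 6,
                      blocks = list(list(rois = 1:6, r_within = 0.8)),
                      planted_edges = data.frame(i = 1, j = 2, attenuation = 0.9),
                      seed = 1)
  expect_message(C2 <- build_latent_correlation(spec, group = 2),
                 "repaired")
  expect_true(attr(C2, "psd_repaired"))
  expect_lt(attr(C2, "min_eigenvalue"), 0)
  expect_gte(min(eigen(C2, symmetric = TRUE)$values), -1e-10)
  expect_equal(unname(diag(C2)), rep(1, 6))
  ## repair pulls the planted entry up, but it stays the weakest edge
  expect_lt(C2[1, 2], min(C2[upper.tri(C2)][-1]))
})

test_that("spec validation rejects malformed inputs", {
  expect_error(cohort_spec(n_rois = 6, blocks = list(
    list(rois = 1:4, r_within = 0.5), list(rois = 4:6, r_within = 0.5))),
    "overlap")
  expect_error(cohort_spec(n_rois = 4, planted_edges =
    data.frame(i = 2, j = 2, attenuation = 0.5)), "distinct")
  expect_error(cohort_spec(n_rois = 4, planted_edges =
    data.frame(i = 1, j = 2, attenuation = 1.5)), "attenuation")
  expect_error(cohort_spec(n_trials = 2), "n_trials")
})

test_that("power generation is seeded, positive, and tracks the latent structure", {
  ## independent ROIs: all sample correlations near zero
  pm <- generate_power_matrix(diag(6), n_trials = 1000, seed = 101)
  expect_true(all(pm > 0))
  r <- cor(log(unclass(pm)))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)

  ## bit-identical under the same seed; different under another
  pm2 <- generate_power_matrix(diag(6), n_trials = 1000, seed = 101)
  expect_identical(unclass(pm), unclass(pm2))
  pm3 <- generate_power_matrix(diag(6), n_trials = 1000, seed = 102)
  expect_false(identical(unclass(pm), unclass(pm3)))

  ## perfectly coupled latents give log-power correlation 1 (singular corr ok)
  C <- matrix(1, 2, 2)
  pm4 <- generate_power_matrix(C, n_trials = 50, seed = 3)
  expect_equal(cor(log(pm4[, 1]), log(pm4[, 2])), 1)

  expect_error(generate_power_matrix(matrix(c(1, 2, 2, 1), 2), 10, seed = 1),
               "positive semi-definite")
  expect_error(generate_power_matrix(diag(2), 2, seed = 1), "n_trials")
})

test_that("cohorts respect group sizes, shared labels, and the null case", {
  spec <- cohort_spec(n_per_group = c(4, 5), n_trials = 20, n_rois = 5,
                      blocks = list(list(rois = 1:5, r_within = 0.5)),
                      planted_edges = data.frame(i = 1, j = 2, attenuation = 0),
                      seed = 9)
  co <- generate_cohort(spec)
  expect_identical(as.integer(table(co$group)), c(4L, 5L))
  labs <- lapply(co$power, colnames)
  expect_true(all(vapply(labs, identical, logical(1), labs[[1]])))
  ## zero attenuation: both groups share the same latent correlation
  expect_equal(unclass(build_latent_correlation(spec, 1)),
               unclass(build_latent_correlation(spec, 2)))
  ## seeded reproducibility of the whole cohort
  co2 <- generate_cohort(spec)
  expect_identical(lapply(co$power, unclass), lapply(co2$power, unclass))
})

test_that("clinical coupling links the effect scalar to the covariate", {
  spec <- cohort_spec(n_per_group = c(5, 30), n_trials = 10, n_rois = 4,
                      blocks = list(list(rois = 1:4, r_within = 0.6)),
                      planted_edges = data.frame(i = 1, j = 2, attenuation = 0.8),
                      clinical = list(covariate = "duration", coefficient = 8,
                                      baseline = c(0.25, 2)),
                      seed = 11)
  co <- generate_cohort(spec)
  g2 <- co$group == "group2"
  expect_true(all(co$effect[!g2] == 0))
  expect_true(all(co$effect[g2] >= 0 & co$effect[g2] <= 1))
  expect_gt(cor(co$effect[g2], co$covariates$duration[g2]), 0)
})

test_that("larger attenuation widens the planted edge's distance gap", {
  gap <- vapply(c(0, 0.5, 0.9), function(att) {
    diffs <- vapply(1:8, function(rep) {
      spec <- cohort_spec(n_per_group = c(6, 6), n_trials = 100, n_rois = 6,
                          blocks = list(list(rois = 1:6, r_within = 0.8)),
                          planted_edges = data.frame(i = 1, j = 2,
                                                     attenuation = att),
                          seed = 1000 + rep)
      co <- generate_cohort(spec)
      d12 <- vapply(co$power, function(pm) pearson_distance(pm)[1, 2], numeric(1))
      mean(d12[co$group == "group2"]) - mean(d12[co$group == "group1"])
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})
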