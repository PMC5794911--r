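#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of trial-by-ROI band-power matrices with a block
#' (community) latent correlation structure, optional planted
#' attenuated-connectivity edges in group 2, and optional clinical covariates
#' coupled to the planted effect. The defaults mirror a typical resting-state
#' MEG band-power study: 19 vs 18 subjects, 200 one-second trials, 76 cortical
#' ROIs.
#'
#' @param n_per_group integer pair: subjects in group 1 (e.g. controls) and
#'   group 2 (e.g. patients).
#' @param n_trials trials per subject (>= 3).
#' @param n_rois number of ROIs.
#' @param blocks list of blocks, each `list(rois = <indices>, r_within = r)`
#'   with `r_within` in `[0, 1)`; blocks must be disjoint.
#' @param r_between latent correlation between ROIs not in the same block, in
#'   `[0, min(r_within)]`.
#' @param planted_edges `NULL` or data frame with columns `i`, `j`,
#'   `attenuation`: group 2's latent correlation on edge `(i, j)` is
#'   multiplied by `1 - attenuation`, `attenuation` in `[0, 1]`.
#' @param noise_sd standard deviation of independent Gaussian noise added to
#'   the latent signal before exponentiation (>= 0).
#' @param clinical `NULL` or `list(covariate = <name>, coefficient = <slope>,
#'   baseline = c(lo, hi), noise_sd = <sd>, effect_range = c(lo, hi))`. When
#'   present, each group-2 subject receives an effect scalar
#'   `e ~ U(effect_range)` (default `U(0, 1)`; a severity heterogeneity dial)
#'   that scales the planted attenuation, and every subject's covariate is
#'   drawn as `U(lo, hi) + coefficient * e` (+ optional Gaussian noise);
#'   group 1 has `e = 0`.
#' @param roi_labels character vector of unique ROI labels.
#' @param seed integer seed making the cohort reproducible.
#' @return validated list of class `"cohort_spec"`.
#' @seealso [generate_cohort()], [build_latent_correlation()]
#' @export
cohort_spec <- function(n_per_group = c(19L, 18L), n_trials = 200L,
                        n_rois = 76L, blocks = list(), r_between = 0,
                        planted_edges = NULL, noise_sd = 0, clinical = NULL,
                        roi_labels = sprintf("R%02d", seq_len(n_rois)),
                        seed = 1L) {
  spec <- structure(
    list(n_per_group = as.integer(n_per_group), n_trials = as.integer(n_trials),
         n_rois = as.integer(n_rois), blocks = blocks, r_between = r_between,
         planted_edges = planted_edges, noise_sd = noise_sd,
         clinical = clinical, roi_labels = as.character(roi_labels),
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (length(n_per_group) != 2L || any(n_per_group < 1L))
      stop("n_per_group must be two positive integers", call. = FALSE)
    if (n_trials < 3L) stop("n_trials must be >= 3", call. = FALSE)
    if (n_rois < 2L) stop("n_rois must be >= 2", call. = FALSE)
    if (length(roi_labels) != n_rois || anyDuplicated(roi_labels))
      stop("roi_labels must be ", n_rois, " unique labels", call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
    used <- integer(0)
    r_within_min <- 1
    for (b in blocks) {
      if (is.null(b$rois) || is.null(b$r_within))
        stop("each block needs 'rois' and 'r_within'", call. = FALSE)
      if (any(b$rois < 1L | b$rois > n_rois))
        stop("block ROI indices out of range", call. = FALSE)
      if (any(b$rois %in% used))
        stop("blocks overlap: ROI ",
             paste(intersect(b$rois, used), collapse = ", "),
             " appears in more than one block", call. = FALSE)
      if (b$r_within < 0 || b$r_within >= 1)
        stop("r_within must lie in [0, 1)", call. = FALSE)
      used <- c(used, b$rois)
      r_within_min <- min(r_within_min, b$r_within)
    }
    if (r_between < 0 || r_between >= 1 ||
        (length(blocks) > 0L && r_between > r_within_min))
      stop("r_between must lie in [0, min(r_within)]", call. = FALSE)
    if (!is.null(planted_edges)) {
      pe <- planted_edges
      if (!all(c("i", "j", "attenuation") %in% names(pe)))
        stop("planted_edges needs columns i, j, attenuation", call. = FALSE)
      if (any(pe$i == pe$j))
        stop("planted edges must join distinct ROIs (i != j)", call. = FALSE)
      if (any(pe$i < 1L | pe$i > n_rois | pe$j < 1L | pe$j > n_rois))
        stop("planted edge ROI indices out of range", call. = FALSE)
      key <- paste(pmin(pe$i, pe$j), pmax(pe$i, pe$j))
      if (anyDuplicated(key))
        stop("planted edges must reference distinct ROI pairs", call. = FALSE)
      if (any(pe$attenuation < 0 | pe$attenuation > 1))
        stop("attenuation must lie in [0, 1]", call. = FALSE)
    }
    if (!is.null(clinical)) {
      if (is.null(clinical$covariate) || is.null(clinical$coefficient))
        stop("clinical coupling needs 'covariate' and 'coefficient'",
             call. = FALSE)
      er <- clinical$effect_range %||% c(0, 1)
      if (length(er) != 2L || er[1L] < 0 || er[2L] > 1 || er[1L] > er[2L])
        stop("clinical$effect_range must be an increasing pair within [0, 1]",
             call. = FALSE)
    }
  })
  invisible(spec)
}

#' Latent inter-ROI correlation matrix for one group
#'
#' Builds the block-structured latent correlation implied by a
#' [cohort_spec()]: `r_within` inside each block, `r_between` elsewhere, unit
#' diagonal. For group 2 each planted edge `(i, j)` is attenuated to
#' `r * (1 - attenuation * effect)`. If the planted matrix is no longer
#' positive semi-definite (strong attenuation inside a tight block makes this
#' unavoidable), it is repaired by clipping negative eigenvalues at zero and
#' rescaling to a unit diagonal; the repair is reported via a message and the
#' `psd_repaired` attribute, since it slightly perturbs entries other than
#' the planted one.
#'
#' @param spec a [cohort_spec()].
#' @param group 1 or 2; planted edges apply only to group 2.
#' @param effect scalar in `[0, 1]` multiplying all attenuations (the
#'   subject-level effect scalar used for clinical coupling).
#' @param quiet suppress the repair message (the repair attribute is always
#'   set).
#' @return correlation matrix with attributes `psd_repaired` (logical) and,
#'   when repaired, `min_eigenvalue` (the smallest eigenvalue before repair).
#' @export
build_latent_correlation <- function(spec, group = 1L, effect = 1, quiet = FALSE) {
  validate_cohort_spec(spec)
  if (!group %in% c(1L, 2L)) stop("group must be 1 or 2", call. = FALSE)
  if (effect < 0 || effect > 1) stop("effect must lie in [0, 1]", call. = FALSE)
  p <- spec$n_rois
  C <- matrix(spec$r_between, p, p)
  for (b in spec$blocks) C[b$rois, b$rois] <- b$r_within
  diag(C) <- 1
  dimnames(C) <- list(spec$roi_labels, spec$roi_labels)
  if (group == 2L && !is.null(spec$planted_edges)) {
    pe <- spec$planted_edges
    for (k in seq_len(nrow(pe))) {
      i <- pe$i[k]; j <- pe$j[k]
      C[i, j] <- C[j, i] <- C[i, j] * (1 - pe$attenuation[k] * effect)
    }
  }
  ev <- eigen(C, symmetric = TRUE)
  min_ev <- min(ev$values)
  repaired <- min_ev < -1e-10
  if (repaired) {
    C2 <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    C <- stats::cov2cor(C2)
    C <- (C + t(C)) / 2
    diag(C) <- 1
    dimnames(C) <- list(spec$roi_labels, spec$roi_labels)
    if (!quiet)
      message(sprintf(
        "latent correlation repaired to positive semi-definite (min eigenvalue %.4g clipped)",
        min_ev))
  }
  structure(C, psd_repaired = repaired,
            min_eigenvalue = if (repaired) min_ev else NULL)
}

#' Simulate one subject's trial-by-ROI power matrix
#'
#' Draws `n_trials` latent Gaussian vectors with the given correlation (via
#' the symmetric eigen square root, so positive semi-definite but singular
#' correlations are allowed), adds independent Gaussian noise of standard
#' deviation `noise_sd`, and exponentiates, yielding strictly positive
#' log-normal band power. Note the sample Pearson correlation of log-normal
#' power is an attenuated, monotone transform of the latent correlation, not
#' equal to it.
#'
#' @param latent_corr positive semi-definite correlation matrix.
#' @param n_trials number of trials (>= 3).
#' @param noise_sd non-negative noise standard deviation.
#' @param seed integer seed; the same seed reproduces the matrix bit for bit.
#' @param subject_id,band passed to [power_matrix()].
#' @return a [power_matrix()].
#' @export
generate_power_matrix <- function(latent_corr, n_trials, noise_sd = 0,
                                  seed = NULL, subject_id = "", band = "") {
  C <- as.matrix(latent_corr)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop("latent_corr must be a symmetric square matrix", call. = FALSE)
  if (n_trials < 3L) stop("n_trials must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(1, abs(ev$values[1L])))
    stop("latent_corr is not positive semi-definite (min eigenvalue ",
         format(min(ev$values)), ")", call. = FALSE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  p <- ncol(C)
  vals <- with_seed(seed, {
    lat <- matrix(stats::rnorm(n_trials * p), n_trials, p) %*% rt
    if (noise_sd > 0)
      lat <- lat + matrix(stats::rnorm(n_trials * p, sd = noise_sd), n_trials, p)
    exp(lat)
  })
  power_matrix(vals, roi_labels = colnames(C) %||% sprintf("R%02d", seq_len(p)),
               subject_id = subject_id, band = band)
}

#' Generate a synthetic two-group cohort
#'
#' Draws every subject's power matrix from the group's latent correlation
#' (group 2 with planted attenuated edges), together with clinical covariates
#' and a provenance record. When clinical coupling is specified, group-2
#' subjects receive heterogeneous effect scalars `e ~ U(0, 1)` scaling the
#' planted attenuation, and the covariate is
#' `U(baseline) + coefficient * e (+ noise)`; without coupling all group-2
#' subjects carry the full planted effect (`e = 1`).
#'
#' @param spec a [cohort_spec()].
#' @param band frequency-band label attached to each power matrix.
#' @return object of class `"phnet_cohort"`: list with `power` (named list of
#'   [power_matrix()]), `group` (factor `group1`/`group2`), `covariates`
#'   (data frame, one row per subject), `effect` (subject effect scalars),
#'   `roi_labels`, `spec` and `provenance` (seed, config hash, whether PSD
#'   repair fired).
#' @export
generate_cohort <- function(spec, band = "") {
  validate_cohort_spec(spec)
  n <- sum(spec$n_per_group)
  group <- factor(rep(c("group1", "group2"), spec$n_per_group),
                  levels = c("group1", "group2"))
  ids <- sprintf("S%03d", seq_len(n))
  coupled <- !is.null(spec$clinical)

  drawn <- with_seed(spec$seed, {
    sub_seeds <- sample.int(2147483646L, n)
    effect <- ifelse(group == "group2", 1, 0)
    if (coupled) {
      er <- spec$clinical$effect_range %||% c(0, 1)
      effect[group == "group2"] <- stats::runif(spec$n_per_group[2L],
                                                er[1L], er[2L])
    }
    covariates <- data.frame(subject_id = ids, group = group)
    if (coupled) {
      cl <- spec$clinical
      base <- cl$baseline %||% c(0.25, 10)
      v <- stats::runif(n, base[1L], base[2L]) + cl$coefficient * effect
      nsd <- cl$noise_sd %||% 0
      if (nsd > 0) v <- v + stats::rnorm(n, sd = nsd)
      covariates[[cl$covariate]] <- v
    }
    list(sub_seeds = sub_seeds, effect = effect, covariates = covariates)
  })

  C1 <- build_latent_correlation(spec, 1L, quiet = TRUE)
  C2_full <- build_latent_correlation(spec, 2L, quiet = TRUE)
  repaired <- isTRUE(attr(C2_full, "psd_repaired"))
  power <- vector("list", n)
  names(power) <- ids
  for (s in seq_len(n)) {
    C <- if (group[s] == "group1") C1
         else if (!coupled) C2_full
         else build_latent_correlation(spec, 2L, effect = drawn$effect[s],
                                       quiet = TRUE)
    repaired <- repaired || isTRUE(attr(C, "psd_repaired"))
    power[[s]] <- generate_power_matrix(C, spec$n_trials, spec$noise_sd,
                                        seed = drawn$sub_seeds[s],
                                        subject_id = ids[s], band = band)
  }
  structure(
    list(power = power, group = group, covariates = drawn$covariates,
         effect = drawn$effect, roi_labels = spec$roi_labels, spec = spec,
         provenance = list(seed = spec$seed, spec_hash = config_hash(unclass(spec)),
                           psd_repaired = repaired)),
    class = "phnet_cohort")
}

#' @export
print.phnet_cohort <- function(x, ...) {
  cat(sprintf("phnet_cohort: %d + %d subjects, %d trials x %d ROIs (seed %d)\n",
              sum(x$group == "group1"), sum(x$group == "group2"),
              x$spec$n_trials, x$spec$n_rois, x$spec$seed))
  if (ncol(x$covariates) > 2L)
    cat("covariates:", paste(setdiff(names(x$covariates),
                                     c("subject_id", "group")), collapse = ", "), "\n")
  invisible(x)
}
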