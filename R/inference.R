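#' Two-sample t test on barcode slopes
#'
#' Compares per-subject barcode slopes between two groups with a two-sided
#' independent t test (pooled-variance Student test by default; Welch
#' available via `var_equal = FALSE`).
#'
#' @param slopes_a,slopes_b numeric vectors of per-subject slopes (each of
#'   length >= 2; at least one group must have nonzero variance).
#' @param var_equal pooled-variance Student test (`TRUE`, default) or Welch.
#' @return object of class `"slope_comparison"`: list with `t_statistic`,
#'   `degrees_of_freedom`, two-sided `p_value`, and `group_means`.
#' @export
compare_barcode_slopes <- function(slopes_a, slopes_b, var_equal = TRUE) {
  slopes_a <- as.numeric(slopes_a); slopes_b <- as.numeric(slopes_b)
  if (length(slopes_a) < 2L || length(slopes_b) < 2L)
    stop("each group needs at least 2 slopes", call. = FALSE)
  if (any(!is.finite(c(slopes_a, slopes_b))))
    stop("slopes must be finite", call. = FALSE)
  if (stats::var(slopes_a) == 0 && stats::var(slopes_b) == 0)
    stop("zero pooled variance: slopes are constant within both groups",
         call. = FALSE)
  tt <- stats::t.test(slopes_a, slopes_b, var.equal = var_equal)
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 group_means = c(mean(slopes_a), mean(slopes_b)),
                 var_equal = var_equal),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope comparison: t = %.4g (df %.4g), p = %.4g; means %.4g vs %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              x$group_means[1L], x$group_means[2L]))
  invisible(x)
}

## stack a list of SLMs (or single_linkage objects) into a subjects x edges
## matrix; all subjects must share ROI labels in the same order
slm_edge_table <- function(slms, labels = NULL) {
  mats <- lapply(slms, function(x) {
    m <- if (inherits(x, "single_linkage")) x$slm else x
    unclass(as.matrix(m))
  })
  if (length(mats) == 0L) stop("empty group of SLMs", call. = FALSE)
  labs <- colnames(mats[[1L]])
  if (!is.null(labels) && !identical(labs, labels))
    stop("SLM ROI labels do not match across groups", call. = FALSE)
  for (m in mats)
    if (!identical(colnames(m), labs))
      stop("all SLMs must share the same ROI labels in the same order",
           call. = FALSE)
  p <- ncol(mats[[1L]])
  S <- t(vapply(mats, function(m) m[upper.tri(m)], numeric(p * (p - 1L) / 2L)))
  attr(S, "edges") <- edge_index(p, labs)
  S
}

#' Permutation test on single-linkage distances
#'
#' Tests, edge by edge, whether single-linkage distances (SLDs) differ
#' between two groups of subjects. The observed statistic per edge is the
#' difference of group mean SLDs (group 2 minus group 1; positive = longer
#' SLD, i.e. reduced connectivity, in group 2). The null distribution is
#' built by randomly reassigning whole subjects to two pseudo-groups of the
#' original sizes and recomputing the statistic for each of
#' `n_permutations` relabellings (this preserves the within-subject
#' dependence between edges). Two-sided p-values use the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (n_permutations + 1)`, so they are
#' never exactly zero. Significance is declared at uncorrected `p < alpha`
#' (default 0.001).
#'
#' `method = "edgewise"` instead shuffles the pooled values of every edge
#' independently; it destroys the inter-edge dependence and is provided for
#' sensitivity analysis only.
#'
#' @param slms_a,slms_b lists of single-linkage matrices (or
#'   [single_linkage()] results), one per subject, sharing ROI labels.
#' @param n_permutations number of random relabellings (>= 1; default 10000).
#' @param alpha uncorrected edge-wise significance level.
#' @param seed integer seed for the relabellings.
#' @param method `"subject"` (default) or `"edgewise"` (see Details).
#' @return object of class `"slm_permutation"`: list with `edges` (data frame
#'   `i`, `j`, `roi_i`, `roi_j`, `observed_diff`, `p_value`, `significant`),
#'   `n_permutations`, `alpha`, `seed`, `method`, `n_per_group`.
#' @export
slm_permutation_test <- function(slms_a, slms_b, n_permutations = 10000L,
                                 alpha = 0.001, seed = NULL,
                                 method = c("subject", "edgewise")) {
  method <- match.arg(method)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  stop_if_not_scalar_prob(alpha, "alpha")
  SA <- slm_edge_table(slms_a)
  SB <- slm_edge_table(slms_b)
  edges <- attr(SA, "edges")
  if (!identical(edges, attr(SB, "edges")))
    stop("SLM ROI labels do not match across groups", call. = FALSE)
  nA <- nrow(SA); nB <- nrow(SB); n <- nA + nB
  S <- rbind(SA, SB)
  obs <- colMeans(SB) - colMeans(SA)
  nperm <- as.integer(n_permutations)

  count <- with_seed(seed, {
    if (method == "subject") {
      cnt <- numeric(ncol(S))
      tot <- colSums(S)
      chunk <- max(1L, min(nperm, as.integer(2e7 / ncol(S))))
      done <- 0L
      while (done < nperm) {
        m <- min(chunk, nperm - done)
        pick <- matrix(0, m, n)
        rows <- rep(seq_len(m), each = nB)
        cols <- as.vector(vapply(seq_len(m),
                                 function(b) sample.int(n, nB), integer(nB)))
        pick[cbind(rows, cols)] <- 1
        sumB <- pick %*% S
        nulld <- sumB / nB - (matrix(tot, m, ncol(S), byrow = TRUE) - sumB) / nA
        ## tiny slack so exact relabelling ties (e.g. the identity) are
        ## counted as >= despite floating-point summation-order noise;
        ## erring towards counting keeps the p-value valid (conservative)
        cnt <- cnt + colSums(abs(nulld) >=
                               matrix(abs(obs) - 1e-10, m, ncol(S), byrow = TRUE))
        done <- done + m
      }
      cnt
    } else {
      ## independent relabelling per edge
      vapply(seq_len(ncol(S)), function(e) {
        v <- S[, e]
        sum(vapply(seq_len(nperm), function(b) {
          idx <- sample.int(n, nB)
          abs(mean(v[idx]) - mean(v[-idx])) >= abs(obs[e]) - 1e-10
        }, logical(1)))
      }, numeric(1))
    }
  })

  p <- (1 + count) / (nperm + 1)
  edges$observed_diff <- obs
  edges$p_value <- p
  edges$significant <- p < alpha
  structure(list(edges = edges, n_permutations = nperm, alpha = alpha,
                 seed = seed, method = method, n_per_group = c(nA, nB)),
            class = "slm_permutation")
}

#' @export
print.slm_permutation <- function(x, ...) {
  sig <- x$edges[x$edges$significant, , drop = FALSE]
  cat(sprintf("SLD permutation test: %d vs %d subjects, %d edges, %d permutations\n",
              x$n_per_group[1L], x$n_per_group[2L], nrow(x$edges),
              x$n_permutations))
  cat(sprintf("%d edge(s) significant at uncorrected p < %g\n", nrow(sig), x$alpha))
  if (nrow(sig) > 0L) print(sig, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation of edge SLDs with clinical covariates
#'
#' For each requested edge and each covariate, the Pearson correlation across
#' subjects between the edge's single-linkage distance and the covariate,
#' with a two-sided p-value and Bonferroni-corrected significance level
#' `alpha / family_size`. The family size is an explicit parameter (e.g. 6
#' edges x 6 clinical measures = 36) and is never inferred from the input.
#' Degenerate records (constant SLD or covariate) are flagged, not dropped.
#'
#' @param slms list of single-linkage matrices, one per subject (typically
#'   the patient group).
#' @param edges data frame with columns `i`, `j` (ROI indices, `i != j`) of
#'   the edges to correlate.
#' @param covariates data frame aligned row-by-row with `slms`; all numeric
#'   columns except `subject_id`/`group` are treated as covariates.
#' @param alpha family-wise significance level before correction.
#' @param family_size number of tests in the Bonferroni family.
#' @return object of class `"clinical_correlation"`: list with `records`
#'   (edge x covariate rows: `r`, `p_value`, `n`, `degenerate`,
#'   `significant`), `alpha`, `family_size` and `corrected_alpha`.
#' @export
clinical_correlations <- function(slms, edges, covariates, alpha = 0.05,
                                  family_size) {
  if (missing(family_size) || is.null(family_size))
    stop("'family_size' must be given explicitly (it is never inferred)",
         call. = FALSE)
  if (family_size < 1) stop("family_size must be >= 1", call. = FALSE)
  stop_if_not_scalar_prob(alpha, "alpha")
  S <- slm_edge_table(slms)
  all_edges <- attr(S, "edges")
  if (nrow(covariates) != nrow(S))
    stop("covariates must have one row per subject (",
         nrow(S), " SLMs vs ", nrow(covariates), " rows)", call. = FALSE)
  if (nrow(S) < 3L)
    stop("need at least 3 subjects for a correlation", call. = FALSE)
  covs <- covariates[, setdiff(names(covariates), c("subject_id", "group")),
                     drop = FALSE]
  covs <- covs[, vapply(covs, is.numeric, logical(1)), drop = FALSE]
  if (ncol(covs) == 0L) stop("no numeric covariate columns", call. = FALSE)

  recs <- list()
  for (k in seq_len(nrow(edges))) {
    i <- min(edges$i[k], edges$j[k]); j <- max(edges$i[k], edges$j[k])
    col <- which(all_edges$i == i & all_edges$j == j)
    if (length(col) != 1L)
      stop(sprintf("edge (%d, %d) is not a valid ROI pair", i, j), call. = FALSE)
    sld <- S[, col]
    for (cv in names(covs)) {
      v <- covs[[cv]]
      degenerate <- stats::sd(sld) == 0 || stats::sd(v) == 0
      if (degenerate) {
        r <- NA_real_; pval <- NA_real_
      } else {
        ct <- stats::cor.test(sld, v, method = "pearson")
        r <- unname(ct$estimate); pval <- ct$p.value
      }
      recs[[length(recs) + 1L]] <- data.frame(
        i = i, j = j,
        roi_i = all_edges$roi_i[col], roi_j = all_edges$roi_j[col],
        covariate = cv, r = r, p_value = pval, n = length(sld),
        degenerate = degenerate,
        significant = !degenerate && pval < alpha / family_size)
    }
  }
  structure(list(records = do.call(rbind, recs), alpha = alpha,
                 family_size = as.integer(family_size),
                 corrected_alpha = alpha / family_size),
            class = "clinical_correlation")
}

#' @export
print.clinical_correlation <- function(x, ...) {
  cat(sprintf("clinical correlations: %d record(s), Bonferroni alpha %g / %d = %.4g\n",
              nrow(x$records), x$alpha, x$family_size, x$corrected_alpha))
  print(x$records, row.names = FALSE)
  invisible(x)
}
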