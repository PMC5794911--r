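#' Pipeline configuration
#'
#' Bundles and validates everything one analysis run needs. Defaults mirror a
#' standard resting-state band-power analysis: barcode-slope window 11-66
#' components, 10000 permutations, slope-test alpha 0.05, uncorrected
#' edge-map alpha 0.001, family-wise clinical alpha 0.05.
#'
#' @param input path to a cohort directory written by [write_cohort()], or
#'   `NULL` to simulate from `spec`.
#' @param spec a [cohort_spec()] to simulate (exactly one of `input`/`spec`).
#' @param out_dir output directory for result files.
#' @param band frequency-band label (bookkeeping only).
#' @param window component-count window for [barcode_slope()].
#' @param n_permutations relabellings for [slm_permutation_test()].
#' @param alpha_slope,alpha_edges,alpha_clinical significance levels, each in
#'   (0, 1).
#' @param family_size Bonferroni family size for the clinical stage; must be
#'   set whenever the cohort carries clinical covariates (never inferred).
#' @param seed integer seed governing simulation and permutations.
#' @param quiet suppress progress messages (results are never logged to
#'   stdout either way).
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, spec = NULL, out_dir,
                       band = "theta", window = c(11L, 66L),
                       n_permutations = 10000L, alpha_slope = 0.05,
                       alpha_edges = 0.001, alpha_clinical = 0.05,
                       family_size = NULL, seed = 1L, quiet = FALSE) {
  if (is.null(input) == is.null(spec))
    stop("give exactly one of 'input' (cohort directory) or 'spec'",
         call. = FALSE)
  if (!is.null(spec)) validate_cohort_spec(spec)
  stop_if_not_scalar_prob(alpha_slope, "alpha_slope")
  stop_if_not_scalar_prob(alpha_edges, "alpha_edges")
  stop_if_not_scalar_prob(alpha_clinical, "alpha_clinical")
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be an increasing pair", call. = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  structure(list(input = input, spec = spec, out_dir = out_dir, band = band,
                 window = as.integer(window),
                 n_permutations = as.integer(n_permutations),
                 alpha_slope = alpha_slope, alpha_edges = alpha_edges,
                 alpha_clinical = alpha_clinical, family_size = family_size,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort: per-subject correlation distance
#' matrices, graph filtration (barcode, dendrogram, SLM, barcode slope),
#' slope t test, SLD permutation test, and -- when covariates and significant
#' edges are present -- clinical correlations over the significant edges in
#' group 2. All result files are written under `config$out_dir` and are
#' stamped with the configuration hash and seed, so identical
#' (config, seed) pairs produce identical files. Any stage error aborts with
#' a message naming the stage.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `slopes`, `slope_test`, `edge_test`,
#'   `clinical` (or `NULL`), `files` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (!config$quiet)
    message(sprintf("[phnet] %s", sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ## hash the analysis-relevant settings only, so identical analyses written
  ## to different directories carry the same provenance stamp
  hash <- config_hash(unclass(config)[setdiff(names(config),
                                              c("out_dir", "quiet"))])
  tag <- sprintf("phnet config %s seed %d", hash, config$seed)

  cohort <- stage("load", {
    if (!is.null(config$spec)) {
      log_msg("simulating cohort (seed %d)", config$spec$seed)
      generate_cohort(config$spec, band = config$band)
    } else {
      log_msg("reading cohort from %s", config$input)
      read_cohort(config$input)
    }
  })

  out <- config$out_dir
  sub_dir <- file.path(out, "subjects")
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)

  n <- length(cohort$power)
  slms <- vector("list", n)
  slopes <- numeric(n)
  stage("topology", {
    for (s in seq_len(n)) {
      id <- names(cohort$power)[s]
      d <- pearson_distance(cohort$power[[s]])
      sl <- single_linkage(d)
      bc <- barcode(d)
      slms[[s]] <- sl$slm
      slopes[s] <- barcode_slope(bc, window = config$window)$slope
      write_distance_matrix(d, file.path(sub_dir, paste0(id, "_distance.tsv")),
                            comment = tag)
      write_distance_matrix(sl$slm, file.path(sub_dir, paste0(id, "_slm.tsv")),
                            comment = tag)
      write_barcode(bc, file.path(sub_dir, paste0(id, "_barcode.tsv")),
                    comment = tag)
      write_dendrogram_newick(sl, file.path(sub_dir, paste0(id, "_dendrogram.nwk")))
    }
    log_msg("filtration done for %d subjects", n)
  })
  g1 <- cohort$group == "group1"

  slope_test <- stage("compare_slopes",
                      compare_barcode_slopes(slopes[g1], slopes[!g1]))
  edge_test <- stage("compare_edges",
                     slm_permutation_test(slms[g1], slms[!g1],
                                          n_permutations = config$n_permutations,
                                          alpha = config$alpha_edges,
                                          seed = config$seed))
  log_msg("slope t = %.3g (p = %.3g); %d significant edge(s) at p < %g",
          slope_test$t_statistic, slope_test$p_value,
          sum(edge_test$edges$significant), config$alpha_edges)

  clinical <- NULL
  cov_cols <- setdiff(names(cohort$covariates), c("subject_id", "group"))
  sig <- edge_test$edges[edge_test$edges$significant, c("i", "j")]
  if (length(cov_cols) > 0L && nrow(sig) > 0L) {
    clinical <- stage("correlate", {
      if (is.null(config$family_size))
        stop("clinical covariates present: config$family_size must be set")
      clinical_correlations(slms[!g1], sig,
                            cohort$covariates[!g1, , drop = FALSE],
                            alpha = config$alpha_clinical,
                            family_size = config$family_size)
    })
  } else if (length(cov_cols) > 0L) {
    log_msg("no significant edges; clinical stage skipped")
  }

  files <- stage("write", {
    slope_df <- data.frame(subject_id = names(cohort$power),
                           group = cohort$group, slope = slopes)
    f_slopes <- file.path(out, "slopes.tsv")
    writeLines(c(paste0("# ", tag), "subject_id\tgroup\tslope",
                 sprintf("%s\t%s\t%s", slope_df$subject_id, slope_df$group,
                         fmt_num(slope_df$slope))), f_slopes)
    f_edges <- file.path(out, "edge_test.tsv")
    ed <- edge_test$edges
    writeLines(c(paste0("# ", tag),
                 "i\tj\troi_i\troi_j\tobserved_diff\tp_value\tsignificant",
                 sprintf("%d\t%d\t%s\t%s\t%s\t%s\t%s", ed$i, ed$j, ed$roi_i,
                         ed$roi_j, fmt_num(ed$observed_diff),
                         fmt_num(ed$p_value), ed$significant)), f_edges)
    f_clin <- NULL
    if (!is.null(clinical)) {
      f_clin <- file.path(out, "clinical.tsv")
      rc <- clinical$records
      writeLines(c(paste0("# ", tag),
                   "i\tj\troi_i\troi_j\tcovariate\tr\tp_value\tn\tdegenerate\tsignificant",
                   sprintf("%d\t%d\t%s\t%s\t%s\t%s\t%s\t%d\t%s\t%s",
                           rc$i, rc$j, rc$roi_i, rc$roi_j, rc$covariate,
                           fmt_num(rc$r), fmt_num(rc$p_value), rc$n,
                           rc$degenerate, rc$significant)), f_clin)
    }
    f_summary <- file.path(out, "summary.json")
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed, band = config$band,
           n_per_group = as.integer(table(cohort$group)),
           n_rois = length(cohort$roi_labels),
           window = config$window, n_permutations = config$n_permutations,
           alphas = list(slope = config$alpha_slope,
                         edges = config$alpha_edges,
                         clinical = config$alpha_clinical),
           family_size = config$family_size,
           slope_test = unclass(slope_test),
           n_significant_edges = sum(ed$significant),
           provenance = cohort$provenance),
      f_summary, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    c(slopes = f_slopes, edge_test = f_edges, clinical = f_clin,
      summary = f_summary)
  })

  invisible(list(slopes = slopes, slope_test = slope_test,
                 edge_test = edge_test, clinical = clinical, files = files,
                 provenance = list(config_hash = hash, seed = config$seed)))
}
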