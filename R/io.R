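## Delimited-text I/O. All matrix files are tab-separated with an ROI-label
## header; numeric values are written with 17 significant digits so a
## write/read round trip reproduces doubles exactly. Lines starting with '#'
## are treated as comments (pipeline outputs carry a provenance comment).

fmt_num <- function(x) sprintf("%.17g", x)

read_noncomment_lines <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}

#' Read and write trial-by-ROI power matrices
#'
#' Tab-separated text, one header row of unique ROI labels, one row per
#' trial. Malformed input (ragged rows, non-numeric cells, duplicate labels)
#' raises an error with a diagnostic. Writing uses 17 significant digits, so
#' the round trip reproduces values to full double precision.
#'
#' @param path file path.
#' @param subject_id,band identifiers attached to the returned matrix.
#' @param comment optional comment line (without the leading `#`) written
#'   before the header.
#' @return `read_power_matrix()` returns a [power_matrix()];
#'   `write_power_matrix()` returns `path` invisibly.
#' @export
read_power_matrix <- function(path, subject_id = "", band = "") {
  lines <- read_noncomment_lines(path)
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(labels))
    stop("duplicate ROI label(s) in header of ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(labels)))
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, which(widths != length(labels))[1L] + 1L,
                 widths[widths != length(labels)][1L], length(labels)),
         call. = FALSE)
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(length(labels))))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at line %d, column %d ('%s')",
                 path, bad[2L] + 1L, bad[1L], body[[bad[2L]]][bad[1L]]),
         call. = FALSE)
  }
  power_matrix(t(matrix(vals, nrow = length(labels))), roi_labels = labels,
               subject_id = subject_id, band = band)
}

#' @rdname read_power_matrix
#' @param pm a [power_matrix()].
#' @export
write_power_matrix <- function(pm, path, comment = NULL) {
  labels <- colnames(pm)
  rows <- apply(unclass(pm), 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             paste(labels, collapse = "\t"), rows)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write square ROI-by-ROI matrices
#'
#' Square tab-separated text with ROI labels as both the header row and the
#' first column, used for distance matrices and single-linkage matrices.
#'
#' @param path file path.
#' @param comment optional provenance comment line.
#' @return `read_distance_matrix()` returns a symmetric matrix of class
#'   `"distance_matrix"`; `write_distance_matrix()` returns `path` invisibly.
#' @export
read_distance_matrix <- function(path) {
  lines <- read_noncomment_lines(path)
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (length(body) != length(labels))
    stop("matrix in ", path, " is not square", call. = FALSE)
  m <- t(vapply(body, function(r) as.numeric(r[-1L]), numeric(length(labels))))
  dimnames(m) <- list(labels, labels)
  structure(validate_distance_matrix(m),
            class = c("distance_matrix", "matrix", "array"))
}

#' @rdname read_distance_matrix
#' @param d square labelled matrix.
#' @export
write_distance_matrix <- function(d, path, comment = NULL) {
  d <- as.matrix(d)
  labels <- colnames(d)
  rows <- vapply(seq_len(nrow(d)), function(i)
    paste(c(labels[i], fmt_num(d[i, ])), collapse = "\t"), character(1))
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             paste(c("ROI", labels), collapse = "\t"), rows)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write barcodes
#'
#' Two-column tab-separated text: filtration value `epsilon` and
#' `n_components` immediately after the merge.
#'
#' @param bc a [barcode()].
#' @param path file path.
#' @param comment optional provenance comment line.
#' @return `read_barcode()` returns a `"phnet_barcode"`; `write_barcode()`
#'   returns `path` invisibly.
#' @export
write_barcode <- function(bc, path, comment = NULL) {
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             "epsilon\tn_components",
             paste(fmt_num(bc$epsilon), bc$n_components, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  lines <- read_noncomment_lines(path)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  eps <- vapply(body, function(r) as.numeric(r[1L]), numeric(1))
  ncomp <- vapply(body, function(r) as.integer(r[2L]), integer(1))
  structure(data.frame(epsilon = eps, n_components = ncomp),
            n_nodes = ncomp[1L] + 1L,
            class = c("phnet_barcode", "data.frame"))
}

#' Export a single-linkage dendrogram as Newick
#'
#' Writes the dendrogram of a [single_linkage()] result to a Newick file via
#' [ape::as.phylo()]. Following the usual hclust-to-phylo convention each
#' merge at height `h` sits at depth `h / 2`, so the patristic (tip-to-tip)
#' distance between two ROIs on the exported tree equals their
#' single-linkage distance.
#'
#' @param sl a [single_linkage()] result (or an `hclust` object).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(sl, path) {
  hc <- if (inherits(sl, "single_linkage")) sl$dendrogram else sl
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Bundled 76-ROI cortical node table
#'
#' A reconstructed table of the 76 cortical AAL parcels (38 per hemisphere;
#' subcortical, parahippocampal and cerebellar regions excluded) commonly
#' used as nodes for whole-cortex MEG network analyses, with interpretive
#' resting-state-network labels (DMN, VN, SMN, AN, DAN, or OTHER). The table
#' is a synthetic reconstruction from standard AAL labels, not a copy of any
#' study-specific supplement; network assignments are indicative only.
#'
#' @return data frame with columns `index` (0-based, contiguous),
#'   `abbreviation` (unique), `name`, `hemisphere` (`L`/`R`), `network`.
#' @export
roi_table <- function() {
  path <- system.file("extdata", "aal76_rois_synthetic.tsv", package = "phnet")
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(df$abbreviation),
            identical(df$index, seq_len(nrow(df)) - 1L))
  df
}

#' Write and read a synthetic cohort on disk
#'
#' A cohort directory holds one tab-separated power matrix per subject under
#' `subjects/` and a JSON manifest (subject ids, groups, covariates, seed and
#' the generating spec).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir target directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `"phnet_cohort"`.
#' @export
write_cohort <- function(cohort, dir) {
  sub_dir <- file.path(dir, "subjects")
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$power))
  for (s in seq_along(cohort$power)) {
    id <- names(cohort$power)[s]
    files[s] <- file.path("subjects", paste0(id, ".tsv"))
    write_power_matrix(cohort$power[[s]], file.path(dir, files[s]),
                       comment = sprintf("cohort seed %d subject %s group %s",
                                         cohort$spec$seed, id, cohort$group[s]))
  }
  manifest <- list(
    seed = cohort$spec$seed,
    spec = unclass(cohort$spec),
    provenance = cohort$provenance,
    subjects = data.frame(subject_id = names(cohort$power),
                          group = as.character(cohort$group),
                          file = files,
                          effect = cohort$effect),
    covariates = cohort$covariates)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subs <- manifest$subjects
  power <- lapply(seq_len(nrow(subs)), function(s)
    read_power_matrix(file.path(dir, subs$file[s]),
                      subject_id = subs$subject_id[s]))
  names(power) <- subs$subject_id
  spec <- manifest$spec
  spec$blocks <- lapply(spec$blocks, as.list)
  covs <- as.data.frame(manifest$covariates)
  covs$group <- factor(covs$group, levels = c("group1", "group2"))
  structure(
    list(power = power,
         group = factor(subs$group, levels = c("group1", "group2")),
         covariates = covs,
         effect = subs$effect,
         roi_labels = spec$roi_labels,
         spec = spec,
         provenance = manifest$provenance),
    class = "phnet_cohort")
}
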