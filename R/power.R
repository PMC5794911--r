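#' Trial-by-ROI band-power matrix
#'
#' Lightweight container for one subject's spectral power observations: rows
#' are trials (epochs), columns are regions of interest (ROIs). Values must be
#' finite and non-negative (band power in arbitrary units) and at least three
#' trials are required so that a Pearson correlation is defined downstream.
#'
#' @param values numeric matrix, `n_trials x n_rois`.
#' @param roi_labels character vector of unique column labels; defaults to the
#'   column names of `values`.
#' @param subject_id,band optional identifying strings carried as attributes.
#' @return a numeric matrix of class `"power_matrix"` with ROI labels as
#'   column names and `subject_id`/`band` attributes.
#' @examples
#' pm <- power_matrix(matrix(rexp(30), 10, 3), c("A", "B", "C"))
#' dim(pm)
#' @export
power_matrix <- function(values, roi_labels = colnames(values),
                         subject_id = "", band = "") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("power values must be numeric", call. = FALSE)
  if (nrow(values) < 3L)
    stop("a power matrix needs at least 3 trials (rows), got ", nrow(values),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("power values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("power values must be non-negative", call. = FALSE)
  if (is.null(roi_labels))
    roi_labels <- sprintf("R%02d", seq_len(ncol(values)))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != ncol(values))
    stop("roi_labels length (", length(roi_labels),
         ") does not match the number of ROI columns (", ncol(values), ")",
         call. = FALSE)
  if (anyDuplicated(roi_labels))
    stop("duplicate ROI labels: ",
         paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(NULL, roi_labels)
  structure(values, subject_id = as.character(subject_id),
            band = as.character(band),
            class = c("power_matrix", class(values)))
}

#' @export
print.power_matrix <- function(x, ...) {
  cat(sprintf("power_matrix: %d trials x %d ROIs", nrow(x), ncol(x)))
  sid <- attr(x, "subject_id"); bnd <- attr(x, "band")
  if (nzchar(sid)) cat(", subject ", sid, sep = "")
  if (nzchar(bnd)) cat(" [", bnd, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' ROI labels of a phnet object
#' @param x a `power_matrix` or a square labelled matrix.
#' @return character vector of ROI labels.
#' @export
roi_labels <- function(x) colnames(x)

#' Pearson correlation distance matrix
#'
#' Converts a trial-by-ROI power matrix into the correlation distance used for
#' graph filtration: `d(i, j) = 1 - max(r(i, j), 0)`, where `r` is the Pearson
#' correlation of the two ROI columns across trials. Negative correlations are
#' clipped at zero, so the distance saturates at 1; the diagonal is 0 and all
#' entries lie in `[0, 1]`. Distances are computed on the power values as
#' given; any transform (e.g. log) is the caller's responsibility.
#'
#' @param power a [power_matrix()] (or plain numeric matrix) with at least 3
#'   rows and no constant column.
#' @return symmetric `n_rois x n_rois` matrix of class `"distance_matrix"`
#'   with ROI labels as dimnames.
#' @examples
#' pm <- power_matrix(cbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4),
#'                          c = c(5, 4, 3, 2, 1)))
#' pearson_distance(pm)
#' @export
pearson_distance <- function(power) {
  x <- unclass(as.matrix(power))
  if (!is.numeric(x)) stop("power values must be numeric", call. = FALSE)
  if (nrow(x) < 3L)
    stop("Pearson distance needs at least 3 trials, got ", nrow(x),
         call. = FALSE)
  if (any(!is.finite(x))) stop("power values must all be finite", call. = FALSE)
  labels <- colnames(x) %||% sprintf("R%02d", seq_len(ncol(x)))
  constant <- apply(x, 2L, function(col) max(col) == min(col))
  if (any(constant))
    stop("constant ROI column(s), correlation undefined: ",
         paste(labels[constant], collapse = ", "), call. = FALSE)
  r <- stats::cor(x)
  d <- 1 - pmin(pmax(r, 0), 1)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d ROIs, range [%.3g, %.3g]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  print(unclass(x), ...)
  invisible(x)
}

## shared validation for filtration inputs: square, symmetric, zero diagonal,
## finite and non-negative. Entries are not required to be <= 1 so that the
## filtration also applies to generic dissimilarities.
validate_distance_matrix <- function(d) {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (is.null(colnames(d))) {
    labels <- sprintf("R%02d", seq_len(ncol(d)))
    dimnames(d) <- list(labels, labels)
  } else {
    rownames(d) <- colnames(d)
  }
  d
}
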