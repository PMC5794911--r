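## Graph filtration over a distance matrix.
##
## The beta-zero persistent homology of a metric network is carried entirely
## by its minimum spanning tree: thresholding the network at epsilon connects
## exactly the node pairs whose minimax path distance is <= epsilon. A single
## Kruskal sweep with union-find therefore yields, at once, the MST, the
## barcode of connected-component counts, the single-linkage dendrogram and
## the ultrametric single-linkage matrix (SLM).

## One Kruskal pass. Ties are broken by weight, then lexicographic (i, j),
## which fixes the MST and dendrogram topology; barcode heights and the SLM
## are invariant to the tie order.
graph_filtration <- function(d) {
  d <- validate_distance_matrix(d)
  p <- nrow(d)
  labels <- colnames(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  ei <- ut[, 1L]; ej <- ut[, 2L]
  w <- d[upper.tri(d)]
  ord <- order(w, ei, ej)

  parent <- seq_len(p)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  members <- as.list(seq_len(p))
  comp_merge <- integer(p)          # merge step that created each root, 0 = leaf
  merge <- matrix(0L, p - 1L, 2L)
  height <- numeric(p - 1L)
  mst_i <- integer(p - 1L); mst_j <- integer(p - 1L); mst_w <- numeric(p - 1L)
  slm <- matrix(0, p, p, dimnames = list(labels, labels))

  k <- 0L
  for (e in ord) {
    ra <- find(ei[e]); rb <- find(ej[e])
    if (ra == rb) next
    k <- k + 1L
    ma <- members[[ra]]; mb <- members[[rb]]
    slm[ma, mb] <- w[e]
    slm[mb, ma] <- w[e]
    code_a <- if (comp_merge[ra] == 0L) -ma[1L] else comp_merge[ra]
    code_b <- if (comp_merge[rb] == 0L) -mb[1L] else comp_merge[rb]
    merge[k, ] <- c(code_a, code_b)
    height[k] <- w[e]
    mst_i[k] <- ei[e]; mst_j[k] <- ej[e]; mst_w[k] <- w[e]
    parent[rb] <- ra
    members[[ra]] <- c(ma, mb)
    members[rb] <- list(NULL)
    comp_merge[ra] <- k
    if (k == p - 1L) break
  }
  if (k < p - 1L) stop("internal error: filtration did not connect the graph")

  ## leaf ordering for plotting: unfold the merge tree bottom-up
  seqs <- vector("list", p - 1L)
  for (m in seq_len(p - 1L)) {
    a <- merge[m, 1L]; b <- merge[m, 2L]
    seqs[[m]] <- c(if (a < 0L) -a else seqs[[a]],
                   if (b < 0L) -b else seqs[[b]])
  }
  dend <- structure(
    list(merge = merge, height = height, order = seqs[[p - 1L]],
         labels = labels, method = "single", dist.method = "pearson_distance",
         call = match.call()),
    class = "hclust")

  list(mst = data.frame(i = mst_i, j = mst_j, weight = mst_w,
                        roi_i = labels[mst_i], roi_j = labels[mst_j]),
       dendrogram = dend,
       slm = structure(slm, class = c("distance_matrix", "matrix", "array")),
       n_nodes = p)
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with deterministic tie-breaking (edges sorted by
#' weight, then by lexicographic `(i, j)`). The MST is the computational
#' backbone of the graph filtration: its edge weights are exactly the merge
#' events of the beta-zero barcode.
#'
#' @param dist symmetric distance matrix (zero diagonal, finite,
#'   non-negative), e.g. from [pearson_distance()].
#' @return data frame with one row per MST edge (`i`, `j`, `weight`,
#'   `roi_i`, `roi_j`), sorted by weight then `(i, j)`; `i < j`.
#' @examples
#' d <- pearson_distance(power_matrix(matrix(rexp(60), 20, 3)))
#' minimum_spanning_tree(d)
#' @export
minimum_spanning_tree <- function(dist) graph_filtration(dist)$mst

#' Beta-zero barcode of the graph filtration
#'
#' Tracks the number of connected components of the thresholded network as
#' the filtration value (threshold distance) epsilon increases. Each merge
#' event is an MST edge weight; immediately after the k-th merge the network
#' has `p - k` components, so the barcode decreases from `p - 1` (after the
#' first merge) to 1 (fully connected).
#'
#' @inheritParams minimum_spanning_tree
#' @return data frame of class `"phnet_barcode"` with columns `epsilon`
#'   (non-decreasing merge heights) and `n_components`, plus an `n_nodes`
#'   attribute.
#' @seealso [barcode_components()] for the implied step function N(epsilon),
#'   [barcode_slope()] for the global-connectivity slope statistic.
#' @export
barcode <- function(dist) {
  gf <- graph_filtration(dist)
  p <- gf$n_nodes
  structure(
    data.frame(epsilon = gf$mst$weight, n_components = seq(p - 1L, 1L)),
    n_nodes = p,
    class = c("phnet_barcode", "data.frame"))
}

#' Number of connected components at given filtration values
#'
#' Evaluates the right-continuous step function N(epsilon) implied by a
#' barcode: nodes `i`, `j` are joined once `d(i, j) <= epsilon`, so
#' `N(epsilon) = n_nodes - #\{merge events with height <= epsilon\}`.
#'
#' @param bc a [barcode()] (or data frame with `epsilon`/`n_components`
#'   columns and an `n_nodes` attribute).
#' @param epsilon numeric vector of filtration values.
#' @return integer vector of component counts, same length as `epsilon`.
#' @export
barcode_components <- function(bc, epsilon) {
  p <- attr(bc, "n_nodes") %||% (bc$n_components[1L] + 1L)
  vapply(epsilon, function(e) as.integer(p - sum(bc$epsilon <= e)), integer(1))
}

#' @export
print.phnet_barcode <- function(x, ...) {
  cat(sprintf("beta-zero barcode: %d nodes, %d merge events, epsilon in [%.4g, %.4g]\n",
              attr(x, "n_nodes"), nrow(x), min(x$epsilon), max(x$epsilon)))
  invisible(x)
}

#' Single-linkage dendrogram and single-linkage matrix
#'
#' The single-linkage distance (SLD) between two nodes is the smallest
#' filtration value at which they fall into the same connected component,
#' i.e. the minimax path distance: the largest edge weight on the MST path
#' joining them. The matrix of all SLDs (the SLM) is an ultrametric, is
#' bounded above entrywise by the input distances, and is the matrix form of
#' the single-linkage dendrogram; the dendrogram's merge heights are exactly
#' the barcode's merge events.
#'
#' @inheritParams minimum_spanning_tree
#' @return list of class `"single_linkage"` with components
#'   \describe{
#'     \item{dendrogram}{an [stats::hclust] object (method `"single"`);}
#'     \item{slm}{the ultrametric SLM as a `"distance_matrix"`.}
#'   }
#' @examples
#' d <- matrix(c(0, .1, .5, .1, 0, .3, .5, .3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' single_linkage(d)$slm
#' @export
single_linkage <- function(dist) {
  gf <- graph_filtration(dist)
  structure(list(dendrogram = gf$dendrogram, slm = gf$slm,
                 n_nodes = gf$n_nodes),
            class = "single_linkage")
}

#' @export
print.single_linkage <- function(x, ...) {
  cat(sprintf("single_linkage: %d ROIs, merge heights in [%.4g, %.4g]\n",
              x$n_nodes, min(x$dendrogram$height), max(x$dendrogram$height)))
  invisible(x)
}

#' Barcode slope: global connectivity statistic
#'
#' Ordinary least-squares regression of the number of connected components
#' (response) on the filtration value epsilon (predictor), restricted to
#' merge events whose component count lies in a closed window (default 11 to
#' 66, suited to 76-node networks). A more negative slope means the network
#' couples faster, i.e. stronger global connectivity.
#'
#' By default the regression points are the merge events themselves. If
#' `grid` is given, the barcode step function is instead sampled at those
#' epsilon values (a uniform grid alternative), keeping samples whose
#' component count is in the window.
#'
#' @param bc a [barcode()].
#' @param window integer pair `(low, high)`: closed component-count window.
#' @param grid optional numeric vector of epsilon values at which to sample
#'   the step function instead of using the merge events.
#' @return object of class `"barcode_slope"`: list with `slope`, `intercept`,
#'   `n_range` and `n_points_used`.
#' @export
barcode_slope <- function(bc, window = c(11L, 66L), grid = NULL) {
  if (!all(c("epsilon", "n_components") %in% names(bc)))
    stop("'bc' must have epsilon and n_components columns", call. = FALSE)
  if (length(window) != 2L || !is.numeric(window) || window[1L] >= window[2L])
    stop("'window' must be an increasing pair (low, high)", call. = FALSE)
  if (is.null(grid)) {
    pts <- data.frame(epsilon = bc$epsilon, n = bc$n_components)
  } else {
    pts <- data.frame(epsilon = sort(grid),
                      n = barcode_components(bc, sort(grid)))
  }
  pts <- pts[pts$n >= window[1L] & pts$n <= window[2L], , drop = FALSE]
  if (nrow(pts) < 2L)
    stop(sprintf("fewer than 2 barcode points with component count in [%g, %g]",
                 window[1L], window[2L]), call. = FALSE)
  if (stats::var(pts$epsilon) == 0)
    stop("in-window filtration values have zero variance; slope undefined",
         call. = FALSE)
  fit <- stats::lm(n ~ epsilon, data = pts)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_range = as.integer(window),
                 n_points_used = nrow(pts)),
            class = "barcode_slope")
}

#' @export
print.barcode_slope <- function(x, ...) {
  cat(sprintf("barcode slope: %.4g components per unit epsilon (window %d-%d, %d points)\n",
              x$slope, x$n_range[1L], x$n_range[2L], x$n_points_used))
  invisible(x)
}
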