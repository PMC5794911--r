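## Independent oracles used to validate the filtration and inference code.
## These deliberately share no code with the package implementation.

four_node_dist <- function() {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 0.1; d["A", "C"] <- 0.5; d["A", "D"] <- 0.9
  d["B", "C"] <- 0.3; d["B", "D"] <- 0.7; d["C", "D"] <- 0.4
  d + t(d)
}

## random symmetric distance matrix; optional rounding induces ties
rand_dist <- function(p, digits = NULL) {
  m <- matrix(0, p, p)
  v <- runif(p * (p - 1) / 2, 0.05, 1)
  if (!is.null(digits)) v <- round(v, digits)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(sprintf("N%02d", 1:p), sprintf("N%02d", 1:p))
  m
}

## barcode oracle: union-find sweep over ALL edges sorted by weight
oracle_barcode_sweep <- function(d) {
  p <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w, ut[, 1], ut[, 2])
  par <- 1:p
  root <- function(x) { while (par[x] != x) x <- par[x]; x }
  eps <- numeric(0); ncomp <- integer(0); comps <- p
  for (e in ord) {
    ra <- root(ut[e, 1]); rb <- root(ut[e, 2])
    if (ra != rb) {
      par[rb] <- ra
      comps <- comps - 1L
      eps <- c(eps, w[e]); ncomp <- c(ncomp, comps)
      if (comps == 1L) break
    }
  }
  data.frame(epsilon = eps, n_components = ncomp)
}

## minimax path distances by Floyd-Warshall closure over the (min, max) semiring
oracle_minimax_fw <- function(d) {
  m <- d
  p <- nrow(d)
  for (k in 1:p)
    m <- pmin(m, pmax(matrix(m[, k], p, p), matrix(m[k, ], p, p, byrow = TRUE)))
  diag(m) <- 0
  m
}

## minimax by exhaustive enumeration of all simple paths (small p only)
oracle_minimax_paths <- function(d) {
  p <- nrow(d)
  best <- matrix(0, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    res <- Inf
    dfs <- function(cur, visited, maxw) {
      if (maxw >= res) return(invisible())
      if (cur == j) { res <<- maxw; return(invisible()) }
      for (nxt in setdiff(1:p, visited))
        dfs(nxt, c(visited, nxt), max(maxw, d[cur, nxt]))
    }
    dfs(i, i, 0)
    best[i, j] <- best[j, i] <- res
  }
  dimnames(best) <- dimnames(d)
  best
}

## all spanning trees by brute force over edge subsets of size p - 1
oracle_spanning_tree_weights <- function(d) {
  p <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  subsets <- utils::combn(nrow(ut), p - 1)
  weights <- apply(subsets, 2, function(sel) {
    par <- 1:p
    root <- function(x) { while (par[x] != x) x <- par[x]; x }
    for (e in sel) {
      ra <- root(ut[e, 1]); rb <- root(ut[e, 2])
      if (ra == rb) return(NA_real_)
      par[rb] <- ra
    }
    sum(d[ut[sel, , drop = FALSE]])
  })
  weights[!is.na(weights)]
}

## triple-wise ultrametric check
is_ultrametric <- function(m, tol = 1e-12) {
  p <- nrow(m)
  for (k in 1:p) {
    bound <- pmax(matrix(m[, k], p, p), matrix(m[k, ], p, p, byrow = TRUE))
    if (any(m > bound + tol)) return(FALSE)
  }
  TRUE
}

## pooled-variance two-sample t statistic and two-sided p, by the textbook formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

## exhaustive two-sided permutation p-values over all group relabellings
oracle_exhaustive_perm <- function(S, nA) {
  n <- nrow(S); nB <- n - nA
  obs <- colMeans(S[(nA + 1):n, , drop = FALSE]) - colMeans(S[1:nA, , drop = FALSE])
  sel <- utils::combn(n, nB)
  cnt <- numeric(ncol(S))
  for (c_i in seq_len(ncol(sel))) {
    idx <- sel[, c_i]
    dd <- colMeans(S[idx, , drop = FALSE]) - colMeans(S[-idx, , drop = FALSE])
    cnt <- cnt + (abs(dd) >= abs(obs))
  }
  cnt / ncol(sel)
}

## SLMs for every subject of a cohort, through the package pipeline
cohort_slms <- function(cohort) {
  lapply(cohort$power, function(pm) single_linkage(pearson_distance(pm))$slm)
}
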