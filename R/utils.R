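`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the user's
#' random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## short polynomial fingerprint of a configuration, used to stamp output files
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null", force = TRUE))
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop(sprintf("'%s' must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  invisible(x)
}

## ordered upper-triangle edge index (i < j, column-major), shared by all
## edge-wise results so every module reports the same edge ordering
edge_index <- function(p, labels = NULL) {
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L])
  if (!is.null(labels)) {
    out$roi_i <- labels[out$i]
    out$roi_j <- labels[out$j]
  }
  out
}
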