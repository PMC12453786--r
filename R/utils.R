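#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (0.5 -> 1), the
#' convention used for all reported scores and percentages. Base R's
#' `round()` rounds halves to even, which does not reproduce tabulated
#' values such as 0.1969 from 0.59065.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## Pairwise squared Euclidean distances between rows of two matrices.
## Clamps tiny negative values arising from floating-point cancellation.
pairwise_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## Indices of the k nearest rows of `ref` for each row of `query`,
## ordered by distance with index as the deterministic tie-break.
## `exclude` is an optional vector (one per query row) of a ref index to skip
## (used to exclude a point from its own neighbourhood).
nn_index <- function(query, ref, k, exclude = NULL) {
  d2 <- pairwise_dist2(query, ref)
  t(vapply(seq_len(nrow(query)), function(i) {
    d <- d2[i, ]
    if (!is.null(exclude)) d[exclude[i]] <- Inf
    order(d, seq_along(d))[seq_len(k)]
  }, integer(k)))
}

## Min-max scale columns of a matrix to [0, 1]; constant columns map to 0.
min_max_scale <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  sweep(sweep(X, 2, lo, "-"), 2, span, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
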