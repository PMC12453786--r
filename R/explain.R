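#' Local surrogate explanation for one instance
#'
#' Perturbation-based sparse linear surrogate in the LIME style: the
#' instance is perturbed `n_samples` times (numeric features get
#' Gaussian noise scaled by the background standard deviation, binary
#' 0/1 features flip with probability 0.3), the model's probability for
#' the target class is predicted on the perturbations, and a locally
#' weighted ridge regression (exponential proximity kernel on
#' standardised distance, kernel width `0.75 * sqrt(p)`) of that
#' probability on the standardised perturbed features yields one signed
#' weight per feature. Deterministic given `seed`.
#'
#' @param handle a `bench_model` or a function `f(X) -> probability matrix`.
#' @param instance numeric vector (named) or one-row matrix.
#' @param background numeric matrix used for perturbation statistics.
#' @param n_samples number of perturbations (>= 10).
#' @param target_class class whose probability is explained; default the
#'   model's predicted class for the instance.
#' @param seed integer seed.
#' @param flip_prob flip probability for binary features.
#' @return a `local_explanation` list: `class_probs` (the instance's
#'   predicted probability vector), `target_class`, and `weights`, a
#'   data frame of per-feature signed weight and the instance's value,
#'   ordered by absolute weight.
#' @export
explain_local <- function(handle, instance, background, n_samples = 1000,
                          target_class = NULL, seed = 1L, flip_prob = 0.3) {
  if (n_samples < 10) stop("n_samples must be >= 10", call. = FALSE)
  x <- as.numeric(instance)
  p <- length(x)
  feat <- names(instance) %||% colnames(background) %||% paste0("x", seq_len(p))
  if (ncol(background) != p)
    stop("background and instance have different feature counts", call. = FALSE)
  probs <- predict_proba(handle, matrix(x, nrow = 1,
                                        dimnames = list(NULL, feat)))
  if (is.null(target_class))
    target_class <- colnames(probs)[which.max(probs[1, ])]
  is_bin <- apply(background, 2, function(col) all(col %in% c(0, 1)))
  sds <- apply(background, 2, sd)
  sds[sds == 0] <- 1
  Z <- withr::with_seed(seed, {
    Z <- matrix(rep(x, each = n_samples), nrow = n_samples)
    for (j in seq_len(p)) {
      if (is_bin[j]) {
        flip <- runif(n_samples) < flip_prob
        Z[flip, j] <- 1 - Z[flip, j]
      } else {
        Z[, j] <- Z[, j] + rnorm(n_samples, 0, sds[j])
      }
    }
    Z
  })
  colnames(Z) <- feat
  yz <- predict_proba(handle, Z)[, target_class]
  ## standardise relative to the instance, weight by proximity
  Zs <- sweep(sweep(Z, 2, x, "-"), 2, sds, "/")
  d <- sqrt(rowSums(Zs^2))
  kw <- 0.75 * sqrt(p)
  w <- exp(-(d^2) / kw^2)
  ## weighted ridge fit with intercept
  A <- cbind(1, Zs)
  WA <- A * w
  M <- crossprod(WA, A) + diag(c(0, rep(1e-3, p)))
  beta <- solve(M, crossprod(WA, yz))[-1]
  out <- data.frame(feature = feat, weight = as.numeric(beta),
                    value = x, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight)), ]
  rownames(out) <- NULL
  structure(list(class_probs = probs[1, ], target_class = target_class,
                 weights = out, n_samples = n_samples),
            class = "local_explanation")
}

#' Global feature importance
#'
#' Two interpretations are offered (the source of published global
#' scores is not stated, so both are labelled as such):
#' `"mean_abs_weight"` averages the absolute local surrogate weights of
#' [explain_local()] over a stratified sample of instances;
#' `"permutation"` measures the accuracy drop when one feature column is
#' permuted (clamped at 0, so a constant or irrelevant column scores 0).
#'
#' @param handle a `bench_model` or probability function.
#' @param X evaluation feature matrix (non-empty).
#' @param y labels (required for `"permutation"`).
#' @param method `"mean_abs_weight"` or `"permutation"`.
#' @param n_instances instances sampled for `"mean_abs_weight"`.
#' @param n_samples perturbations per instance.
#' @param seed integer seed.
#' @return a `data.frame` of nonnegative `importance` per `feature`,
#'   sorted descending.
#' @export
explain_global <- function(handle, X, y = NULL,
                           method = c("mean_abs_weight", "permutation"),
                           n_instances = 100, n_samples = 500, seed = 1L) {
  method <- match.arg(method)
  if (!nrow(X)) stop("empty evaluation table", call. = FALSE)
  feat <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- feat
  if (method == "mean_abs_weight") {
    idx <- withr::with_seed(seed, {
      if (is.null(y)) sample(nrow(X), min(n_instances, nrow(X)))
      else {
        ## stratified draw over labels
        unlist(lapply(split(seq_len(nrow(X)), y), function(ii) {
          take <- max(1L, round(n_instances * length(ii) / nrow(X)))
          sample(ii, min(take, length(ii)))
        }), use.names = FALSE)
      }
    })
    W <- vapply(seq_along(idx), function(s) {
      ex <- explain_local(handle, setNames(X[idx[s], ], feat), X,
                          n_samples = n_samples, seed = seed + s)
      ex$weights$weight[match(feat, ex$weights$feature)]
    }, numeric(length(feat)))
    imp <- rowMeans(abs(W))
  } else {
    if (is.null(y)) stop("permutation importance requires labels y", call. = FALSE)
    if (is.function(handle))
      base_pred <- colnames(predict_proba(handle, X))[
        max.col(predict_proba(handle, X), ties.method = "first")]
    else base_pred <- predict_labels(handle, X)
    base_acc <- mean(base_pred == as.character(y))
    imp <- withr::with_seed(seed, vapply(seq_along(feat), function(j) {
      Xp <- X
      Xp[, j] <- X[sample(nrow(X)), j]
      pred <- if (is.function(handle))
        colnames(predict_proba(handle, Xp))[
          max.col(predict_proba(handle, Xp), ties.method = "first")]
      else predict_labels(handle, Xp)
      max(0, base_acc - mean(pred == as.character(y)))
    }, numeric(1)))
  }
  out <- data.frame(feature = feat, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Write a local explanation as a two-column (Weight, Value) CSV
#'
#' @param explanation a `local_explanation`.
#' @param path CSV path.
#' @export
write_local_explanation <- function(explanation, path) {
  df <- explanation$weights
  write.csv(data.frame(Feature = df$feature,
                       Weight = round_half_up(df$weight, 4),
                       Value = df$value),
            path, row.names = FALSE)
  invisible(path)
}
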