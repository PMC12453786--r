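## Mean of a normal truncated to [lo, hi] with pre-truncation location mu
## and scale sd (closed form via the standard hazard terms). The mass of
## the window is computed in whichever tail dominates so the ratio stays
## accurate when the window sits many sd away from mu.
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- if (a > 0) pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE)
  else pnorm(b) - pnorm(a)
  if (z <= 0 || !is.finite(z)) return(if (a > 0) lo else hi)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / z
  min(max(m, lo), hi)
}

## Pre-truncation location whose truncated mean equals `target`.
## Needed because heavily skewed marginals (e.g. age with mean close to
## the lower bound relative to its sd) would otherwise drift upwards
## after clipping to [lo, hi].
calibrate_location <- function(target, sd, lo, hi) {
  span <- hi - lo
  target <- min(max(target, lo + 0.005 * span), hi - 0.005 * span)
  uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target,
          lower = lo - 12 * sd, upper = hi + 12 * sd, tol = 1e-8)$root
}

## Truncated-normal sampler. Central regime: rejection from N(mu, sd),
## keeping draws inside [lo, hi]. When the window carries negligible mass
## (a strongly shifted class mean pushed the location far outside the
## range), rejection would almost never accept, so the draw switches to
## the exact inverse-CDF computed in the dominant tail, which stays
## numerically accurate at tail probabilities near the double-precision
## floor.
rtrunc_reject <- function(n, mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  accept <- if (a > 0) pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE)
  else pnorm(b) - pnorm(a)
  if (accept < 1e-3) {
    u <- runif(n)
    if (a > 0) {
      pa <- pnorm(a, lower.tail = FALSE)
      pb <- pnorm(b, lower.tail = FALSE)
      q <- qnorm(pb + u * (pa - pb), lower.tail = FALSE)
    } else {
      pa <- pnorm(a)
      pb <- pnorm(b)
      q <- qnorm(pa + u * (pb - pa))
    }
    return(pmin(pmax(mu + sd * q, lo), hi))
  }
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / accept * 1.2) + 16L
    x <- rnorm(m, mu, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic patient cohort
#'
#' Samples a complete (no missing values) cohort from a
#' [generator_config()]. Each class contributes `n` rows. Numeric
#' features are drawn from a truncated normal on `[lo, hi]` whose
#' location is calibrated so the class mean equals the configured
#' marginal mean plus the class shift; binary features are Bernoulli
#' with the class positivity (marginal positivity when the class gives
#' none). Generation is fully deterministic given `config$seed`.
#'
#' @param config a validated [generator_config()].
#' @return a `data.frame` with one column per feature plus a `Class`
#'   column, carrying attribute `label_col = "Class"`.
#' @examples
#' cfg <- default_generator_config(seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$Class)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_config("config", "must be a generator_config object")
  specs <- config$feature_specs
  withr::with_seed(config$seed, {
    blocks <- lapply(config$class_profiles, function(cp) {
      cols <- lapply(specs, function(f) {
        if (f$kind == "numeric") {
          shift <- cp$num_shifts[f$name]
          target <- f$mean + if (is.na(shift) || !length(shift)) 0 else unname(shift)
          mu <- calibrate_location(target, f$sd, f$lo, f$hi)
          rtrunc_reject(cp$n, mu, f$sd, f$lo, f$hi)
        } else {
          p <- cp$bin_probs[f$name]
          p <- if (is.na(p) || !length(p)) f$mean else unname(p)
          as.numeric(runif(cp$n) < p)
        }
      })
      names(cols) <- names(specs)
      df <- as.data.frame(cols, check.names = FALSE)
      df$Class <- cp$label
      df
    })
    out <- do.call(rbind, blocks)
  })
  rownames(out) <- NULL
  attr(out, "label_col") <- "Class"
  out
}

#' Mask feature values completely at random
#'
#' Applies per-column MCAR masking at each feature's `missing_rate`.
#' The label column is never masked, and features with rate 0 (age,
#' gender in the default configuration) are untouched.
#'
#' @param table cohort from [generate_cohort()], with no pre-existing
#'   missing values in the targeted columns.
#' @param specs list of [feature_spec()]s (defaults expected to match
#'   the table's columns by name).
#' @param seed integer seed.
#' @return the table with `NA`s inserted.
#' @export
inject_missingness <- function(table, specs, seed = 1L) {
  label_col <- attr(table, "label_col") %||% "Class"
  withr::with_seed(seed, {
    for (f in specs) {
      if (f$missing_rate <= 0) next
      if (f$missing_rate >= 1)
        stop_config("missing_rate", sprintf("must be < 1 for feature '%s'", f$name))
      if (!f$name %in% names(table)) next
      if (f$name == label_col) next
      if (anyNA(table[[f$name]]))
        stop(sprintf("column '%s' already contains missing values", f$name),
             call. = FALSE)
      mask <- runif(nrow(table)) < f$missing_rate
      table[[f$name]][mask] <- NA
    }
  })
  table
}

#' Per-feature summary of a cohort
#'
#' One row per feature column: non-missing count, missing count and
#' percentage, min/max, mean and standard deviation (for a single
#' observed value the standard deviation is reported as 0).
#'
#' @param table a cohort `data.frame`.
#' @return a `data.frame` summary.
#' @export
summarize_cohort <- function(table) {
  if (!nrow(table)) stop("cannot summarize an empty table", call. = FALSE)
  label_col <- attr(table, "label_col") %||% "Class"
  feats <- setdiff(names(table), label_col)
  n <- nrow(table)
  rows <- lapply(feats, function(f) {
    x <- table[[f]]
    obs <- x[!is.na(x)]
    data.frame(
      feature = f,
      count = length(obs),
      missing = n - length(obs),
      missing_pct = round_half_up(100 * (n - length(obs)) / n, 2),
      min = if (length(obs)) min(obs) else NA_real_,
      max = if (length(obs)) max(obs) else NA_real_,
      mean = if (length(obs)) mean(obs) else NA_real_,
      sd = if (length(obs) > 1) sd(obs) else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write a cohort CSV
#'
#' One row per patient, feature columns plus the label column; missing
#' cells are written empty.
#'
#' @param table cohort `data.frame` (for writing).
#' @param path CSV file path.
#' @param label_col label column name.
#' @return `read_cohort` returns the cohort `data.frame`.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, label_col = "Class") {
  out <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = "")
  attr(out, "label_col") <- label_col
  out
}
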