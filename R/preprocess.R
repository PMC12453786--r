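## A column counts as categorical for imputation/encoding purposes when it
## is character/factor/logical, or numeric with all observed values in {0, 1}
## (the at-generation encoding of binary markers).
is_categorical_col <- function(x) {
  if (is.character(x) || is.factor(x) || is.logical(x)) return(TRUE)
  obs <- x[!is.na(x)]
  length(obs) > 0 && all(obs %in% c(0, 1))
}

col_mode <- function(x) {
  obs <- x[!is.na(x)]
  tab <- table(obs)
  mode_chr <- names(tab)[which.max(tab)]  # first maximal category on ties
  if (is.numeric(x)) as.numeric(mode_chr) else mode_chr
}

#' Mean/mode imputation
#'
#' Fills missing feature values with the column mean of the observed
#' values (numeric features) or the most frequent observed category
#' (categorical and 0/1 binary features). The label column is never
#' touched. Imputation is idempotent and preserves numeric column means
#' exactly.
#'
#' @param table cohort `data.frame`, possibly with `NA`s in feature columns.
#' @param label_col label column name.
#' @return a list with `table` (no missing cells) and `report`, a
#'   `data.frame` of per-feature fill value, method and count filled.
#' @export
impute <- function(table, label_col = attr(table, "label_col") %||% "Class") {
  feats <- setdiff(names(table), label_col)
  report <- list()
  for (f in feats) {
    x <- table[[f]]
    n_miss <- sum(is.na(x))
    if (n_miss == length(x))
      stop(sprintf("column '%s' is entirely missing; no mean/mode defined", f),
           call. = FALSE)
    if (n_miss == 0) {
      report[[f]] <- data.frame(feature = f, method = NA_character_,
                                fill = NA_character_, n_filled = 0L,
                                stringsAsFactors = FALSE)
      next
    }
    if (is_categorical_col(x)) {
      fill <- col_mode(x)
      method <- "mode"
    } else {
      fill <- mean(x, na.rm = TRUE)
      method <- "mean"
    }
    x[is.na(x)] <- fill
    table[[f]] <- x
    report[[f]] <- data.frame(feature = f, method = method,
                              fill = as.character(fill), n_filled = n_miss,
                              stringsAsFactors = FALSE)
  }
  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  list(table = table, report = rep_df)
}

## Known binary encodings: level reported as 0 / level reported as 1.
binary_conventions <- list(
  c("F", "M"), c("Female", "Male"),
  c("Negative", "Positive"), c("N", "P"), c("0", "1")
)

binary_levels <- function(levels) {
  for (conv in binary_conventions)
    if (setequal(levels, conv) || all(levels %in% conv)) return(conv)
  sort(levels)
}

#' Encode a cohort into a numeric feature matrix
#'
#' Binary categoricals map to a single 0/1 column (female = 0 / male = 1,
#' negative = 0 / positive = 1); categoricals with more than two levels
#' expand to one-hot blocks with exactly one 1 per row; numeric columns
#' pass through. When `encoder` (a previous result's `encoder` element)
#' is supplied, its mappings are reapplied and an unseen category raises
#' an error naming the column.
#'
#' @param table cohort `data.frame` with no missing values.
#' @param label_col label column name (dropped from the matrix, returned
#'   as a factor `y`; pass a column absent from the table for unlabelled data).
#' @param encoder optional fitted encoder to reapply.
#' @return list with `X` (numeric matrix), `y` (factor or `NULL`) and
#'   `encoder` (per-column mappings, reusable and invertible for binary
#'   columns via [decode_binary()]).
#' @export
encode <- function(table, label_col = attr(table, "label_col") %||% "Class",
                   encoder = NULL) {
  feats <- setdiff(names(table), label_col)
  if (anyNA(table[feats])) stop("encode() requires a table with no missing values",
                                call. = FALSE)
  fit <- is.null(encoder)
  if (fit) encoder <- list()
  cols <- list()
  for (f in feats) {
    x <- table[[f]]
    if (is.factor(x)) x <- as.character(x)
    if (is.character(x) || is.logical(x)) {
      x <- as.character(x)
      if (fit) {
        lev <- unique(x)
        if (length(lev) < 2) lev <- binary_levels(lev)
        encoder[[f]] <- if (length(lev) <= 2)
          list(type = "binary", levels = binary_levels(lev))
        else list(type = "onehot", levels = sort(lev))
      }
      enc <- encoder[[f]]
      if (is.null(enc)) stop(sprintf("no encoding fitted for column '%s'", f),
                             call. = FALSE)
      unseen <- setdiff(unique(x), enc$levels)
      if (length(unseen))
        stop(sprintf("unseen category '%s' in column '%s'", unseen[1], f),
             call. = FALSE)
      if (enc$type == "binary") {
        cols[[f]] <- as.numeric(x == enc$levels[2])
      } else {
        block <- vapply(enc$levels, function(l) as.numeric(x == l),
                        numeric(length(x)))
        colnames(block) <- paste(f, enc$levels, sep = "=")
        cols[[f]] <- block
      }
    } else {
      if (fit) encoder[[f]] <- list(type = "numeric")
      cols[[f]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, lapply(names(cols), function(f) {
    m <- cols[[f]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1, dimnames = list(NULL, f))
    m
  }))
  y <- if (label_col %in% names(table)) factor(table[[label_col]]) else NULL
  list(X = X, y = y, encoder = encoder)
}

#' @rdname encode
#' @param values 0/1 vector to decode.
#' @param enc one element of a fitted encoder, of type `"binary"`.
#' @export
decode_binary <- function(values, enc) {
  stopifnot(enc$type == "binary")
  enc$levels[values + 1]
}

#' ADASYN configuration
#'
#' @param target_class minority label to oversample.
#' @param k neighbour count for the local-imbalance and interpolation
#'   searches (default 5).
#' @param beta desired balance level in `(0, 1]`; the number of synthetic
#'   samples is `G = (n_maj - n_min) * beta`.
#' @param seed integer seed.
#' @return an `adasyn_config` list.
#' @export
adasyn_config <- function(target_class, k = 5L, beta = 1, seed = 1L) {
  if (k < 1) stop_config("k", "must be >= 1")
  if (beta < 0 || beta > 1) stop_config("beta", "must lie in [0, 1]")
  structure(list(target_class = target_class, k = as.integer(k),
                 beta = beta, seed = as.integer(seed)),
            class = "adasyn_config")
}

#' ADASYN adaptive synthetic oversampling
#'
#' Oversamples the minority class by interpolation, allocating more
#' synthetic points to minority samples whose neighbourhoods are
#' dominated by other classes. The four steps: the synthetic budget
#' `G = (n_maj - n_min) * beta` where `n_maj` is the size of the largest
#' class; per minority point the fraction `eta_i` of its `k` nearest
#' neighbours (searched over the entire dataset, Euclidean distance on
#' min-max scaled features) that belong to other classes; normalised
#' weights `r_i = eta_i / sum(eta)`; per-point counts `g_i = r_i * G`
#' rounded half-up, with the residual added to or removed from the
#' largest-`r_i` points so the counts sum to `G`. Each synthetic point
#' is `x_i + delta * (x_zi - x_i)` with `x_zi` one of the `k` nearest
#' minority neighbours and `delta ~ U(0, 1)`, so all synthetic points
#' lie on segments between two original minority points. Original rows
#' are preserved verbatim and only minority-labelled rows are added.
#'
#' @param X numeric feature matrix.
#' @param y label vector (factor or character), same length as `nrow(X)`.
#' @param cfg an [adasyn_config()].
#' @param delta optional fixed interpolation factor (testing hook);
#'   default `NULL` draws `delta ~ U(0,1)` per synthetic point.
#' @return list with `X`, `y` (originals followed by synthetic rows) and
#'   `info` (G, eta, r, g per minority point, plus the minority indices).
#' @export
adasyn <- function(X, y, cfg, delta = NULL) {
  stopifnot(inherits(cfg, "adasyn_config"))
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  min_idx <- which(y == cfg$target_class)
  m <- length(min_idx)
  if (m < cfg$k + 1)
    stop(sprintf("minority class '%s' has %d samples; need at least k + 1 = %d",
                 cfg$target_class, m, cfg$k + 1), call. = FALSE)
  counts <- table(y)
  n_maj <- max(counts)
  G <- round_half_up((n_maj - m) * cfg$beta)
  if (cfg$beta == 0 || G <= 0) {
    warning("beta = 0 or no imbalance: nothing to generate")
    return(list(X = X, y = y, info = list(G = 0)))
  }
  S <- min_max_scale(X)
  ## local imbalance: k NN over the entire dataset, self excluded
  nn_all <- nn_index(S[min_idx, , drop = FALSE], S, cfg$k, exclude = min_idx)
  eta <- rowMeans(matrix(y[nn_all] != cfg$target_class, nrow = m))
  r <- if (sum(eta) > 0) eta / sum(eta) else rep(1 / m, m)
  g <- round_half_up(r * G)
  ## redistribute the rounding residual on the largest-r_i points
  ord <- order(-r, seq_along(r))
  excess <- sum(g) - G
  j <- 1L
  while (excess != 0) {
    i <- ord[(j - 1L) %% m + 1L]
    if (excess > 0 && g[i] > 0) { g[i] <- g[i] - 1L; excess <- excess - 1L }
    else if (excess < 0)        { g[i] <- g[i] + 1L; excess <- excess + 1L }
    j <- j + 1L
  }
  ## k nearest minority neighbours for interpolation
  nn_min <- nn_index(S[min_idx, , drop = FALSE], S[min_idx, , drop = FALSE],
                     cfg$k, exclude = seq_len(m))
  synth <- withr::with_seed(cfg$seed, {
    rows <- vector("list", m)
    for (i in seq_len(m)) {
      if (g[i] == 0) next
      z <- sample.int(cfg$k, g[i], replace = TRUE)
      d <- if (is.null(delta)) runif(g[i]) else rep(delta, g[i])
      xi <- X[min_idx[i], ]
      rows[[i]] <- t(vapply(seq_len(g[i]), function(s) {
        xz <- X[min_idx[nn_min[i, z[s]]], ]
        xi + d[s] * (xz - xi)
      }, numeric(ncol(X))))
    }
    do.call(rbind, rows)
  })
  if (is.null(synth)) synth <- matrix(numeric(0), ncol = ncol(X))
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth),
       y = c(y, rep(cfg$target_class, nrow(synth))),
       info = list(G = G, eta = eta, r = r, g = g, minority_index = min_idx))
}

#' Stratified train/test split
#'
#' Splits per class: `round(train_fraction * n)` rows (half-up) go to
#' the training set, the remainder to the test set. Membership is a
#' seeded random draw within each class; the two parts are disjoint and
#' their union is the input.
#'
#' @param table cohort `data.frame`.
#' @param train_fraction fraction in `(0, 1)`, default 0.70.
#' @param label_col label column name.
#' @param seed integer seed.
#' @return list with `train` and `test` data frames.
#' @export
stratified_split <- function(table, train_fraction = 0.7,
                             label_col = attr(table, "label_col") %||% "Class",
                             seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction", "must lie strictly between 0 and 1")
  cls <- split(seq_len(nrow(table)), table[[label_col]])
  small <- names(cls)[vapply(cls, length, integer(1)) < 2]
  if (length(small))
    stop(sprintf("class(es) with fewer than 2 rows cannot be split: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  tr_idx <- withr::with_seed(seed, {
    unlist(lapply(cls, function(idx) {
      n_tr <- round_half_up(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train <- table[sort(tr_idx), , drop = FALSE]
  test <- table[setdiff(seq_len(nrow(table)), tr_idx), , drop = FALSE]
  attr(train, "label_col") <- label_col
  attr(test, "label_col") <- label_col
  list(train = train, test = test)
}
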