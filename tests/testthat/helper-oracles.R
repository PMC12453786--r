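## Independent brute-force oracles. These deliberately share no code with
## the package: plain loops, direct textbook formulas, and their own
## tie-break conventions matching the documented contracts.

ext_fixture <- function(f) system.file("extdata", f, package = "fdosmbench")

## Direct evaluation of the metric-suite formulas from one-vs-rest counts
## obtained by an explicit pairwise tally.
brute_metrics <- function(y_true, y_pred, classes = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  N <- length(y_true)
  prec <- rec <- f1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    k <- classes[ci]
    tp <- fp <- fn <- 0
    for (i in seq_len(N)) {
      if (y_pred[i] == k && y_true[i] == k) tp <- tp + 1
      if (y_pred[i] == k && y_true[i] != k) fp <- fp + 1
      if (y_pred[i] != k && y_true[i] == k) fn <- fn + 1
    }
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec[ci] + rec[ci] > 0)
      2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci]) else 0
  }
  correct <- sum(y_true == y_pred)
  p_o <- correct / N
  p_e <- 0
  for (k in classes)
    p_e <- p_e + (sum(y_true == k) / N) * (sum(y_pred == k) / N)
  kappa <- (p_o - p_e) / (1 - p_e)
  ## Gorodkin via the covariance form
  t_k <- sapply(classes, function(k) sum(y_true == k))
  p_k <- sapply(classes, function(k) sum(y_pred == k))
  num <- correct * N - sum(t_k * p_k)
  den <- sqrt(N^2 - sum(p_k^2)) * sqrt(N^2 - sum(t_k^2))
  mcc <- if (den > 0) num / den else 0
  c(precision = 100 * mean(prec), recall = 100 * mean(rec),
    f_score = 100 * mean(f1), kappa = 100 * kappa,
    hamming_loss = 100 * (1 - p_o), mcc = 100 * mcc,
    accuracy = 100 * p_o)
}

## Loop-based re-derivation of the per-point synthetic allocation
## (budget, local imbalance, normalisation, half-up rounding with
## largest-weight redistribution), using its own distance computation.
brute_adasyn_g <- function(X, y, target, k, beta) {
  y <- as.character(y)
  idx <- which(y == target)
  m <- length(idx)
  n_maj <- max(table(y))
  G <- floor((n_maj - m) * beta + 0.5 + 1e-9)
  ## min-max scale
  S <- X
  for (j in seq_len(ncol(S))) {
    rng <- range(S[, j])
    S[, j] <- if (diff(rng) > 0) (S[, j] - rng[1]) / diff(rng) else 0
  }
  eta <- numeric(m)
  for (ii in seq_len(m)) {
    i <- idx[ii]
    d <- sqrt(rowSums((S - matrix(S[i, ], nrow(S), ncol(S), byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d, seq_along(d))[1:k]
    eta[ii] <- sum(y[nb] != target) / k
  }
  r <- if (sum(eta) > 0) eta / sum(eta) else rep(1 / m, m)
  g <- floor(r * G + 0.5 + 1e-9)
  ord <- order(-r, seq_along(r))
  excess <- sum(g) - G
  j <- 1
  while (excess != 0) {
    i <- ord[(j - 1) %% m + 1]
    if (excess > 0 && g[i] > 0) { g[i] <- g[i] - 1; excess <- excess - 1 }
    else if (excess < 0) { g[i] <- g[i] + 1; excess <- excess + 1 }
    j <- j + 1
  }
  list(G = G, eta = eta, r = r, g = g)
}

## Random confusion pair on k classes with a controllable error rate.
random_labels <- function(n, k, err = 0.3) {
  classes <- LETTERS[seq_len(k)]
  y <- sample(classes, n, replace = TRUE)
  p <- y
  flip <- runif(n) < err
  p[flip] <- sample(classes, sum(flip), replace = TRUE)
  list(y_true = y, y_pred = p, classes = classes)
}

## Small fully separated dataset: class = quadrant sign pattern.
separable_toy <- function(n_per = 20, seed = 99) {
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
    X <- do.call(rbind, lapply(1:4, function(k)
      cbind(rnorm(n_per, centers[k, 1], 0.4), rnorm(n_per, centers[k, 2], 0.4))))
    colnames(X) <- c("f1", "f2")
    y <- factor(rep(paste0("c", 1:4), each = n_per))
    list(X = X, y = y)
  })
}

## A small preprocessed cohort shared across bench/explain tests.
scaled_cohort <- function(frac = 0.15, seed = 201) {
  cfg <- default_generator_config(seed = seed)
  for (i in seq_along(cfg$class_profiles))
    cfg$class_profiles[[i]]$n <- as.integer(ceiling(cfg$class_profiles[[i]]$n * frac))
  coh <- generate_cohort(cfg)
  miss <- inject_missingness(coh, cfg$feature_specs, seed = seed + 1)
  enc <- encode(impute(miss)$table)
  df <- data.frame(enc$X, check.names = FALSE)
  df$Class <- as.character(enc$y)
  sp <- stratified_split(df, 0.7, label_col = "Class", seed = seed + 2)
  tr <- encode(sp$train, "Class")
  te <- encode(sp$test, "Class", encoder = tr$encoder)
  list(train = tr, test = te, config = cfg)
}
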