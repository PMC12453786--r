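#' Per-class confusion counts
#'
#' Tabulates the K-by-K confusion table and derives one-vs-rest counts
#' (TP, FP, FN, TN) per class. For every class TP + FP + FN + TN = N and
#' the TPs sum to the number of correct predictions.
#'
#' @param y_true,y_pred equal-length label vectors; predictions must lie
#'   within the class vocabulary.
#' @param classes class vocabulary; defaults to the sorted union of the
#'   observed labels.
#' @return a `confusion_counts` object: the confusion `table`, a per-class
#'   `counts` data frame, and `N`.
#' @export
confusion_counts <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths", call. = FALSE)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(y_pred %in% classes) || !all(y_true %in% classes))
    stop("labels outside the class vocabulary", call. = FALSE)
  tt <- factor(y_true, levels = classes)
  pp <- factor(y_pred, levels = classes)
  tab <- table(true = tt, pred = pp)
  N <- length(y_true)
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  tn <- N - tp - fn - fp
  structure(list(
    table = tab, N = N, classes = classes,
    counts = data.frame(class = classes, TP = as.integer(tp),
                        FP = as.integer(fp), FN = as.integer(fn),
                        TN = as.integer(tn), row.names = NULL)
  ), class = "confusion_counts")
}

#' Seven-metric evaluation report
#'
#' Computes the benchmark metric suite from confusion counts, all as
#' percentages: macro-averaged precision, recall and F-score (per-class
#' one-vs-rest ratios averaged over classes, a class with an empty
#' denominator contributing 0 and being flagged), multiclass Cohen's
#' kappa `(p_o - p_e) / (1 - p_e)`, Hamming loss (for single-label
#' multiclass, the error rate, so HL = 100 - accuracy exactly),
#' the Gorodkin multiclass Matthews correlation coefficient, and
#' accuracy.
#'
#' @param counts a [confusion_counts()] object.
#' @return a `metric_report`: named list of the seven percentages plus
#'   `flags` naming degenerate per-class terms.
#' @export
metric_report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  cc <- counts$counts
  N <- counts$N
  tab <- counts$table
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  prec_k <- safe_div(cc$TP, cc$TP + cc$FP)
  rec_k <- safe_div(cc$TP, cc$TP + cc$FN)
  f_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  flags <- character(0)
  if (any(cc$TP + cc$FP == 0))
    flags <- c(flags, paste0("precision undefined (0 used): ",
                             paste(cc$class[cc$TP + cc$FP == 0], collapse = ",")))
  if (any(cc$TP + cc$FN == 0))
    flags <- c(flags, paste0("recall undefined (0 used): ",
                             paste(cc$class[cc$TP + cc$FN == 0], collapse = ",")))
  correct <- sum(diag(tab))
  p_o <- correct / N
  p_e <- sum(rowSums(tab) * colSums(tab)) / N^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  ## Gorodkin multiclass MCC
  t_k <- rowSums(tab)  # true counts
  p_k <- colSums(tab)  # predicted counts
  num <- correct * N - sum(as.numeric(t_k) * p_k)
  den <- sqrt(N^2 - sum(as.numeric(p_k)^2)) * sqrt(N^2 - sum(as.numeric(t_k)^2))
  mcc <- if (den > 0) num / den else 0
  structure(list(
    precision = 100 * mean(prec_k),
    recall = 100 * mean(rec_k),
    f_score = 100 * mean(f_k),
    kappa = 100 * kappa,
    hamming_loss = 100 * (1 - p_o),
    mcc = 100 * mcc,
    accuracy = 100 * p_o,
    flags = flags
  ), class = "metric_report")
}

metric_names <- c("precision", "recall", "f_score", "kappa",
                  "hamming_loss", "mcc", "accuracy")

#' @export
as.data.frame.metric_report <- function(x, ...) {
  as.data.frame(x[metric_names])
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  v <- round_half_up(unlist(x[metric_names]), digits)
  print(v)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Overfitting report from cross-validation means
#'
#' The overfitting percentage is `(train - validation) / train * 100`,
#' rounded to 2 decimals, with status `"Yes"` at 10% or more, `"Mild"`
#' from 5% up to 10%, `"No"` below 5%.
#'
#' @param train_mean,validation_mean mean accuracies as proportions;
#'   `train_mean` must be positive.
#' @return an `overfit_report` list: `train_mean`, `validation_mean`,
#'   `overfit_pct`, `status`.
#' @export
overfit <- function(train_mean, validation_mean) {
  if (!is.finite(train_mean) || train_mean <= 0)
    stop("train_mean must be > 0", call. = FALSE)
  pct <- round_half_up((train_mean - validation_mean) / train_mean * 100, 2)
  status <- if (pct >= 10) "Yes" else if (pct >= 5) "Mild" else "No"
  structure(list(train_mean = train_mean, validation_mean = validation_mean,
                 overfit_pct = pct, status = status),
            class = "overfit_report")
}

#' Balanced-versus-unbalanced difference report
#'
#' Per metric, the absolute difference `AD = balanced - unbalanced` and
#' the percentage difference `PD = AD / unbalanced * 100` (rounded to 2
#' decimals; a zero unbalanced value leaves PD `NA` and flags it).
#'
#' @param balanced,unbalanced [metric_report()] objects or named numeric
#'   vectors over the same metric set.
#' @return a `diff_report` data frame with columns `metric`, `AD`, `PD`.
#' @export
diff_report <- function(balanced, unbalanced) {
  to_vec <- function(r) {
    if (inherits(r, "metric_report")) unlist(r[metric_names])
    else unlist(r)
  }
  b <- to_vec(balanced)
  u <- to_vec(unbalanced)
  if (!setequal(names(b), names(u)))
    stop("metric sets differ between the two reports", call. = FALSE)
  u <- u[names(b)]
  ad <- b - u
  pd <- ifelse(u != 0, round_half_up(ad / u * 100, 2), NA_real_)
  out <- data.frame(metric = names(b), AD = unname(ad), PD = unname(pd),
                    stringsAsFactors = FALSE)
  if (anyNA(pd))
    attr(out, "flags") <- paste0("PD undefined (unbalanced = 0): ",
                                 paste(out$metric[is.na(pd)], collapse = ","))
  class(out) <- c("diff_report", "data.frame")
  out
}

#' One-vs-rest ROC AUC
#'
#' Per-class area under the ROC curve computed by the Mann-Whitney rank
#' statistic (midranks for ties), plus the macro mean over classes with
#' both positives and negatives present.
#'
#' @param y_true label vector.
#' @param class_scores numeric matrix of scores, one column per class
#'   (column names are the class vocabulary).
#' @return list with `per_class` (named AUCs, `NA` where undefined) and
#'   `macro`.
#' @export
roc_auc <- function(y_true, class_scores) {
  y_true <- as.character(y_true)
  classes <- colnames(class_scores)
  if (is.null(classes)) stop("class_scores must have column names", call. = FALSE)
  if (length(unique(y_true)) < 2)
    stop("AUC undefined for single-class truth", call. = FALSE)
  aucs <- vapply(classes, function(k) {
    pos <- y_true == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(class_scores[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}
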