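fdosm_terms <- c("ND", "SD", "D", "BD", "HD")

#' Decision matrix
#'
#' Alternatives-by-criteria table of raw performance values with a
#' direction per criterion: `"benefit"` (larger is better), `"cost"`
#' (smaller is better) or `"critical"` (closest to a stated target is
#' best; requires `critical_targets`).
#'
#' @param values numeric matrix (alternatives in rows).
#' @param alternatives,criteria row/column names.
#' @param directions character vector, one per criterion.
#' @param critical_targets named numeric vector of targets for
#'   `"critical"` criteria.
#' @return a `decision_matrix` object.
#' @export
decision_matrix <- function(values, alternatives = rownames(values),
                            criteria = colnames(values),
                            directions = rep("benefit", ncol(values)),
                            critical_targets = NULL) {
  values <- as.matrix(values)
  if (!nrow(values) || !ncol(values)) stop("decision matrix must be non-empty",
                                           call. = FALSE)
  if (is.null(alternatives)) alternatives <- paste0("A", seq_len(nrow(values)))
  if (is.null(criteria)) criteria <- paste0("C", seq_len(ncol(values)))
  if (!all(is.finite(values))) stop("decision matrix values must be finite",
                                    call. = FALSE)
  if (length(directions) != ncol(values))
    stop("one direction per criterion required", call. = FALSE)
  if (!all(directions %in% c("benefit", "cost", "critical")))
    stop("directions must be 'benefit', 'cost' or 'critical'", call. = FALSE)
  crit <- criteria[directions == "critical"]
  if (length(crit) && (is.null(critical_targets) ||
                       !all(crit %in% names(critical_targets))))
    stop("critical criteria require critical_targets", call. = FALSE)
  dimnames(values) <- list(alternatives, criteria)
  structure(list(values = values, directions = setNames(directions, criteria),
                 critical_targets = critical_targets),
            class = "decision_matrix")
}

#' Read a decision matrix from CSV (+ optional JSON direction sidecar)
#'
#' The CSV holds alternatives in rows (first column = names); the JSON
#' sidecar maps criterion name to direction, defaulting every criterion
#' to benefit when absent.
#'
#' @param path CSV path.
#' @param directions_path optional JSON sidecar path.
#' @return a [decision_matrix()].
#' @export
read_decision_matrix <- function(path, directions_path = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  dirs <- rep("benefit", ncol(vals))
  names(dirs) <- colnames(vals)
  if (!is.null(directions_path)) {
    side <- unlist(jsonlite::read_json(directions_path, simplifyVector = TRUE))
    dirs[names(side)[names(side) %in% names(dirs)]] <-
      side[names(side) %in% names(dirs)]
  }
  decision_matrix(vals, directions = unname(dirs))
}

#' Per-criterion ideal solution
#'
#' Benefit criteria take the column maximum, cost criteria the column
#' minimum, critical criteria the value nearest the stated target
#' (first-listed alternative wins ties).
#'
#' @param dm a [decision_matrix()].
#' @return data frame with `criterion`, `direction`, `ideal`, and the
#'   `alternative` attaining it.
#' @export
ideal_solution <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  v <- dm$values
  out <- lapply(colnames(v), function(cn) {
    col <- v[, cn]
    idx <- switch(dm$directions[[cn]],
                  benefit = which.max(col),
                  cost = which.min(col),
                  critical = which.min(abs(col - dm$critical_targets[[cn]])))
    data.frame(criterion = cn, direction = dm$directions[[cn]],
               ideal = col[[idx]], alternative = rownames(v)[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Triangular fuzzy membership scale
#'
#' The five ordered linguistic terms - No Difference (ND), Slight
#' Difference (SD), Difference (D), Big Difference (BD), Huge
#' Difference (HD) - and their triangular fuzzy numbers `(V1, V2, V3)`.
#' Defaults are the published scale.
#'
#' @param mapping data frame with columns `term`, `V1`, `V2`, `V3`.
#' @return a `tfm_scale` data frame.
#' @export
tfm_scale <- function(mapping = NULL) {
  if (is.null(mapping))
    mapping <- data.frame(
      term = fdosm_terms,
      V1 = c(0.00, 0.10, 0.30, 0.50, 0.75),
      V2 = c(0.10, 0.30, 0.50, 0.75, 0.90),
      V3 = c(0.30, 0.50, 0.75, 0.90, 1.00),
      stringsAsFactors = FALSE)
  stopifnot(all(c("term", "V1", "V2", "V3") %in% names(mapping)))
  if (any(mapping$V1 > mapping$V2 | mapping$V2 > mapping$V3))
    stop("each TFM must satisfy V1 <= V2 <= V3", call. = FALSE)
  structure(mapping, class = c("tfm_scale", "data.frame"))
}

#' Expert opinion matrix
#'
#' A grid of linguistic terms, one row per alternative and one column
#' per criterion, expressing one expert's judgement of each cell's
#' distance from the criterion's ideal solution.
#'
#' @param terms character matrix (or data frame) of term symbols.
#' @param expert optional expert identifier.
#' @return an `opinion_matrix` object.
#' @export
opinion_matrix <- function(terms, expert = NULL) {
  terms <- as.matrix(terms)
  bad_mat <- matrix(!(terms %in% fdosm_terms), nrow = nrow(terms))
  bad <- which(bad_mat, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unknown linguistic term '%s' at row %d, column %d",
                 terms[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]),
         call. = FALSE)
  structure(list(terms = terms, expert = expert), class = "opinion_matrix")
}

#' Load an expert opinion matrix
#'
#' Reads a CSV of term symbols (first column = alternative names) or
#' validates a data frame / matrix. When a decision matrix is supplied,
#' each criterion's ideal alternative is checked to carry `ND` (a
#' warning is raised otherwise, since the ideal solution has no
#' difference from itself).
#'
#' @param source CSV path, data frame or matrix.
#' @param dm optional [decision_matrix()] for shape/ideal validation.
#' @param expert optional expert identifier.
#' @return an `opinion_matrix`.
#' @export
load_opinions <- function(source, dm = NULL, expert = NULL) {
  if (is.character(source) && length(source) == 1) {
    df <- read.csv(source, check.names = FALSE, stringsAsFactors = FALSE)
    terms <- as.matrix(df[, -1, drop = FALSE])
    rownames(terms) <- df[[1]]
  } else {
    terms <- as.matrix(source)
  }
  om <- opinion_matrix(terms, expert = expert)
  if (!is.null(dm)) {
    if (!identical(dim(om$terms), dim(dm$values)))
      stop("opinion matrix shape does not match the decision matrix",
           call. = FALSE)
    ideal <- ideal_solution(dm)
    for (j in seq_len(nrow(ideal))) {
      i <- match(ideal$alternative[j], rownames(dm$values))
      if (om$terms[i, j] != "ND")
        warning(sprintf(
          "ideal alternative '%s' for criterion '%s' is not marked ND",
          ideal$alternative[j], ideal$criterion[j]))
    }
  }
  om
}

term_means <- function(scale) {
  setNames((scale$V1 + scale$V2 + scale$V3) / 3, scale$term)
}

#' Fuzzy opinion scores
#'
#' Converts each linguistic term to its triangular fuzzy number and
#' defuzzifies by the mean `(V1 + V2 + V3) / 3`, then aggregates across
#' criteria. Two aggregation conventions are provided, matching the two
#' conventions observable in the published results:
#' \describe{
#'   \item{`"mean"` (default)}{the per-criterion fuzzy means are averaged
#'     unrounded across criteria and the alternative's score is rounded
#'     to 4 decimals. Reproduces the per-expert scores of the main
#'     ranking table (e.g. an all-ND row scores 0.1333, six ND plus one
#'     SD scores 0.1571).}
#'   \item{`"sum"`}{each per-criterion fuzzy mean is rounded to 4
#'     decimals first and the rounded values are summed (the worked
#'     three-model example: two D terms give 0.5167 + 0.5167 = 1.0334).}
#' }
#'
#' @param op an [opinion_matrix()].
#' @param scale a [tfm_scale()].
#' @param aggregation `"mean"` or `"sum"`.
#' @return a `score_table` data frame with `alternative`, `score`,
#'   `rank` (rank 1 = lowest score = best).
#' @export
fuzzy_scores <- function(op, scale = tfm_scale(),
                         aggregation = c("mean", "sum")) {
  stopifnot(inherits(op, "opinion_matrix"))
  aggregation <- match.arg(aggregation)
  tm <- term_means(scale)
  vals <- matrix(tm[op$terms], nrow = nrow(op$terms),
                 dimnames = dimnames(op$terms))
  score <- if (aggregation == "sum")
    round_half_up(rowSums(round_half_up(vals, 4)), 4)
  else
    round_half_up(rowMeans(vals), 4)
  st <- data.frame(alternative = rownames(op$terms) %||%
                     paste0("A", seq_len(nrow(op$terms))),
                   score = unname(score), stringsAsFactors = FALSE)
  st <- rank_scores(st)
  attr(st, "expert") <- op$expert
  attr(st, "aggregation") <- aggregation
  class(st) <- c("score_table", "data.frame")
  st
}

#' Rank a score table
#'
#' `rank_i = 1 +` number of strictly smaller scores; tied alternatives
#' share the smallest applicable rank, and the lowest score ranks 1
#' (best).
#'
#' @param scores data frame with a `score` column.
#' @return the data frame with a `rank` column added/replaced.
#' @export
rank_scores <- function(scores) {
  s <- scores$score
  scores$rank <- vapply(s, function(x) 1L + sum(s < x), integer(1))
  scores
}

#' Group decision from per-expert score tables
#'
#' The group score per alternative is the arithmetic mean of the
#' per-expert scores (which are already rounded to 4 decimals), rounded
#' to 4 decimals, then ranked.
#'
#' @param per_expert list of `score_table`s over identical alternatives.
#' @return a group `score_table`.
#' @export
group_decision <- function(per_expert) {
  if (!length(per_expert)) stop("need at least one expert table", call. = FALSE)
  alts <- per_expert[[1]]$alternative
  for (st in per_expert)
    if (!identical(st$alternative, alts))
      stop("expert score tables cover different alternatives", call. = FALSE)
  mat <- vapply(per_expert, `[[`, numeric(length(alts)), "score")
  mat <- matrix(mat, nrow = length(alts))
  out <- data.frame(alternative = alts,
                    score = round_half_up(rowMeans(mat), 4),
                    stringsAsFactors = FALSE)
  out <- rank_scores(out)
  attr(out, "context") <- "group"
  class(out) <- c("score_table", "data.frame")
  out
}

#' Run the full FDOSM pipeline
#'
#' Ideal solutions from the decision matrix, per-expert fuzzy scores and
#' ranks from the opinion matrices, and the group (final) ranking.
#'
#' @param dm a [decision_matrix()].
#' @param opinions list of opinion sources accepted by [load_opinions()].
#' @param scale a [tfm_scale()].
#' @param aggregation `"mean"` or `"sum"` (see [fuzzy_scores()]).
#' @return an `fdosm_result` list: `ideal`, `per_expert` (score tables),
#'   `group`, `aggregation`.
#' @export
run_fdosm <- function(dm, opinions, scale = tfm_scale(),
                      aggregation = "mean") {
  stopifnot(inherits(dm, "decision_matrix"))
  oms <- lapply(seq_along(opinions), function(i) {
    src <- opinions[[i]]
    if (inherits(src, "opinion_matrix")) src
    else load_opinions(src, dm = dm,
                       expert = names(opinions)[i] %||% paste0("expert", i))
  })
  per_expert <- lapply(oms, fuzzy_scores, scale = scale,
                       aggregation = aggregation)
  structure(list(ideal = ideal_solution(dm), per_expert = per_expert,
                 group = group_decision(per_expert),
                 aggregation = aggregation),
            class = "fdosm_result")
}

#' @export
print.fdosm_result <- function(x, ...) {
  wide <- data.frame(alternative = x$group$alternative,
                     stringsAsFactors = FALSE)
  for (i in seq_along(x$per_expert)) {
    wide[[paste0("score_e", i)]] <- x$per_expert[[i]]$score
    wide[[paste0("rank_e", i)]] <- x$per_expert[[i]]$rank
  }
  wide$final_score <- x$group$score
  wide$final_rank <- x$group$rank
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write a score table (per-expert columns plus final decision) to CSV
#'
#' @param result an `fdosm_result`.
#' @param path CSV path.
#' @export
write_score_table <- function(result, path) {
  stopifnot(inherits(result, "fdosm_result"))
  wide <- data.frame(alternative = result$group$alternative,
                     stringsAsFactors = FALSE)
  for (i in seq_along(result$per_expert)) {
    wide[[paste0("score_e", i)]] <- result$per_expert[[i]]$score
    wide[[paste0("rank_e", i)]] <- result$per_expert[[i]]$rank
  }
  wide$final_score <- result$group$score
  wide$final_rank <- result$group$rank
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Suggest linguistic terms from a decision matrix (demo helper)
#'
#' A non-normative, invented convenience for demonstrations: maps each
#' cell's normalised gap to the criterion's ideal value into the five
#' terms by equal-width bins. Real FDOSM opinions are expert judgements
#' and are inputs, never computed; do not use this helper to fabricate
#' expert data in analyses.
#'
#' @param dm a [decision_matrix()].
#' @return an [opinion_matrix()].
#' @export
suggest_opinions <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  ideal <- ideal_solution(dm)
  gaps <- vapply(seq_len(ncol(dm$values)), function(j) {
    g <- abs(dm$values[, j] - ideal$ideal[j])
    if (max(g) > 0) g / max(g) else g
  }, numeric(nrow(dm$values)))
  terms <- matrix(fdosm_terms[findInterval(gaps, c(-Inf, 1e-12, 0.25, 0.5, 0.75))],
                  nrow = nrow(dm$values), dimnames = dimnames(dm$values))
  opinion_matrix(terms, expert = "suggested")
}
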