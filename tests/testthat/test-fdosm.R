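scale8 <- tfm_scale()

test_that("ideal solutions follow the criterion direction", {
  dm9 <- read_decision_matrix(ext_fixture("table9_dm.csv"))
  ideal <- ideal_solution(dm9)
  expect_equal(ideal$ideal[ideal$criterion == "Precision"], 83.6)
  expect_equal(ideal$alternative[ideal$criterion == "Precision"], "DT")
  expect_equal(ideal$ideal[ideal$criterion == "Accuracy"], 82.9)

  dm_cost <- decision_matrix(matrix(c(0.1, 0.2), ncol = 1,
                                    dimnames = list(c("a", "b"), "c1")),
                             directions = "cost")
  expect_equal(ideal_solution(dm_cost)$ideal, 0.1)

  dm_crit <- decision_matrix(matrix(c(30, 49, 80), ncol = 1,
                                    dimnames = list(c("a", "b", "c"), "c1")),
                             directions = "critical",
                             critical_targets = c(c1 = 50))
  expect_equal(ideal_solution(dm_crit)$ideal, 49)
  expect_error(decision_matrix(matrix(1), directions = "critical"),
               "critical_targets")
})

test_that("opinion matrices load, validate symbols and check the ideal cells", {
  om <- load_opinions(ext_fixture("expert1.csv"))
  expect_equal(dim(om$terms), c(12, 7))
  expect_true(all(om$terms["GBoost", ] == "ND"))

  expect_silent(opinion_matrix(matrix("ND", 1, 1)))
  expect_error(opinion_matrix(matrix(c("ND", "XX"), 1, 2)),
               "unknown linguistic term 'XX' at row 1, column 2")

  dm <- read_decision_matrix(ext_fixture("dm_balanced.csv"),
                             ext_fixture("dm_directions.json"))
  bad <- as.data.frame(matrix("SD", 12, 7))
  rownames(bad) <- rownames(dm$values)
  w <- capture_warnings(load_opinions(as.matrix(bad), dm = dm))
  expect_true(all(grepl("not marked ND", w)) && length(w) == 7)
})

test_that("fuzzy scores hit the reference values in both aggregation modes", {
  ## all-ND and all-HD rows bound the mean-mode score range
  allnd <- fuzzy_scores(opinion_matrix(matrix("ND", 1, 7)), scale8, "mean")
  expect_equal(allnd$score, 0.1333)
  allhd <- fuzzy_scores(opinion_matrix(matrix("HD", 1, 7)), scale8, "mean")
  expect_equal(allhd$score, 0.8833)
  ## six ND plus one SD averages to 0.1571
  rf_row <- matrix(c("ND", "SD", "ND", "ND", "ND", "ND", "ND"), 1, 7)
  expect_equal(fuzzy_scores(opinion_matrix(rf_row), scale8, "mean")$score, 0.1571)
  ## worked example, sum mode: D+D = 0.5167 + 0.5167
  ex <- opinion_matrix(rbind(c("D", "D"), c("BD", "BD"), c("ND", "ND")))
  st <- fuzzy_scores(ex, scale8, "sum")
  expect_equal(st$score, c(1.0334, 1.4334, 0.2666))
  expect_equal(st$rank, c(2L, 3L, 1L))
})

test_that("ranking counts strictly smaller scores with shared ties", {
  st <- rank_scores(data.frame(score = c(1.0334, 1.4334, 0.2666)))
  expect_equal(st$rank, c(2L, 3L, 1L))
  tie <- rank_scores(data.frame(score = c(0.5, 0.5)))
  expect_equal(tie$rank, c(1L, 1L))
  withr::with_seed(5, {
    for (i in 1:25) {
      s <- runif(sample(2:10, 1))
      rk <- rank_scores(data.frame(score = s))$rank
      expect_equal(sort(rk), seq_along(s))  # distinct scores -> permutation
    }
  })
})

test_that("group decisions average per-expert scores before re-ranking", {
  mk <- function(s) {
    st <- data.frame(alternative = c("XGBoost", "KNN"), score = s,
                     stringsAsFactors = FALSE)
    class(st) <- c("score_table", "data.frame")
    rank_scores(st)
  }
  g <- group_decision(list(mk(c(0.2286, 0.6595)), mk(c(0.181, 0.5738)),
                           mk(c(0.2048, 0.6881))))
  expect_equal(g$score, c(0.2048, 0.6405))
  single <- group_decision(list(mk(c(0.3, 0.4))))
  expect_equal(single$score, c(0.3, 0.4))
  bad <- mk(c(0.1, 0.2)); bad$alternative <- c("A", "B")
  expect_error(group_decision(list(mk(c(0.1, 0.2)), bad)), "different alternatives")
})

test_that("the full pipeline is permutation-equivariant and handles one alternative", {
  dm <- read_decision_matrix(ext_fixture("dm_balanced.csv"),
                             ext_fixture("dm_directions.json"))
  ops <- lapply(1:3, function(i) load_opinions(ext_fixture(sprintf("expert%d.csv", i))))
  res <- run_fdosm(dm, ops)
  perm <- withr::with_seed(9, sample(nrow(dm$values)))
  dm_p <- decision_matrix(dm$values[perm, ], directions = unname(dm$directions))
  ops_p <- lapply(ops, function(o) opinion_matrix(o$terms[perm, ]))
  res_p <- run_fdosm(dm_p, ops_p)
  expect_equal(res_p$group$score, res$group$score[perm])
  expect_equal(res_p$group$rank, res$group$rank[perm])

  one <- fuzzy_scores(opinion_matrix(matrix("BD", 1, 3)), scale8, "mean")
  expect_equal(one$rank, 1L)
})

test_that("score tables serialize to the wide per-expert layout", {
  dm <- read_decision_matrix(ext_fixture("dm_balanced.csv"),
                             ext_fixture("dm_directions.json"))
  res <- run_fdosm(dm, list(ext_fixture("expert1.csv"), ext_fixture("expert2.csv"),
                            ext_fixture("expert3.csv")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_table(res, path)
  back <- read.csv(path)
  expect_equal(names(back), c("alternative", "score_e1", "rank_e1", "score_e2",
                              "rank_e2", "score_e3", "rank_e3",
                              "final_score", "final_rank"))
  expect_equal(back$final_score[back$alternative == "GBoost"], 0.1333)
})

test_that("the demo term-suggestion helper marks the ideal as ND", {
  dm9 <- read_decision_matrix(ext_fixture("table9_dm.csv"))
  om <- suggest_opinions(dm9)
  expect_true(all(om$terms["DT", ] == "ND"))
  expect_true(all(om$terms %in% c("ND", "SD", "D", "BD", "HD")))
})
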