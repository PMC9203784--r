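make_set <- function(group, ...) {
  group_scores(group, data.frame(...))
}

test_that("identical score sets produce no discrepancies", {
  sc <- data.frame(source = c("A", "B"), target = c("B", "A"), score = c(2L, 1L))
  recs <- find_discrepancies(list(group_scores("G1", sc), group_scores("G2", sc)))
  expect_equal(nrow(recs), 0)
})

test_that("differing scores are listed with their max pairwise difference", {
  a <- make_set("G1", source = "A", target = "B", score = 3L)
  b <- make_set("G2", source = "A", target = "B", score = 1L)
  recs <- find_discrepancies(list(a, b), threshold = 1)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$max_diff, 2)
  expect_equal(recs$n_groups, 2)
  # below threshold the same pair is not a discrepancy
  expect_equal(nrow(find_discrepancies(list(a, b), threshold = 3)), 0)
})

test_that("pairs scored by a single group are never listed", {
  a <- make_set("G1", source = c("A", "A"), target = c("B", "C"), score = c(3L, 2L))
  b <- make_set("G2", source = "A", target = "B", score = 3L)
  recs <- find_discrepancies(list(a, b))
  expect_equal(nrow(recs), 0) # A->C has no second opinion, A->B agrees
})

test_that("discrepancy listing requires two groups and an integer threshold", {
  a <- make_set("G1", source = "A", target = "B", score = 3L)
  expect_error(find_discrepancies(list(a)), class = "cim_error_config")
  b <- make_set("G2", source = "A", target = "B", score = 1L)
  expect_error(find_discrepancies(list(a, b), threshold = 0),
               class = "cim_error_config")
})

test_that("records come out in registry order", {
  sc1 <- data.frame(source = c("C", "A", "B"), target = c("A", "B", "C"),
                    score = c(1L, 1L, 1L))
  sc2 <- data.frame(source = c("C", "A", "B"), target = c("A", "B", "C"),
                    score = c(3L, 3L, 3L))
  recs <- find_discrepancies(list(group_scores("G1", sc1), group_scores("G2", sc2)),
                             goals = c("A", "B", "C"))
  expect_equal(recs$source, c("A", "B", "C"))
})

test_that("median and rounded-mean rules resolve to in-scale integers", {
  a <- make_set("G1", source = c("A", "B"), target = c("B", "A"), score = c(3L, 2L))
  b <- make_set("G2", source = c("A", "B"), target = c("B", "A"), score = c(1L, 2L))
  c3 <- make_set("G3", source = c("A", "B"), target = c("B", "A"), score = c(1L, -1L))

  recs2 <- find_discrepancies(list(a, b))
  res2 <- resolve_consensus(recs2, rule = "median")
  expect_equal(res2$score, 2L) # median of {3, 1} = midpoint 2
  expect_equal(res2$provenance, "consensus")

  recs3 <- find_discrepancies(list(a, b, c3))
  res3 <- resolve_consensus(recs3, rule = "median")
  expect_equal(res3$score[res3$source == "A"], 1L) # median {3,1,1}
  expect_equal(res3$score[res3$source == "B"], 2L) # median {2,2,-1}

  # rounded mean of {3, 1, 1} = 1.67 -> 2; of {2, 2, -1} = 1
  resm <- resolve_consensus(recs3, rule = "rounded-mean")
  expect_equal(resm$score[resm$source == "A"], 2L)
  expect_equal(resm$score[resm$source == "B"], 1L)
})

test_that("non-integral midpoints round half away from zero on both sides", {
  pos <- find_discrepancies(list(
    make_set("G1", source = "A", target = "B", score = 1L),
    make_set("G2", source = "A", target = "B", score = 2L)
  ))
  expect_equal(resolve_consensus(pos, "median")$score, 2L) # 1.5 -> 2
  neg <- find_discrepancies(list(
    make_set("G1", source = "A", target = "B", score = -1L),
    make_set("G2", source = "A", target = "B", score = -2L)
  ))
  expect_equal(resolve_consensus(neg, "median")$score, -2L) # -1.5 -> -2
})

test_that("the manual rule replays plenary decisions and insists on coverage", {
  a <- make_set("G1", source = "A", target = "B", score = 3L)
  b <- make_set("G2", source = "A", target = "B", score = 1L)
  recs <- find_discrepancies(list(a, b))

  expect_error(resolve_consensus(recs, rule = "manual"), class = "cim_error_config")
  expect_error(
    resolve_consensus(recs, rule = "manual",
                      decisions = data.frame(source = "B", target = "A",
                                             final_score = 1L)),
    class = "cim_error_missing_decision"
  )
  res <- resolve_consensus(recs, rule = "manual",
                           decisions = data.frame(source = "A", target = "B",
                                                  final_score = 1L,
                                                  note = "plenary"))
  expect_equal(res$score, 1L)
  expect_equal(res$provenance, "consensus")
  expect_equal(res$note, "plenary")
  expect_error(
    resolve_consensus(recs, rule = "manual",
                      decisions = data.frame(source = "A", target = "B",
                                             final_score = 5L)),
    class = "cim_error_score_range"
  )
})

test_that("merging identical group scorings reproduces the input matrix exactly", {
  truth <- generate_matrix(n_goals = 6, seed = 77)
  base <- as_score_table(truth)
  sets <- lapply(1:3, function(k) group_scores(paste0("G", k), base))
  for (rule in c("median", "rounded-mean")) {
    merged <- merge_group_scores(sets, rule = rule, goals = goal_ids(truth))
    rebuilt <- build_matrix(truth$goals, merged)
    expect_identical(rebuilt$weights, truth$weights)
    expect_true(all(merged$provenance == "agreed"))
  }
})

test_that("consensus over complete union coverage yields a buildable matrix", {
  truth <- generate_matrix(n_goals = 5, seed = 13)
  sets <- generate_group_scores(truth, disagreement_rate = 0.3, n_groups = 3,
                                seed = 14)
  merged <- merge_group_scores(sets, rule = "median", goals = goal_ids(truth))
  rebuilt <- build_matrix(truth$goals, merged)
  expect_s3_class(rebuilt, "cross_impact_matrix")
  expect_equal(nrow(as_score_table(rebuilt)), 20)
  expect_true(all(merged$provenance %in% c("agreed", "consensus")))
})

test_that("a group cannot score the same pair twice", {
  expect_error(
    group_scores("G1", data.frame(source = c("A", "A"), target = c("B", "B"),
                                  score = c(1L, 2L))),
    class = "cim_error_duplicate_pair"
  )
})
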