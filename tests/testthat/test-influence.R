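test_that("degrees, second-order and total influence match hand sums on the toy network", {
  m <- toy_matrix()
  expect_equal(weighted_degree(m, "A", "out"), c(A = 3))
  expect_equal(weighted_degree(m, "C", "in"), c(C = 4))
  expect_equal(second_order_influence(m, "A", "C"), 6) # single path A->B->C
  expect_equal(second_order_influence(m, "A", "A"), 0) # no return links
  expect_equal(unname(total_influence(m, "A")), 9)     # 3 + (2*3 + 1*0)
  expect_equal(unname(total_influence(m, "C")), 0)     # zero out-degree
  expect_error(weighted_degree(m, "Z", "out"), class = "cim_error_unknown_goal")
  expect_error(second_order_influence(m, "A", "Z"), class = "cim_error_unknown_goal")
})

test_that("second-order influence equals brute-force path enumeration on random matrices", {
  for (seed in 1:10) {
    n <- 3 + (seed %% 6) # n in 3..8
    m <- random_small_matrix(n, seed)
    S <- second_order_matrix(m)
    ids <- goal_ids(m)
    for (a in ids) {
      for (d in ids) {
        expect_equal(S[a, d], brute_second_order(m, a, d),
                     info = sprintf("seed %d, %s->%s", seed, a, d))
      }
    }
  }
})

test_that("total influence equals literal formula substitution on random matrices", {
  for (seed in 11:20) {
    m <- random_small_matrix(3 + (seed %% 6), seed)
    tot <- total_influence(m)
    for (g in goal_ids(m)) {
      expect_equal(unname(tot[g]), literal_total(m, g),
                   info = sprintf("seed %d, goal %s", seed, g))
    }
  }
})

test_that("total influence with all neighbour out-degrees zero reduces to first order", {
  # star: only A has outgoing links, so the second-order term vanishes
  ids <- c("A", "B", "C", "D")
  sc <- scores_from_fun(ids, function(i, j) if (i == "A") 2L else 0L)
  m <- build_matrix(ids, sc)
  expect_equal(total_influence(m), weighted_degree(m, direction = "out"))
})

test_that("first order scales by c and second order by c^2", {
  # base scores in {-1, 0, 1} so scaled scores stay on the seven-point scale
  set.seed(4)
  ids <- letters[1:6]
  base <- scores_from_fun(ids, function(i, j) sample(-1:1, 1))
  m1 <- build_matrix(ids, base)
  for (c in 2:3) {
    scaled <- base
    scaled$score <- base$score * c
    mc <- build_matrix(ids, scaled)
    expect_equal(weighted_degree(mc, direction = "out"),
                 c * weighted_degree(m1, direction = "out"))
    expect_equal(second_order_matrix(mc), c^2 * second_order_matrix(m1))
  }
})

test_that("relabeling goals permutes every influence quantity identically", {
  set.seed(8)
  m <- random_small_matrix(6, 21)
  ids <- goal_ids(m)
  perm <- sample(ids)
  sc <- as_score_table(m)
  mp <- build_matrix(perm, sc)
  expect_equal(weighted_degree(mp, direction = "out")[ids],
               weighted_degree(m, direction = "out")[ids])
  expect_equal(total_influence(mp)[ids], total_influence(m)[ids])
  expect_equal(second_order_matrix(mp)[ids, ids], second_order_matrix(m)[ids, ids])
  rp <- influence_report(mp)
  r1 <- influence_report(m)
  expect_equal(rp[match(ids, rp$goal), -1], r1[match(ids, r1$goal), -1],
               ignore_attr = TRUE)
})

test_that("total signed weight equals both the out-degree and in-degree sums", {
  for (seed in 31:35) {
    m <- random_small_matrix(7, seed)
    W <- m$weights
    total <- sum(W[row(W) != col(W)])
    expect_equal(sum(weighted_degree(m, direction = "out")), total)
    expect_equal(sum(weighted_degree(m, direction = "in")), total)
  }
})

test_that("ranks are competition-style, deterministic, and cover 1..n", {
  m <- toy_matrix() # totals: A 9, B 3, C 0
  rk <- rank_goals(m, "total")
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$goal, c("A", "B", "C"))

  z <- constant_matrix(c("A", "B", "C"), 0L)
  rz <- rank_goals(z, "total")
  expect_equal(rz$rank, rep(1L, 3)) # full tie
  expect_equal(rz$goal, c("A", "B", "C")) # registry order within the tie

  m17 <- generate_matrix(n_goals = 17, seed = 5)
  for (ord in c("first", "total")) {
    r <- rank_goals(m17, ord)
    expect_equal(nrow(r), 17)
    expect_true(all(r$rank >= 1 & r$rank <= 17))
  }
  rep17 <- influence_report(m17)
  expect_equal(rep17$total, rep17$first_order + rep17$second_order_total)
  expect_equal(rep17$rank_shift, rep17$rank_first - rep17$rank_total)
})

test_that("excluding the backlink subtracts exactly the feedback loop", {
  for (seed in 41:45) {
    m <- random_small_matrix(6, seed)
    S <- second_order_matrix(m)
    expect_equal(total_influence(m) - total_influence(m, exclude_backlink = TRUE),
                 diag(S)[goal_ids(m)])
  }
})

test_that("focal perspective returns the row, column and path sums of the focal goal", {
  m <- toy_matrix()
  p <- focal_perspective(m, "A")
  expect_equal(p$first_order_out, c(B = 2, C = 1))
  expect_equal(p$first_order_in, c(B = 0, C = 0))
  expect_equal(p$second_order_out[["C"]], 6)
  expect_equal(p$feedback, 0)
  expect_error(focal_perspective(m, "Z"), class = "cim_error_unknown_goal")
})
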