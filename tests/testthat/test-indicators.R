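u5mr_series <- function() {
  indicator_series("3", "under-five mortality", c(2000, 2005, 2010, 2015, 2019),
                   c(106, 65, 44, 32, 27), increase_is_progress = FALSE)
}

forest_series <- function() {
  indicator_series("15", "forest area", c(2000, 2005, 2010, 2015),
                   c(61, 60, 50, 46), increase_is_progress = TRUE)
}

test_that("series construction enforces its invariants", {
  expect_error(indicator_series("1", "x", 2000, 1, TRUE), class = "cim_error_series")
  expect_error(indicator_series("1", "x", c(2000, 2000), c(1, 2), TRUE),
               class = "cim_error_series")
  expect_error(indicator_series("1", "x", c(2005, 2000), c(1, 2), TRUE),
               class = "cim_error_series")
  expect_error(indicator_series("1", "x", c(2000, 2005), c(1, Inf), TRUE),
               class = "cim_error_series")
})

test_that("recoding negates decrease-is-progress series and is idempotent", {
  u5 <- u5mr_series()
  rec <- recode_series(u5)
  expect_equal(rec$values, -c(106, 65, 44, 32, 27))
  expect_true(rec$increase_is_progress)
  expect_identical(recode_series(rec), rec) # negation happens exactly once

  fa <- forest_series()
  expect_identical(recode_series(fa), fa) # already progress-oriented
})

test_that("identical increasing series correlate perfectly", {
  a <- indicator_series("1", "x", 2000:2005, 1:6, TRUE)
  b <- indicator_series("2", "y", 2000:2005, 1:6, TRUE)
  expect_equal(progress_correlation(a, b)$r, 1)
})

test_that("recoded under-five mortality vs forest area matches the textbook formula", {
  res <- progress_correlation(u5mr_series(), forest_series())
  expect_equal(res$n_overlap, 4) # 2019 has no forest observation
  expect_equal(res$years, c(2000, 2005, 2010, 2015))
  oracle <- pearson_oracle(-c(106, 65, 44, 32), c(61, 60, 50, 46))
  expect_equal(res$r, oracle)
  expect_equal(round(res$r, 2), -0.88)
})

test_that("insufficient year overlap is a named error, not a silent NA", {
  a <- indicator_series("1", "x", c(2000, 2005, 2010), 1:3, TRUE)
  b <- indicator_series("2", "y", c(2005, 2010, 2020), 1:3, TRUE)
  err <- expect_error(progress_correlation(a, b, min_overlap = 3),
                      class = "cim_error_insufficient_overlap")
  expect_match(conditionMessage(err), "2 shared years")
  expect_equal(progress_correlation(a, b, min_overlap = 2)$n_overlap, 2)
})

test_that("correlation is symmetric, affine-invariant, and flips under negation", {
  a <- u5mr_series()
  b <- forest_series()
  r_ab <- progress_correlation(a, b)$r
  expect_equal(progress_correlation(b, a)$r, r_ab)

  shifted <- indicator_series("15", "forest area scaled", b$years,
                              3.5 * b$values + 100, TRUE)
  expect_equal(progress_correlation(a, shifted)$r, r_ab)

  # flipping the direction flag of one raw series negates r
  flipped <- indicator_series("15", "forest loss", b$years, b$values,
                              increase_is_progress = FALSE)
  expect_equal(progress_correlation(a, flipped)$r, -r_ab)
})

test_that("constant series are reported as degenerate, never r = 0", {
  a <- indicator_series("1", "x", 2000:2004, rep(5, 5), TRUE)
  b <- indicator_series("2", "y", 2000:2004, 1:5, TRUE)
  res <- progress_correlation(a, b)
  expect_equal(res$status, "degenerate")
  expect_true(is.na(res$r))
})

test_that("the packaged indicator table loads and matches the published series", {
  tab <- cambodia_indicators()
  expect_true(all(c("goal_id", "indicator", "year", "value",
                    "increase_is_progress") %in% names(tab)))
  u5 <- series_from_table(tab, "3", "under-five mortality rate (per 1000 live births)")
  expect_equal(u5$values, c(106, 65, 44, 32, 27))
  expect_false(u5$increase_is_progress)
  # off-grid years are stored at their true year, not the column year
  pov <- series_from_table(tab, "1")
  expect_equal(pov$years, c(2003, 2006, 2010, 2014))
})

test_that("series extraction demands a named indicator when a goal has several", {
  tab <- cambodia_indicators()
  expect_error(series_from_table(tab, "3"), class = "cim_error_series")
  expect_error(series_from_table(tab, "99"), class = "cim_error_series")
})

test_that("pairwise correlation sweeps report every pair with a status", {
  tab <- cambodia_indicators()
  sub <- tab[tab$goal_id %in% c("3", "15", "14"), ]
  res <- correlate_indicators(sub, min_overlap = 3)
  n_series <- nrow(unique(sub[, c("goal_id", "indicator")]))
  expect_equal(nrow(res), choose(n_series, 2))
  expect_true(all(res$status %in% c("ok", "degenerate", "insufficient_overlap")))
  # fisheries (2011/2015/2017) shares < 3 years with forest area
  fish_forest <- res[res$goal_a == "14" & res$goal_b == "15", ]
  expect_equal(fish_forest$status, "insufficient_overlap")
  u5_forest <- res[res$goal_b == "15" &
                     res$indicator_a == "under-five mortality rate (per 1000 live births)", ]
  expect_equal(round(u5_forest$r, 2), -0.88)
})
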