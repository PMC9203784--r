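#' Generate a random cross-impact matrix
#'
#' Seeded generator emulating the composition of a stakeholder-scored SDG
#' cross-impact matrix. Each off-diagonal cell is drawn independently: sign
#' from `(p_positive, p_negative, p_zero)`, magnitude of nonzero scores from
#' `magnitude_probs` over 1..3. Defaults are calibrated to the observed
#' composition of the Cambodia assessment (78% positive, 4% negative, 18%
#' zero); magnitudes default to uniform since only the sign composition is
#' reported. An optional reciprocity knob copies the score of i -> j onto
#' j -> i with the given probability, for sensitivity studies — real
#' stakeholder matrices are plainly not independent across reciprocal pairs.
#'
#' @param n_goals Number of goals (>= 2), default 17.
#' @param p_positive,p_negative,p_zero Sign probabilities; must sum to 1.
#' @param magnitude_probs Probabilities of |score| = 1, 2, 3 for nonzero
#'   cells; must sum to 1. Default uniform.
#' @param reciprocity Probability that cell (j, i) mirrors cell (i, j).
#'   Default 0 (fully independent cells).
#' @param goals Optional goal registry; default ids `"G1".."Gn"`.
#' @param seed Integer seed; same seed, same matrix.
#' @return A complete `cross_impact_matrix`.
#' @examples
#' m <- generate_matrix(n_goals = 17, seed = 42)
#' summarize_matrix(m)
#' @export
generate_matrix <- function(n_goals = 17,
                            p_positive = 0.78, p_negative = 0.04, p_zero = 0.18,
                            magnitude_probs = c(1, 1, 1) / 3,
                            reciprocity = 0,
                            goals = NULL,
                            seed = NULL) {
  p <- c(p_positive, p_negative, p_zero)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    cim_stop("p_positive, p_negative, p_zero must be nonnegative and sum to 1",
             class = "cim_error_config")
  }
  if (length(magnitude_probs) != 3 || any(magnitude_probs < 0) ||
      abs(sum(magnitude_probs) - 1) > 1e-8) {
    cim_stop("magnitude_probs must be 3 nonnegative numbers summing to 1",
             class = "cim_error_config")
  }
  if (reciprocity < 0 || reciprocity > 1) {
    cim_stop("reciprocity must be in [0, 1]", class = "cim_error_config")
  }
  if (is.null(goals)) {
    if (!is_whole(n_goals) || n_goals < 2) {
      cim_stop("n_goals must be an integer >= 2", class = "cim_error_registry")
    }
    goals <- goal_registry(paste0("G", seq_len(n_goals)))
  } else {
    goals <- goal_registry(goals)
    n_goals <- nrow(goals)
  }
  n <- n_goals
  with_seed(seed, {
    ncell <- n * (n - 1)
    sgn <- sample(c(1L, -1L, 0L), ncell, replace = TRUE, prob = p)
    mag <- sample(1:3, ncell, replace = TRUE, prob = magnitude_probs)
    sc <- sgn * mag
    W <- matrix(NA_integer_, n, n, dimnames = list(goals$id, goals$id))
    W[row(W) != col(W)] <- sc
    if (reciprocity > 0) {
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          if (stats::runif(1) < reciprocity) W[j, i] <- W[i, j]
        }
      }
    }
    validate_cim(new_cim(W, goals))
  })
}

#' Simulate multi-group workshop scorings of a known matrix
#'
#' Each group reproduces the truth matrix except that, independently per
#' cell with probability `disagreement_rate`, its score is perturbed: a new
#' score is drawn uniformly from the in-scale values within `max_shift` of
#' the truth, excluding the truth itself. A perturbation therefore always
#' changes the score (no silent clamping back onto the truth at the scale
#' boundaries), so the fraction of pairs on which any group deviates from
#' truth follows the independence law `1 - (1 - rate)^n_groups` exactly.
#'
#' @param truth A complete `cross_impact_matrix`.
#' @param disagreement_rate Per-cell, per-group perturbation probability.
#' @param max_shift Maximum absolute shift of a perturbed score (>= 1).
#' @param n_groups Number of groups, default 2.
#' @param seed Integer seed.
#' @return A list of group score sets (data frames with `group_id`,
#'   `source`, `target`, `score`), group ids `"G1"`, `"G2"`, ...
#' @examples
#' tr <- generate_matrix(n_goals = 5, seed = 1)
#' gs <- generate_group_scores(tr, disagreement_rate = 0.2, seed = 2)
#' find_discrepancies(gs)
#' @export
generate_group_scores <- function(truth, disagreement_rate = 0.1, max_shift = 1,
                                  n_groups = 2, seed = NULL) {
  validate_cim(truth)
  if (disagreement_rate < 0 || disagreement_rate > 1) {
    cim_stop("disagreement_rate must be in [0, 1]", class = "cim_error_config")
  }
  if (!is_whole(max_shift) || max_shift < 1) {
    cim_stop("max_shift must be an integer >= 1", class = "cim_error_config")
  }
  if (!is_whole(n_groups) || n_groups < 1) {
    cim_stop("n_groups must be an integer >= 1", class = "cim_error_config")
  }
  base <- as_score_table(truth)
  with_seed(seed, {
    lapply(seq_len(n_groups), function(k) {
      sc <- base$score
      hit <- stats::runif(length(sc)) < disagreement_rate
      if (any(hit)) {
        sc[hit] <- vapply(sc[hit], function(s) {
          cand <- setdiff(max(-3L, s - max_shift):min(3L, s + max_shift), s)
          if (length(cand) == 1) cand else sample(cand, 1)
        }, integer(1))
      }
      out <- base
      out$score <- sc
      group_scores(paste0("G", k), out)
    })
  })
}

.csdg_ids <- c(as.character(1:16), "18")

#' The Cambodia SDG goal registry
#'
#' The 17 goals of the Cambodia Sustainable Development Goals analysis:
#' CSDG 1-16 plus CSDG 18 (mine/ERW free), with CSDG 3 restricted to child
#' health and CSDG 17 (partnerships) excluded as too broad to score.
#' Shipped as a packaged CSV fixture.
#'
#' @return A goal registry data frame (17 rows: ids "1".."16", "18").
#' @examples
#' cambodia_goals()$id
#' @export
cambodia_goals <- function() {
  path <- system.file("extdata", "cambodia_goals.csv", package = "crossimpact",
                      mustWork = TRUE)
  goal_registry(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

#' Child-health row and column of the Cambodia cross-impact matrix
#'
#' The directed scores between child health (CSDG 3) and the 16 other
#' CSDGs, as assessed by the stakeholder group: the row (how progress on
#' child health influences each goal — strongly promoting CSDG 1, 4 and 8,
#' moderately 10 and 12, weakly 9, 11 and 16, no direct influence on the
#' rest) and the column (how each goal influences child health — strongly
#' CSDG 6 and 11, moderately 2, 4, 5, 7, 8, 9, 10, 12 and 16, weakly 1,
#' 13, 14, 15 and 18). There are no restricting interactions in either
#' direction. The hand sums are 16 (row), 29 (column), and the implied
#' feedback-loop strength through reciprocal pairs is 30.
#'
#' @return A list with named integer vectors `row` and `column` (16 entries
#'   each, names = CSDG ids) and the focal id `goal` (`"3"`).
#' @examples
#' fx <- cambodia_child_health_fixture()
#' sum(fx$row)    # 16
#' sum(fx$column) # 29
#' @export
cambodia_child_health_fixture <- function() {
  others <- setdiff(.csdg_ids, "3")
  row <- stats::setNames(integer(16), others)
  row[c("1", "4", "8")] <- 3L
  row[c("10", "12")] <- 2L
  row[c("9", "11", "16")] <- 1L
  column <- stats::setNames(integer(16), others)
  column[c("6", "11")] <- 3L
  column[c("2", "4", "5", "7", "8", "9", "10", "12", "16")] <- 2L
  column[c("1", "13", "14", "15", "18")] <- 1L
  list(goal = "3", row = row, column = column)
}

#' Embed the child-health fixture into a matrix
#'
#' Overwrites the focal goal's row and column of `M` with the fixture
#' scores. The focal goal's own influence numbers (out-degree, in-degree,
#' feedback loop) depend only on this row and column, so they are fixed
#' regardless of how the rest of the matrix is filled in.
#'
#' @param M A complete `cross_impact_matrix` on the Cambodia registry (or
#'   any registry containing the fixture's goal ids).
#' @param fixture A fixture as returned by
#'   [cambodia_child_health_fixture()].
#' @return The modified `cross_impact_matrix`.
#' @examples
#' m <- generate_matrix(goals = cambodia_goals(), seed = 9)
#' m <- embed_fixture(m)
#' weighted_degree(m, "3", "out") # 16
#' @export
embed_fixture <- function(M, fixture = cambodia_child_health_fixture()) {
  validate_cim(M)
  g <- assert_goal(M, fixture$goal)
  assert_goal(M, names(fixture$row))
  assert_goal(M, names(fixture$column))
  W <- M$weights
  W[g, names(fixture$row)] <- fixture$row
  W[names(fixture$column), g] <- fixture$column
  validate_cim(new_cim(W, M$goals))
}

#' Cambodia SDG indicator table
#'
#' A reconstruction of the published overview of key Cambodian sustainable
#' development indicators (2000-2019): one row per goal, indicator and
#' observation year, with the direction-of-progress flag used by
#' [recode_series()]. Observations reported off the five-year grid (e.g. a
#' poverty estimate for 2003) are stored at their true year. Where the
#' printed table is ambiguous about column alignment the reconstruction
#' places values at the most plausible years; the series used in worked
#' examples (under-five mortality, forest area) are unambiguous.
#'
#' @return A data frame with columns `goal_id`, `indicator`, `year`,
#'   `value`, `increase_is_progress`.
#' @examples
#' head(cambodia_indicators())
#' @export
cambodia_indicators <- function() {
  path <- system.file("extdata", "cambodia_indicators.csv",
                      package = "crossimpact", mustWork = TRUE)
  read_indicator_csv(path)
}

#' Generate a synthetic indicator series
#'
#' Linear-trend-plus-noise series for exercising the correlation layer:
#' `value(year) = intercept + slope * (year - first year) + N(0, noise_sd)`.
#'
#' @param goal_id,indicator Labels for the series.
#' @param years Observation years (>= 3, strictly increasing).
#' @param slope Linear trend per year.
#' @param intercept Value at the first year.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param increase_is_progress Direction flag of the generated indicator.
#' @param seed Integer seed.
#' @return An [indicator_series()].
#' @export
generate_indicator_series <- function(goal_id, indicator,
                                      years = seq(2000, 2019, by = 5),
                                      slope = 1, intercept = 0, noise_sd = 0.5,
                                      increase_is_progress = TRUE, seed = NULL) {
  if (length(years) < 3) {
    cim_stop("need at least 3 years", class = "cim_error_config")
  }
  if (noise_sd < 0) {
    cim_stop("noise_sd must be >= 0", class = "cim_error_config")
  }
  with_seed(seed, {
    vals <- intercept + slope * (years - years[1]) +
      stats::rnorm(length(years), 0, noise_sd)
    indicator_series(goal_id, indicator, years, vals, increase_is_progress)
  })
}
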