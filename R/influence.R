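#' Weighted in- and out-degree of a goal
#'
#' The out-degree of goal g is its row sum, `D_g^Out = sum_{j != g} w_gj`:
#' the net first-order influence of the goal on the network. The in-degree
#' is the column sum: how much the goal is directly influenced by all other
#' goals. The structural diagonal is skipped.
#'
#' @param M A complete `cross_impact_matrix`.
#' @param goal Goal id, or `NULL` for all goals.
#' @param direction `"out"` (row sum) or `"in"` (column sum).
#' @return A named numeric vector (length 1 if `goal` given).
#' @examples
#' m <- generate_matrix(n_goals = 5, seed = 1)
#' weighted_degree(m, direction = "out")
#' @export
weighted_degree <- function(M, goal = NULL, direction = c("out", "in")) {
  validate_cim(M)
  direction <- match.arg(direction)
  W <- weights0(M)
  d <- if (direction == "out") rowSums(W) else colSums(W)
  if (!is.null(goal)) d <- d[assert_goal(M, goal)]
  d
}

#' Second-order influence between two goals
#'
#' The aggregated second-order influence of goal A on goal D is the sum of
#' products of weights along every directed length-2 path A -> i -> D,
#' `sum_i w_Ai * w_iD`, with the intermediate i running over the goals
#' connecting A and D (i is never A or D itself; self-links do not exist).
#' With A = D this is the feedback-loop strength of the goal: a positive
#' value means progress on the goal indirectly reinforces itself through
#' its interactions with the rest of the network.
#'
#' @param M A complete `cross_impact_matrix`.
#' @param from,to Goal ids (may be equal: feedback loop).
#' @return A single number; exact integer arithmetic on integer scores.
#' @seealso [second_order_matrix()] for all ordered pairs at once.
#' @export
second_order_influence <- function(M, from, to) {
  S <- second_order_matrix(M)
  S[assert_goal(M, from), assert_goal(M, to)]
}

#' All pairwise second-order influences
#'
#' Computes `I2[A, D] = sum_i w_Ai * w_iD` for every ordered pair including
#' A = D (the diagonal holds feedback-loop strengths). Because the stored
#' diagonal of the weight matrix is structurally absent, the matrix square
#' of the zero-diagonal weights realises exactly the path sum with
#' i excluded from {A, D}. Entries are bilinear in the weights: scaling all
#' scores by c scales every entry by c^2.
#'
#' @param M A complete `cross_impact_matrix`.
#' @return A numeric matrix with goal ids as dimnames.
#' @export
second_order_matrix <- function(M) {
  validate_cim(M)
  W <- weights0(M)
  W %*% W
}

#' Total (net) influence of a goal on the network
#'
#' Total influence adds to the first-order term (the out-degree) the
#' influence transmitted through each neighbour's own outgoing links:
#' \deqn{I_g^{Total} = I_g^{1st} + \sum I^{2nd}
#'   = D_g^{Out} + \sum_{j \ne g} w_{gj} D_j^{Out}}{
#'   I_total(g) = D_out(g) + sum_{j != g} w_gj * D_out(j)}
#' implemented exactly as written: the neighbour out-degree `D_j^Out`
#' includes the backlink `w_jg` unless `exclude_backlink = TRUE`.
#'
#' @param M A complete `cross_impact_matrix`.
#' @param goal Goal id, or `NULL` for all goals.
#' @param exclude_backlink Drop the `w_gj * w_jg` backlink terms (i.e.
#'   subtract the feedback loop) from the second-order sum. Default `FALSE`
#'   (the literal formula).
#' @return A named numeric vector.
#' @examples
#' m <- generate_matrix(n_goals = 5, seed = 1)
#' total_influence(m)
#' @export
total_influence <- function(M, goal = NULL, exclude_backlink = FALSE) {
  validate_cim(M)
  W <- weights0(M)
  dout <- rowSums(W)
  tot <- dout + drop(W %*% dout)
  if (exclude_backlink) tot <- tot - diag(W %*% W)
  names(tot) <- M$goals$id
  if (!is.null(goal)) tot <- tot[assert_goal(M, goal)]
  tot
}

# Competition ("1224") ranking of a descending-ordered criterion:
# rank = 1 + number of goals with strictly larger influence.
competition_rank <- function(x) {
  vapply(x, function(v) 1L + sum(x > v), integer(1))
}

#' Per-goal influence report
#'
#' One row per goal: weighted out- and in-degree, first-order influence
#' (= out-degree), aggregate second-order influence, total influence, and
#' competition ranks under first-order and total accounting together with
#' the rank shift (`rank_first - rank_total`; positive means the goal rises
#' once indirect effects are counted).
#'
#' @inheritParams total_influence
#' @return A data frame in registry order with columns `goal`, `out_degree`,
#'   `in_degree`, `first_order`, `second_order_total`, `total`,
#'   `rank_first`, `rank_total`, `rank_shift`.
#' @examples
#' m <- generate_matrix(n_goals = 6, seed = 7)
#' influence_report(m)
#' @export
influence_report <- function(M, exclude_backlink = FALSE) {
  validate_cim(M)
  W <- weights0(M)
  ids <- M$goals$id
  dout <- rowSums(W)
  din <- colSums(W)
  tot <- total_influence(M, exclude_backlink = exclude_backlink)
  rf <- competition_rank(dout)
  rt <- competition_rank(tot)
  data.frame(
    goal = ids,
    out_degree = unname(dout),
    in_degree = unname(din),
    first_order = unname(dout),
    second_order_total = unname(tot - dout),
    total = unname(tot),
    rank_first = rf,
    rank_total = rt,
    rank_shift = rf - rt,
    stringsAsFactors = FALSE
  )
}

#' Rank goals by network influence
#'
#' Goals sorted by descending influence under the chosen accounting. Ties
#' receive equal (competition) rank; within a tie group goals keep registry
#' order, so the listing is deterministic.
#'
#' @inheritParams total_influence
#' @param order `"total"` (first- plus second-order, the default) or
#'   `"first"` (out-degree only).
#' @return A data frame sorted by rank with columns `rank`, `goal`,
#'   `influence`, `rank_other` (the rank under the other accounting) and
#'   `rank_shift` (`rank_first - rank_total`).
#' @examples
#' m <- generate_matrix(n_goals = 6, seed = 7)
#' rank_goals(m, order = "total")
#' @export
rank_goals <- function(M, order = c("total", "first"), exclude_backlink = FALSE) {
  order <- match.arg(order)
  rep <- influence_report(M, exclude_backlink = exclude_backlink)
  if (order == "total") {
    out <- data.frame(
      rank = rep$rank_total, goal = rep$goal, influence = rep$total,
      rank_other = rep$rank_first, rank_shift = rep$rank_shift,
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      rank = rep$rank_first, goal = rep$goal, influence = rep$first_order,
      rank_other = rep$rank_total, rank_shift = rep$rank_shift,
      stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$rank, seq_len(nrow(out))), ]
  rownames(out) <- NULL
  out
}

#' Focal-goal perspective
#'
#' The network seen from one goal: its first-order outgoing influences (its
#' row), first-order incoming influences (its column), second-order
#' outgoing and incoming influences against every other goal, and its
#' feedback-loop strength (second-order influence on itself).
#'
#' @param M A complete `cross_impact_matrix`.
#' @param goal The focal goal id.
#' @return An object of class `focal_perspective`: a list with the focal
#'   `goal`, named vectors `first_order_out`, `first_order_in`,
#'   `second_order_out`, `second_order_in` over all other goals, and the
#'   scalar `feedback`.
#' @examples
#' m <- generate_matrix(n_goals = 6, seed = 7)
#' focal_perspective(m, goal_ids(m)[1])
#' @export
focal_perspective <- function(M, goal) {
  validate_cim(M)
  g <- assert_goal(M, goal)
  W <- weights0(M)
  S <- W %*% W
  others <- setdiff(M$goals$id, g)
  structure(
    list(
      goal = g,
      first_order_out = W[g, others],
      first_order_in = W[others, g],
      second_order_out = S[g, others],
      second_order_in = S[others, g],
      feedback = unname(S[g, g])
    ),
    class = "focal_perspective"
  )
}

#' @export
print.focal_perspective <- function(x, ...) {
  cat(sprintf("Perspective of goal %s\n", sQuote(x$goal)))
  cat(sprintf("  first-order out-influence : %g\n", sum(x$first_order_out)))
  cat(sprintf("  first-order in-influence  : %g\n", sum(x$first_order_in)))
  cat(sprintf("  feedback-loop strength    : %g\n", x$feedback))
  tab <- rbind(
    `1st out` = x$first_order_out,
    `1st in` = x$first_order_in,
    `2nd out` = x$second_order_out,
    `2nd in` = x$second_order_in
  )
  print(tab, ...)
  invisible(x)
}
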