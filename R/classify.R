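#' Summarise the composition of a cross-impact matrix
#'
#' Counts of promoting (positive), restricting (negative) and
#' no-direct-influence (zero) interactions over all `n * (n - 1)` ordered
#' pairs, with integer percentages rounded half away from zero. Percentages
#' are reported as computed — the three can sum to 99, 100 or 101 after
#' rounding and are deliberately not adjusted.
#'
#' @param M A complete `cross_impact_matrix`.
#' @return An object of class `cim_summary`: a list with `n_goals`,
#'   `n_interactions`, `count_positive`, `count_negative`, `count_zero`,
#'   `pct_positive`, `pct_negative`, `pct_zero`.
#' @examples
#' m <- generate_matrix(n_goals = 17, seed = 1)
#' summarize_matrix(m)
#' @export
summarize_matrix <- function(M) {
  validate_cim(M)
  W <- M$weights
  off <- W[row(W) != col(W)]
  n <- nrow(W)
  counts <- c(positive = sum(off > 0), negative = sum(off < 0), zero = sum(off == 0))
  pct <- as.integer(round_half_away(100 * counts / length(off)))
  structure(
    list(
      n_goals = n,
      n_interactions = length(off),
      count_positive = unname(counts["positive"]),
      count_negative = unname(counts["negative"]),
      count_zero = unname(counts["zero"]),
      pct_positive = pct[1],
      pct_negative = pct[2],
      pct_zero = pct[3]
    ),
    class = "cim_summary"
  )
}

#' @export
print.cim_summary <- function(x, ...) {
  cat(sprintf("%d goals, %d ordered interactions\n", x$n_goals, x$n_interactions))
  cat(sprintf("  positive: %d (%d%%)\n", x$count_positive, x$pct_positive))
  cat(sprintf("  negative: %d (%d%%)\n", x$count_negative, x$pct_negative))
  cat(sprintf("  zero    : %d (%d%%)\n", x$count_zero, x$pct_zero))
  invisible(x)
}

#' @export
format.cim_summary <- function(x, ...) {
  paste(
    c("n_goals", "n_interactions", "count_positive", "count_negative",
      "count_zero", "pct_positive", "pct_negative", "pct_zero"),
    unlist(x[c("n_goals", "n_interactions", "count_positive", "count_negative",
               "count_zero", "pct_positive", "pct_negative", "pct_zero")]),
    sep = "=", collapse = "\t"
  )
}

#' Strength-stratified interaction tally
#'
#' Debug-level view of the matrix composition: how many interactions fall
#' on each of the seven scale levels.
#'
#' @param M A complete `cross_impact_matrix`.
#' @return A data frame with columns `score`, `label`, `count`.
#' @export
strength_table <- function(M) {
  validate_cim(M)
  W <- M$weights
  off <- W[row(W) != col(W)]
  data.frame(
    score = -3:3,
    label = score_to_label(-3:3),
    count = vapply(-3:3, function(s) sum(off == s), integer(1)),
    stringsAsFactors = FALSE
  )
}
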