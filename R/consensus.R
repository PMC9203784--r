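#' Assemble a group score set
#'
#' Workshop scoring happens in small groups, each scoring a (possibly
#' partial) set of directed goal pairs. A group score set is the long table
#' of one group's scores tagged with the group id.
#'
#' @param group_id Group label.
#' @param scores Data frame with `source`, `target`, `score` columns.
#' @return Data frame with columns `group_id`, `source`, `target`, `score`
#'   (plus `motivation` if present), validated for duplicate pairs,
#'   self-pairs and score range.
#' @export
group_scores <- function(group_id, scores) {
  stopifnot(is.data.frame(scores), all(c("source", "target", "score") %in% names(scores)))
  src <- as.character(scores$source)
  tgt <- as.character(scores$target)
  if (any(src == tgt)) {
    cim_stop("self-interaction not allowed in group scores", class = "cim_error_self_pair")
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    cim_stop(sprintf("group %s scores the same pair more than once", sQuote(group_id)),
             class = "cim_error_duplicate_pair")
  }
  assert_in_scale(scores$score)
  out <- data.frame(
    group_id = as.character(group_id), source = src, target = tgt,
    score = as.integer(scores$score), stringsAsFactors = FALSE
  )
  if ("motivation" %in% names(scores)) out$motivation <- as.character(scores$motivation)
  out
}

# Normalise input: list of group score sets or one long table -> long table.
bind_group_scores <- function(sets) {
  if (is.data.frame(sets)) {
    stopifnot(all(c("group_id", "source", "target", "score") %in% names(sets)))
    long <- sets
  } else {
    stopifnot(is.list(sets), length(sets) >= 1)
    long <- do.call(rbind, lapply(sets, function(s) {
      s[, c("group_id", "source", "target", "score")]
    }))
  }
  long$group_id <- as.character(long$group_id)
  long$source <- as.character(long$source)
  long$target <- as.character(long$target)
  long
}

#' Find scoring discrepancies between groups
#'
#' After double-scoring — groups re-checking their own scores and verifying
#' a set of pairs scored by another group — any ordered pair scored by two
#' or more groups whose scores differ by at least `threshold` is listed for
#' plenary discussion. Pairs scored by a single group are never listed
#' (there is nothing to compare).
#'
#' @param sets A list of group score sets ([group_scores()]) or a single
#'   long data frame with a `group_id` column. At least two distinct groups.
#' @param threshold Minimum max pairwise absolute score difference for a
#'   pair to count as discrepant. Default 1: any difference is discussed.
#' @param goals Optional goal registry (or id vector) fixing the ordering
#'   of the output; defaults to order of first appearance.
#' @return A data frame with one row per discrepant ordered pair, columns
#'   `source`, `target`, `max_diff`, `n_groups`, `scores` (comma-joined
#'   `group=score`), ordered by source then target in registry order.
#' @examples
#' a <- group_scores("G1", data.frame(source = "A", target = "B", score = 3))
#' b <- group_scores("G2", data.frame(source = "A", target = "B", score = 1))
#' find_discrepancies(list(a, b))
#' @export
find_discrepancies <- function(sets, threshold = 1, goals = NULL) {
  if (!is_whole(threshold) || threshold < 1) {
    cim_stop("threshold must be an integer >= 1", class = "cim_error_config")
  }
  long <- bind_group_scores(sets)
  if (length(unique(long$group_id)) < 2) {
    cim_stop("need score sets from at least 2 groups", class = "cim_error_config")
  }
  ids <- if (is.null(goals)) unique(c(long$source, long$target)) else goal_registry(goals)$id
  key <- paste(long$source, long$target, sep = "\r")
  recs <- lapply(split(seq_len(nrow(long)), key), function(i) {
    sc <- long$score[i]
    if (length(i) < 2) return(NULL)
    md <- max(sc) - min(sc)
    if (md < threshold) return(NULL)
    data.frame(
      source = long$source[i[1]], target = long$target[i[1]],
      max_diff = md, n_groups = length(i),
      scores = paste(long$group_id[i], sc, sep = "=", collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) {
    recs <- data.frame(source = character(), target = character(),
                       max_diff = integer(), n_groups = integer(),
                       scores = character(), stringsAsFactors = FALSE)
  }
  ord <- order(match(recs$source, ids), match(recs$target, ids))
  recs <- recs[ord, ]
  rownames(recs) <- NULL
  recs
}

# Parse the "G1=3,G2=1" scores field of a discrepancy record.
parse_record_scores <- function(scores) {
  parts <- strsplit(scores, ",", fixed = TRUE)[[1]]
  as.integer(sub("^[^=]*=", "", parts))
}

#' Resolve discrepant scores into consensus
#'
#' In the workshop protocol, discrepancies are settled in plenary session;
#' the `manual` rule replays such decisions from an explicit table. The
#' `median` and `rounded-mean` rules are deterministic stand-ins for
#' simulation studies. Either way every discrepant pair receives exactly
#' one in-scale integer score tagged with provenance `"consensus"`.
#'
#' @param records Discrepancy records from [find_discrepancies()].
#' @param rule `"median"`, `"rounded-mean"` or `"manual"`. Non-integral
#'   medians/means are rounded half away from zero (stays in scale).
#' @param decisions For `rule = "manual"`: a data frame with `source`,
#'   `target`, `final_score` (and optionally `note`) covering every record.
#' @return Data frame with `source`, `target`, `score`, `provenance`
#'   (`"consensus"`), and `note` for manual decisions.
#' @examples
#' a <- group_scores("G1", data.frame(source = "A", target = "B", score = 3))
#' b <- group_scores("G2", data.frame(source = "A", target = "B", score = 1))
#' resolve_consensus(find_discrepancies(list(a, b)), rule = "median")
#' @export
resolve_consensus <- function(records, rule = c("median", "rounded-mean", "manual"),
                              decisions = NULL) {
  rule <- match.arg(rule)
  if (nrow(records) == 0) {
    return(data.frame(source = character(), target = character(),
                      score = integer(), provenance = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  if (rule == "manual") {
    if (is.null(decisions)) {
      cim_stop("manual rule requires a decisions table", class = "cim_error_config")
    }
    stopifnot(all(c("source", "target", "final_score") %in% names(decisions)))
    dk <- paste(decisions$source, decisions$target, sep = "\r")
    rk <- paste(records$source, records$target, sep = "\r")
    hit <- match(rk, dk)
    if (anyNA(hit)) {
      miss <- paste(records$source[is.na(hit)], "->", records$target[is.na(hit)])
      cim_stop(sprintf("manual rule: no decision for pair%s %s",
                       if (length(miss) > 1) "s" else "", paste(miss, collapse = ", ")),
               class = "cim_error_missing_decision", pairs = miss)
    }
    final <- decisions$final_score[hit]
    assert_in_scale(final, what = "resolved score")
    note <- if ("note" %in% names(decisions)) as.character(decisions$note[hit]) else NA_character_
  } else {
    final <- vapply(records$scores, function(s) {
      sc <- parse_record_scores(s)
      v <- if (rule == "median") stats::median(sc) else mean(sc)
      as.integer(round_half_away(v))
    }, integer(1), USE.NAMES = FALSE)
    assert_in_scale(final, what = "resolved score")
    note <- NA_character_
  }
  data.frame(
    source = records$source, target = records$target,
    score = as.integer(final), provenance = "consensus",
    note = note, stringsAsFactors = FALSE
  )
}

#' Merge group scorings into a single consensus score table
#'
#' Convenience wrapper over [find_discrepancies()] and [resolve_consensus()]:
#' pairs on which all scoring groups agree pass through unchanged (provenance
#' `"agreed"`); discrepant pairs get the resolution rule. The result builds a
#' complete matrix whenever the union of group coverages is complete.
#'
#' @inheritParams find_discrepancies
#' @inheritParams resolve_consensus
#' @return Data frame with `source`, `target`, `score`, `provenance`, ready
#'   for [build_matrix()].
#' @export
merge_group_scores <- function(sets, rule = c("median", "rounded-mean", "manual"),
                               threshold = 1, decisions = NULL, goals = NULL) {
  rule <- match.arg(rule)
  long <- bind_group_scores(sets)
  if (length(unique(long$group_id)) < 2) {
    cim_stop("need score sets from at least 2 groups", class = "cim_error_config")
  }
  ids <- if (is.null(goals)) unique(c(long$source, long$target)) else goal_registry(goals)$id
  recs <- find_discrepancies(long, threshold = threshold, goals = ids)
  resolved <- resolve_consensus(recs, rule = rule, decisions = decisions)
  rk <- paste(recs$source, recs$target, sep = "\r")

  key <- paste(long$source, long$target, sep = "\r")
  first <- !duplicated(key)
  agreed <- data.frame(
    source = long$source[first], target = long$target[first],
    score = long$score[first], provenance = "agreed",
    stringsAsFactors = FALSE
  )
  ak <- paste(agreed$source, agreed$target, sep = "\r")
  agreed <- agreed[!(ak %in% rk), ]
  out <- rbind(agreed, resolved[, c("source", "target", "score", "provenance")])
  out <- out[order(match(out$source, ids), match(out$target, ids)), ]
  rownames(out) <- NULL
  out
}
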