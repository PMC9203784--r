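#' Validate a goal registry
#'
#' A goal registry lists the goals (nodes) of the system: a short unique id,
#' a name, and an optional longer definition. Ids are open-ended — any set
#' of at least two distinct labels defines a valid system.
#'
#' @param goals A data frame with columns `id` and `name` (optionally
#'   `definition`), or a character vector of ids.
#' @return A validated data frame with columns `id`, `name`, `definition`.
#' @examples
#' goal_registry(c("A", "B", "C"))
#' @export
goal_registry <- function(goals) {
  if (is.character(goals)) {
    goals <- data.frame(id = goals, name = goals, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(goals) || !all(c("id") %in% names(goals))) {
    cim_stop("goal registry must be a data frame with an `id` column or a character vector",
             class = "cim_error_registry")
  }
  goals$id <- as.character(goals$id)
  if (!"name" %in% names(goals)) goals$name <- goals$id
  if (!"definition" %in% names(goals)) goals$definition <- ""
  if (anyDuplicated(goals$id)) {
    cim_stop(
      sprintf("duplicate goal ids: %s",
              paste(unique(goals$id[duplicated(goals$id)]), collapse = ", ")),
      class = "cim_error_registry"
    )
  }
  if (nrow(goals) < 2) {
    cim_stop("a goal registry needs at least 2 goals", class = "cim_error_registry")
  }
  rownames(goals) <- NULL
  goals[, c("id", "name", "definition")]
}

#' Number of ordered interactions among n goals
#'
#' Every ordered pair of distinct goals is one directed interaction, so a
#' complete cross-impact matrix on `n` goals holds `n * (n - 1)` scores
#' (17 goals give 272).
#'
#' @param n_goals Number of goals, an integer >= 2.
#' @return `n_goals * (n_goals - 1)` as an integer-valued number.
#' @examples
#' interaction_count(17) # 272
#' @export
interaction_count <- function(n_goals) {
  if (!all(is_whole(n_goals)) || any(n_goals < 2)) {
    cim_stop("n_goals must be an integer >= 2", class = "cim_error_registry")
  }
  n_goals * (n_goals - 1)
}

#' Create one directed interaction score
#'
#' Convenience row constructor for the score table consumed by
#' [build_matrix()]: a directed pair of goals, the seven-point score and
#' optional motivation and provenance (e.g. the scoring group or
#' `"consensus"`).
#'
#' @param source,target Goal ids; must differ.
#' @param score Integer in -3..+3.
#' @param motivation Optional free-text justification for the score.
#' @param provenance Optional tag for where the score came from.
#' @return A one-row data frame.
#' @export
interaction_score <- function(source, target, score,
                              motivation = NA_character_,
                              provenance = NA_character_) {
  source <- as.character(source)
  target <- as.character(target)
  if (source == target) {
    cim_stop(sprintf("self-interaction not allowed (goal %s)", sQuote(source)),
             class = "cim_error_self_pair", goal = source)
  }
  assert_in_scale(score)
  data.frame(
    source = source, target = target, score = as.integer(score),
    motivation = as.character(motivation), provenance = as.character(provenance),
    stringsAsFactors = FALSE
  )
}

new_cim <- function(weights, goals) {
  structure(list(weights = weights, goals = goals), class = "cross_impact_matrix")
}

#' Build a validated cross-impact matrix from scored interactions
#'
#' Assembles the square score table whose cell (i, j) records how progress
#' on goal i influences progress on goal j. Self-interactions are
#' structurally absent (the diagonal is undefined, stored as `NA`, never
#' zero). The build fails loudly on duplicate pairs, self pairs, unknown
#' goals, out-of-scale scores and — unless `allow_incomplete` — missing
#' pairs, which are reported by id.
#'
#' @param goals A goal registry ([goal_registry()]) or character vector of ids.
#' @param scores A data frame with columns `source`, `target`, `score`
#'   (e.g. rows from [interaction_score()]). Row order is irrelevant.
#' @param allow_incomplete Keep unscored cells as missing instead of
#'   erroring. Default `FALSE`: analysis expects a complete matrix.
#' @return A `cross_impact_matrix`: a list with an integer `weights` matrix
#'   (diagonal `NA`) and the `goals` registry.
#' @examples
#' sc <- expand.grid(source = c("A", "B", "C"), target = c("A", "B", "C"),
#'                   stringsAsFactors = FALSE)
#' sc <- sc[sc$source != sc$target, ]
#' sc$score <- 1L
#' m <- build_matrix(c("A", "B", "C"), sc)
#' @export
build_matrix <- function(goals, scores, allow_incomplete = FALSE) {
  goals <- goal_registry(goals)
  ids <- goals$id
  stopifnot(is.data.frame(scores), all(c("source", "target", "score") %in% names(scores)))
  src <- as.character(scores$source)
  tgt <- as.character(scores$target)

  unknown <- setdiff(unique(c(src, tgt)), ids)
  if (length(unknown) > 0) {
    cim_stop(sprintf("scores reference unregistered goal ids: %s",
                     paste(unknown, collapse = ", ")),
             class = "cim_error_unknown_goal", goals = unknown)
  }
  if (any(src == tgt)) {
    bad <- unique(src[src == tgt])
    cim_stop(sprintf("self-interaction not allowed (goal %s)",
                     paste(sQuote(bad), collapse = ", ")),
             class = "cim_error_self_pair", goals = bad)
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    dup <- sub("\r", " -> ", dup)
    cim_stop(sprintf("duplicate interaction pair%s: %s",
                     if (length(dup) > 1) "s" else "", paste(dup, collapse = ", ")),
             class = "cim_error_duplicate_pair", pairs = dup)
  }
  assert_in_scale(scores$score)

  n <- length(ids)
  W <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  W[cbind(match(src, ids), match(tgt, ids))] <- as.integer(scores$score)

  if (!allow_incomplete) {
    miss <- which(is.na(W) & row(W) != col(W), arr.ind = TRUE)
    if (nrow(miss) > 0) {
      pairs <- paste(ids[miss[, 1]], "->", ids[miss[, 2]])
      cim_stop(sprintf("incomplete matrix: %d missing ordered pair%s: %s",
                       length(pairs), if (length(pairs) > 1) "s" else "",
                       paste(pairs, collapse = ", ")),
               class = "cim_error_missing_pair", pairs = pairs)
    }
  }
  new_cim(W, goals)
}

#' Test or assert the cross-impact matrix class
#'
#' @param x An object.
#' @return `is_cim()` returns a logical; `validate_cim()` returns `x`
#'   invisibly or throws a classed validation error.
#' @export
is_cim <- function(x) inherits(x, "cross_impact_matrix")

#' @rdname is_cim
#' @param complete Require every off-diagonal cell to be scored.
#' @export
validate_cim <- function(x, complete = TRUE) {
  if (!is_cim(x)) cim_stop("not a cross_impact_matrix", class = "cim_error_type")
  W <- x$weights
  ids <- x$goals$id
  stopifnot(is.matrix(W), nrow(W) == ncol(W), identical(rownames(W), ids),
            identical(colnames(W), ids))
  if (any(!is.na(diag(W)))) {
    cim_stop("self-interaction not allowed: diagonal must be empty",
             class = "cim_error_diagonal")
  }
  off <- W[row(W) != col(W)]
  if (complete && anyNA(off)) {
    cim_stop("incomplete matrix: unscored off-diagonal cells present",
             class = "cim_error_missing_pair")
  }
  assert_in_scale(off[!is.na(off)])
  invisible(x)
}

#' @export
print.cross_impact_matrix <- function(x, ...) {
  n <- nrow(x$weights)
  off <- x$weights[row(x$weights) != col(x$weights)]
  cat(sprintf("Cross-impact matrix: %d goals, %d ordered interactions (%d scored)\n",
              n, n * (n - 1), sum(!is.na(off))))
  cat("Goals:", paste(x$goals$id, collapse = ", "), "\n")
  if (!anyNA(off)) {
    cat(sprintf("Composition: %d positive, %d negative, %d zero\n",
                sum(off > 0), sum(off < 0), sum(off == 0)))
  }
  invisible(x)
}

#' Goal ids of a matrix
#' @param M A `cross_impact_matrix`.
#' @return Character vector of goal ids in registry order.
#' @export
goal_ids <- function(M) {
  validate_cim(M, complete = FALSE)
  M$goals$id
}

#' Interactions of a matrix as a long score table
#'
#' The inverse of [build_matrix()]: one row per scored ordered pair, in
#' registry (row-major) order.
#'
#' @param M A `cross_impact_matrix`.
#' @return Data frame with columns `source`, `target`, `score`.
#' @export
as_score_table <- function(M) {
  validate_cim(M, complete = FALSE)
  W <- M$weights
  ids <- M$goals$id
  idx <- which(row(W) != col(W) & !is.na(W), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    source = ids[idx[, 1]], target = ids[idx[, 2]],
    score = W[idx], stringsAsFactors = FALSE
  )
}

# Weight matrix with structural diagonal replaced by 0 for sums/products.
# Any aggregate built on this explicitly skips i = j.
weights0 <- function(M) {
  W <- M$weights
  diag(W) <- 0L
  storage.mode(W) <- "double"
  W
}

assert_goal <- function(M, g) {
  g <- as.character(g)
  bad <- setdiff(g, M$goals$id)
  if (length(bad) > 0) {
    cim_stop(sprintf("unknown goal id%s: %s", if (length(bad) > 1) "s" else "",
                     paste(sQuote(bad), collapse = ", ")),
             class = "cim_error_unknown_goal", goals = bad)
  }
  g
}
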