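#' Read a cross-impact matrix from CSV
#'
#' Canonical dialect: first row `goal,<id>,...,<id>`; each following row a
#' goal id then n cells; diagonal cells empty or `NA`; integer scores;
#' UTF-8, comma-separated. A semicolon-delimited file is accepted with a
#' warning. Malformed headers, non-integer or out-of-range cells and filled
#' diagonals each raise a distinct classed error naming the offending
#' row/column.
#'
#' @param path CSV file path.
#' @param goals Optional registry supplying names/definitions for the ids
#'   in the file; defaults to a bare registry of the header ids.
#' @return A complete `cross_impact_matrix`.
#' @seealso [write_matrix_csv()] for the inverse; the pair round-trips
#'   canonical files byte-exactly.
#' @export
read_matrix_csv <- function(path, goals = NULL) {
  if (!file.exists(path)) {
    cim_stop(sprintf("matrix file not found: %s", path), class = "cim_error_io")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    cim_stop("matrix CSV has no data rows", class = "cim_error_io")
  }
  sep <- ","
  if (!grepl(",", lines[1]) && grepl(";", lines[1])) {
    warning("matrix CSV appears semicolon-delimited; accepting with sep=';'")
    sep <- ";"
  }
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(cells[[1]])
  if (length(header) < 3 || tolower(header[1]) != "goal") {
    cim_stop("malformed header: expected 'goal' followed by goal ids",
             class = "cim_error_io")
  }
  ids <- header[-1]
  n <- length(ids)
  if (length(cells) - 1 != n) {
    cim_stop(sprintf("expected %d data rows for %d goals, found %d",
                     n, n, length(cells) - 1), class = "cim_error_io")
  }
  W <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (r in seq_len(n)) {
    row <- trimws(cells[[r + 1]])
    # strsplit drops a trailing empty field (diagonal in the last column)
    if (length(row) == n) row <- c(row, "")
    if (length(row) != n + 1) {
      cim_stop(sprintf("row %d has %d cells, expected %d", r, length(row) - 1, n),
               class = "cim_error_io")
    }
    rid <- row[1]
    if (rid != ids[r]) {
      cim_stop(sprintf("row %d is goal %s but header column %d is %s",
                       r, sQuote(rid), r, sQuote(ids[r])), class = "cim_error_io")
    }
    for (c in seq_len(n)) {
      cell <- row[c + 1]
      if (r == c) {
        if (!(cell == "" || toupper(cell) == "NA")) {
          cim_stop(sprintf("self-interaction not allowed: diagonal cell (%s, %s) is %s",
                           rid, ids[c], sQuote(cell)),
                   class = "cim_error_diagonal", row = rid, column = ids[c])
        }
        next
      }
      if (cell == "" || toupper(cell) == "NA") {
        cim_stop(sprintf("missing score at (%s, %s)", rid, ids[c]),
                 class = "cim_error_missing_pair", row = rid, column = ids[c])
      }
      val <- suppressWarnings(as.numeric(cell))
      if (is.na(val) || !is_whole(val)) {
        cim_stop(sprintf("non-integer cell at (%s, %s): %s", rid, ids[c], sQuote(cell)),
                 class = "cim_error_io", row = rid, column = ids[c])
      }
      if (val < -3 || val > 3) {
        cim_stop(sprintf("score out of range at (%s, %s): %s", rid, ids[c], cell),
                 class = "cim_error_score_range", row = rid, column = ids[c])
      }
      W[r, c] <- as.integer(val)
    }
  }
  reg <- if (is.null(goals)) goal_registry(ids) else goal_registry(goals)
  if (!identical(reg$id, ids)) {
    reg <- reg[match(ids, reg$id), ]
    if (anyNA(reg$id)) {
      cim_stop("registry does not cover all goal ids in the file",
               class = "cim_error_unknown_goal")
    }
    rownames(reg) <- NULL
  }
  validate_cim(new_cim(W, reg))
}

#' Write a cross-impact matrix to canonical CSV
#'
#' Canonical form: comma-separated, diagonal written empty, no trailing
#' whitespace, LF line endings. Reading the file back reproduces the matrix
#' and re-writing reproduces the file byte-exactly.
#'
#' @param M A `cross_impact_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  validate_cim(M, complete = FALSE)
  W <- M$weights
  ids <- M$goals$id
  body <- vapply(seq_along(ids), function(r) {
    cells <- ifelse(is.na(W[r, ]), "", as.character(W[r, ]))
    paste(c(ids[r], cells), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("goal", ids), collapse = ","), body), con, sep = "\n")
  invisible(path)
}

#' Export the interaction network as an edge list
#'
#' One row per directed link in registry (row-major) order. Zero-weight
#' cells are excluded by default — drawn networks show influences, not the
#' absence of influence — and included on request, giving all `n * (n - 1)`
#' rows.
#'
#' @param M A complete `cross_impact_matrix`.
#' @param path Optional TSV output path; when `NULL` only the data frame is
#'   returned.
#' @param include_zeros Emit zero-weight links too. Default `FALSE`.
#' @return Data frame with columns `source`, `target`, `weight`
#'   (invisibly when `path` is given).
#' @export
export_edge_list <- function(M, path = NULL, include_zeros = FALSE) {
  validate_cim(M)
  edges <- as_score_table(M)
  names(edges)[names(edges) == "score"] <- "weight"
  if (!include_zeros) edges <- edges[edges$weight != 0, ]
  rownames(edges) <- NULL
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    return(invisible(edges))
  }
  edges
}

#' Export the interaction network as GraphML
#'
#' Builds a weighted directed igraph graph (vertices = goals with `name`
#' attribute, edges carrying the integer `weight`) and writes GraphML for
#' use in external network tools.
#'
#' @inheritParams export_edge_list
#' @param path GraphML output path.
#' @return The igraph object, invisibly.
#' @export
export_graphml <- function(M, path, include_zeros = FALSE) {
  g <- as_igraph(M, include_zeros = include_zeros)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Convert a cross-impact matrix to an igraph graph
#'
#' @inheritParams export_edge_list
#' @return A directed igraph graph with edge attribute `weight` and vertex
#'   attributes `name` and `label`.
#' @export
as_igraph <- function(M, include_zeros = FALSE) {
  validate_cim(M)
  edges <- export_edge_list(M, include_zeros = include_zeros)
  verts <- data.frame(name = M$goals$id, label = M$goals$name,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

matrix_checksum <- function(M) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_matrix_csv(M, tmp)
  unname(tools::md5sum(tmp))
}

#' Full analysis report for a matrix
#'
#' Bundles the composition summary, the per-goal influence table, both
#' rankings with rank shifts, and (optionally) a focal-goal perspective,
#' together with provenance (input path or seed, matrix checksum, package
#' version) sufficient to reproduce the report. The report is a pure
#' function of the matrix and flags: re-deriving it from the same matrix
#' reproduces it exactly.
#'
#' @param M A complete `cross_impact_matrix`.
#' @param focal Optional focal goal id to include a perspective block.
#' @param exclude_backlink Passed to [total_influence()].
#' @param input Optional provenance note (input path).
#' @param seed Optional provenance note (generator seed).
#' @return An object of class `analysis_report` (a nested list).
#' @seealso [write_report_json()]
#' @export
analysis_report <- function(M, focal = NULL, exclude_backlink = FALSE,
                            input = NULL, seed = NULL) {
  validate_cim(M)
  s <- summarize_matrix(M)
  rep <- influence_report(M, exclude_backlink = exclude_backlink)
  out <- list(
    summary = unclass(s),
    influence = rep,
    ranking_first = rank_goals(M, "first", exclude_backlink = exclude_backlink),
    ranking_total = rank_goals(M, "total", exclude_backlink = exclude_backlink),
    provenance = list(
      tool = "crossimpact",
      version = as.character(utils::packageVersion("crossimpact")),
      input = input,
      seed = seed,
      matrix_md5 = matrix_checksum(M),
      exclude_backlink = exclude_backlink
    )
  )
  if (!is.null(focal)) {
    p <- focal_perspective(M, focal)
    out$focal <- list(
      goal = p$goal,
      first_order_out = as.list(p$first_order_out),
      first_order_in = as.list(p$first_order_in),
      second_order_out = as.list(p$second_order_out),
      second_order_in = as.list(p$second_order_in),
      feedback = p$feedback
    )
  }
  structure(out, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Cross-impact analysis report\n")
  cat(sprintf("  %d goals, %d interactions: %d%% positive, %d%% negative, %d%% zero\n",
              x$summary$n_goals, x$summary$n_interactions,
              x$summary$pct_positive, x$summary$pct_negative, x$summary$pct_zero))
  top <- x$ranking_total[1, ]
  cat(sprintf("  top goal by total influence: %s (%g)\n", top$goal, top$influence))
  if (!is.null(x$focal)) {
    cat(sprintf("  focal goal %s: feedback loop %g\n", x$focal$goal, x$focal$feedback))
  }
  invisible(x)
}

#' Write / read an analysis report as JSON
#'
#' @param report An [analysis_report()].
#' @param path Output path.
#' @return `path` invisibly; `read_report_json()` returns the parsed list.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write an influence report to flat CSV
#'
#' One row per goal: out/in degree, first-order, aggregate second-order,
#' total influence, both ranks and the rank shift.
#'
#' @param M A complete `cross_impact_matrix`.
#' @param path Output path.
#' @inheritParams total_influence
#' @return The influence data frame, invisibly.
#' @export
write_influence_csv <- function(M, path, exclude_backlink = FALSE) {
  rep <- influence_report(M, exclude_backlink = exclude_backlink)
  utils::write.csv(rep, path, row.names = FALSE, quote = FALSE)
  invisible(rep)
}

#' Read group score sets from CSV
#'
#' Expected columns: `group_id`, `source`, `target`, `score`, optionally
#' `motivation`.
#'
#' @param path CSV file path (one file may hold several groups).
#' @return A list of group score sets, one per distinct `group_id`.
#' @export
read_group_scores_csv <- function(path) {
  if (!file.exists(path)) {
    cim_stop(sprintf("group scores file not found: %s", path), class = "cim_error_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "source", "target", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    cim_stop(sprintf("group scores missing column(s): %s", paste(miss, collapse = ", ")),
             class = "cim_error_io")
  }
  lapply(split(df, df$group_id), function(g) group_scores(g$group_id[1], g))
}
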