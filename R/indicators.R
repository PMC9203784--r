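#' Construct an indicator time series
#'
#' A goal indicator observed in a (possibly sparse) set of years, together
#' with its direction of progress: for some indicators larger is better
#' (electricity access), for others smaller is better (under-five
#' mortality). The direction flag drives [recode_series()].
#'
#' @param goal_id Goal the indicator tracks.
#' @param indicator Indicator name.
#' @param years Integer vector of observation years, strictly increasing.
#' @param values Numeric observations, finite, same length as `years`.
#' @param increase_is_progress `TRUE` if larger values mean progress.
#' @return An object of class `indicator_series`.
#' @examples
#' indicator_series("3", "under-five mortality", c(2000, 2010), c(106, 44),
#'                  increase_is_progress = FALSE)
#' @export
indicator_series <- function(goal_id, indicator, years, values,
                             increase_is_progress) {
  years <- as.numeric(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    cim_stop("years and values must have equal length", class = "cim_error_series")
  }
  if (length(years) < 2) {
    cim_stop("an indicator series needs at least 2 observations",
             class = "cim_error_series")
  }
  if (is.unsorted(years, strictly = TRUE)) {
    cim_stop("years must be strictly increasing", class = "cim_error_series")
  }
  if (!all(is.finite(values))) {
    cim_stop("indicator values must be finite", class = "cim_error_series")
  }
  stopifnot(is.logical(increase_is_progress), length(increase_is_progress) == 1)
  structure(
    list(
      goal_id = as.character(goal_id),
      indicator = as.character(indicator),
      years = years,
      values = values,
      increase_is_progress = increase_is_progress
    ),
    class = "indicator_series"
  )
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("Indicator series: goal %s, %s (%s)\n", x$goal_id, x$indicator,
              if (x$increase_is_progress) "increase is progress" else "decrease is progress"))
  print(stats::setNames(x$values, x$years))
  invisible(x)
}

#' Recode a series so that higher always means progress
#'
#' Correlating raw indicators mixes directions (falling mortality is
#' progress, falling forest cover is not), so before any trend comparison
#' each series is re-oriented: values of decrease-is-progress indicators
#' are negated and the flag set. Recoding is idempotent — a series already
#' oriented to progress passes through unchanged.
#'
#' @param s An [indicator_series()].
#' @return The recoded `indicator_series` with `increase_is_progress = TRUE`.
#' @examples
#' s <- indicator_series("3", "u5mr", c(2000, 2019), c(106, 27), FALSE)
#' recode_series(s)$values # -106 -27
#' @export
recode_series <- function(s) {
  stopifnot(inherits(s, "indicator_series"))
  if (s$increase_is_progress) return(s)
  s$values <- -s$values
  s$increase_is_progress <- TRUE
  s
}

#' Paired-observation progress correlation between two indicators
#'
#' Pearson correlation over the years observed in both series, pairing by
#' exact year match only — missing years are never interpolated. Both
#' series are first recoded to progress orientation, so a positive r means
#' progress on one indicator has coincided with progress on the other, and
#' a negative r flags a diverging trend (a potential trade-off). A constant
#' series leaves r undefined; this is reported as a `"degenerate"` status,
#' never silently coerced to 0.
#'
#' @param a,b [indicator_series()] objects (recoded internally).
#' @param min_overlap Minimum number of shared observation years, default 3.
#' @return An object of class `correlation_result`: list with `pair`
#'   (goal/indicator of both series), `r`, `n_overlap`, `years`, `status`
#'   (`"ok"` or `"degenerate"`).
#' @examples
#' u5 <- indicator_series("3", "u5mr", c(2000, 2005, 2010, 2015),
#'                        c(106, 65, 44, 32), FALSE)
#' fa <- indicator_series("15", "forest area", c(2000, 2005, 2010, 2015),
#'                        c(61, 60, 50, 46), TRUE)
#' progress_correlation(u5, fa)
#' @export
progress_correlation <- function(a, b, min_overlap = 3) {
  stopifnot(inherits(a, "indicator_series"), inherits(b, "indicator_series"))
  if (!is_whole(min_overlap) || min_overlap < 2) {
    cim_stop("min_overlap must be an integer >= 2", class = "cim_error_config")
  }
  a <- recode_series(a)
  b <- recode_series(b)
  shared <- intersect(a$years, b$years)
  if (length(shared) < min_overlap) {
    cim_stop(
      sprintf(
        "insufficient overlap between %s/%s and %s/%s: %d shared year%s, need %d",
        a$goal_id, a$indicator, b$goal_id, b$indicator,
        length(shared), if (length(shared) == 1) "" else "s", min_overlap
      ),
      class = "cim_error_insufficient_overlap",
      n_overlap = length(shared)
    )
  }
  shared <- sort(shared)
  va <- a$values[match(shared, a$years)]
  vb <- b$values[match(shared, b$years)]
  degenerate <- stats::sd(va) == 0 || stats::sd(vb) == 0
  r <- if (degenerate) NA_real_ else stats::cor(va, vb)
  structure(
    list(
      pair = list(
        a = c(goal_id = a$goal_id, indicator = a$indicator),
        b = c(goal_id = b$goal_id, indicator = b$indicator)
      ),
      r = r,
      n_overlap = length(shared),
      years = shared,
      status = if (degenerate) "degenerate" else "ok"
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Progress correlation %s/%s vs %s/%s: r = %s over %d paired years (%s)\n",
    x$pair$a["goal_id"], x$pair$a["indicator"],
    x$pair$b["goal_id"], x$pair$b["indicator"],
    if (is.na(x$r)) "undefined (constant series)" else sprintf("%.3f", x$r),
    x$n_overlap, x$status
  ))
  invisible(x)
}

#' Read an indicator table from CSV
#'
#' Expected columns: `goal_id`, `indicator`, `year`, `value`,
#' `increase_is_progress` (logical or 0/1). One row per observation.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @seealso [series_from_table()] to extract one series;
#'   [cambodia_indicators()] for the packaged example table.
#' @export
read_indicator_csv <- function(path) {
  if (!file.exists(path)) {
    cim_stop(sprintf("indicator file not found: %s", path), class = "cim_error_io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("goal_id", "indicator", "year", "value", "increase_is_progress")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    cim_stop(sprintf("indicator table missing column(s): %s", paste(miss, collapse = ", ")),
             class = "cim_error_io")
  }
  df$goal_id <- as.character(df$goal_id)
  df$increase_is_progress <- as.logical(df$increase_is_progress)
  df
}

#' Extract one indicator series from a long indicator table
#'
#' @param table Data frame as returned by [read_indicator_csv()].
#' @param goal_id Goal id to select.
#' @param indicator Indicator name; may be omitted when the goal has a
#'   single indicator.
#' @return An [indicator_series()].
#' @export
series_from_table <- function(table, goal_id, indicator = NULL) {
  rows <- table[table$goal_id == as.character(goal_id), ]
  if (!is.null(indicator)) rows <- rows[rows$indicator == indicator, ]
  if (nrow(rows) == 0) {
    cim_stop(sprintf("no observations for goal %s%s", goal_id,
                     if (is.null(indicator)) "" else paste0(" / ", indicator)),
             class = "cim_error_series")
  }
  inds <- unique(rows$indicator)
  if (length(inds) > 1) {
    cim_stop(sprintf("goal %s has %d indicators (%s); name one",
                     goal_id, length(inds), paste(inds, collapse = "; ")),
             class = "cim_error_series")
  }
  rows <- rows[order(rows$year), ]
  indicator_series(goal_id, inds, rows$year, rows$value,
                   unique(rows$increase_is_progress))
}

#' All pairwise progress correlations in an indicator table
#'
#' Computes [progress_correlation()] for every pair of indicator series in
#' the table (per indicator, not pooled per goal: goals carrying several
#' indicators contribute each one separately). Pairs with insufficient year
#' overlap are reported with status `"insufficient_overlap"` and `r = NA`
#' rather than dropped silently.
#'
#' @param table Long indicator data frame ([read_indicator_csv()]).
#' @param min_overlap Minimum shared years, default 3.
#' @return A data frame with one row per indicator pair: goal ids,
#'   indicator names, `r`, `n_overlap`, `status`.
#' @export
correlate_indicators <- function(table, min_overlap = 3) {
  keys <- unique(table[, c("goal_id", "indicator")])
  series <- lapply(seq_len(nrow(keys)), function(i) {
    series_from_table(table, keys$goal_id[i], keys$indicator[i])
  })
  n <- length(series)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      res <- tryCatch(
        progress_correlation(series[[i]], series[[j]], min_overlap = min_overlap),
        cim_error_insufficient_overlap = function(e) e
      )
      if (inherits(res, "correlation_result")) {
        row <- data.frame(
          goal_a = series[[i]]$goal_id, indicator_a = series[[i]]$indicator,
          goal_b = series[[j]]$goal_id, indicator_b = series[[j]]$indicator,
          r = res$r, n_overlap = res$n_overlap, status = res$status,
          stringsAsFactors = FALSE
        )
      } else {
        row <- data.frame(
          goal_a = series[[i]]$goal_id, indicator_a = series[[i]]$indicator,
          goal_b = series[[j]]$goal_id, indicator_b = series[[j]]$indicator,
          r = NA_real_, n_overlap = res$n_overlap %||% NA_integer_,
          status = "insufficient_overlap",
          stringsAsFactors = FALSE
        )
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
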