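#' The seven-point cross-impact scale
#'
#' Cross-impact scoring uses the Weimer-Jehle seven-point scale: integer
#' scores from -3 (strongly restricting) through 0 (no influence) to +3
#' (strongly promoting). The scale is the unit of every matrix cell in this
#' package; all analysis layers operate on these integers and reject
#' anything outside them.
#'
#' @return A data frame with columns `label` and `score`, one row per level,
#'   ordered from -3 to +3.
#' @examples
#' scale_definition()
#' @export
scale_definition <- function() {
  data.frame(
    label = names(.cim_scale),
    score = unname(.cim_scale),
    stringsAsFactors = FALSE
  )
}

.cim_scale <- c(
  "strongly restricting"   = -3L,
  "moderately restricting" = -2L,
  "weakly restricting"     = -1L,
  "no influence"           = 0L,
  "weakly promoting"       = 1L,
  "moderately promoting"   = 2L,
  "strongly promoting"     = 3L
)

# Built-in synonyms: bare verb forms ("strongly promote") map to the
# canonical participles.
.cim_scale_synonyms <- local({
  syn <- c(
    "strongly restrict"   = "strongly restricting",
    "moderately restrict" = "moderately restricting",
    "weakly restrict"     = "weakly restricting",
    "strongly promote"    = "strongly promoting",
    "moderately promote"  = "moderately promoting",
    "weakly promote"      = "weakly promoting"
  )
  syn
})

normalise_label <- function(label) {
  label <- tolower(trimws(label))
  gsub("[[:space:]]+", " ", label)
}

#' Convert a qualitative scale label to its integer score
#'
#' @param label Character vector of scale labels. Matching is
#'   case-insensitive and whitespace-tolerant; bare verb forms such as
#'   `"strongly promote"` are accepted, and further synonyms can be supplied.
#' @param synonyms Optional named character vector of additional synonyms
#'   (`c("fortement positif" = "strongly promoting")`).
#' @return Integer vector of scores in -3..+3.
#' @seealso [score_to_label()] for the inverse mapping.
#' @examples
#' label_to_score("strongly promoting") # 3
#' label_to_score("No Influence")       # 0
#' @export
label_to_score <- function(label, synonyms = NULL) {
  stopifnot(is.character(label))
  lab <- normalise_label(label)
  syn <- .cim_scale_synonyms
  if (!is.null(synonyms)) {
    stopifnot(is.character(synonyms), !is.null(names(synonyms)))
    syn <- c(syn, stats::setNames(normalise_label(synonyms), normalise_label(names(synonyms))))
  }
  hit <- !is.na(match(lab, names(syn)))
  lab[hit] <- syn[lab[hit]]
  out <- .cim_scale[lab]
  if (anyNA(out)) {
    bad <- unique(label[is.na(out)])
    cim_stop(
      sprintf(
        "unknown scale label%s: %s",
        if (length(bad) > 1) "s" else "",
        paste(sQuote(bad), collapse = ", ")
      ),
      class = "cim_error_unknown_label",
      labels = bad
    )
  }
  unname(out)
}

#' Convert an integer score to its qualitative scale label
#'
#' @param score Integer vector with values in -3..+3.
#' @return Character vector of canonical labels.
#' @examples
#' score_to_label(-3) # "strongly restricting"
#' @export
score_to_label <- function(score) {
  assert_in_scale(score)
  names(.cim_scale)[match(as.integer(score), .cim_scale)]
}

assert_in_scale <- function(score, what = "score") {
  if (!all(is_whole(score)) || any(score < -3 | score > 3)) {
    bad <- unique(score[!(is_whole(score) & score >= -3 & score <= 3)])
    cim_stop(
      sprintf(
        "%s must be an integer in -3..+3; got %s",
        what, paste(bad, collapse = ", ")
      ),
      class = "cim_error_score_range",
      values = bad
    )
  }
  invisible(TRUE)
}

#' Classify a score by sign
#'
#' Interactions are synergies (positive scores), trade-offs (negative
#' scores) or neutral (zero: no direct influence).
#'
#' @param score Integer vector with values in -3..+3.
#' @return Character vector: `"positive"`, `"negative"` or `"zero"`.
#' @examples
#' classify_score(c(3, 0, -1))
#' @export
classify_score <- function(score) {
  assert_in_scale(score)
  c("negative", "zero", "positive")[sign(score) + 2L]
}
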