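# Ordinal reader scores: straining effort and organ-point visibility, with the
# frequency/percentage summaries used in reader studies.

#' Ordinal scale levels
#' @return Character vector of levels in scale order.
#' @name qualitative_scales
NULL

#' @rdname qualitative_scales
#' @export
effort_levels <- function() c("good", "suboptimal", "none")

#' @rdname qualitative_scales
#' @export
visibility_levels <- function() c("not_visible", "partly_visible", "fully_visible")

# Round half away from zero to `digits` decimals (matches how clinical tables
# are typically rounded; base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.summarize_scale <- function(values, levels, what) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no ", what, " scores to summarize", call. = FALSE)
  bad <- setdiff(unique(values), levels)
  if (length(bad)) {
    stop("unknown ", what, " score(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- vapply(levels, function(l) sum(values == l), integer(1))
  tibble::tibble(score = levels, n = unname(n),
                 percent = round_half_up(100 * unname(n) / sum(n), 1))
}

#' Summarize straining-effort scores
#'
#' Counts and percentages (one decimal, half-up) per category of the 3-point
#' straining-effort scale, in scale order (good, suboptimal, none).
#'
#' @param scores Data frame with columns `sequence` and `score`, or a character
#'   vector of scores.
#' @param sequence If `scores` is a data frame, which sequence to summarize.
#' @return Tibble with `score`, `n`, `percent`.
#' @export
summarize_effort <- function(scores, sequence = NULL) {
  values <- if (is.data.frame(scores)) {
    if (!is.null(sequence)) scores$score[scores$sequence == sequence]
    else scores$score
  } else scores
  .summarize_scale(values, effort_levels(), "straining-effort")
}

#' Summarize organ-point visibility scores
#'
#' Counts and percentages per category of the 3-point visibility scale, plus
#' the combined "not fully visible" fraction (not visible + partly visible).
#'
#' @param scores Data frame with columns `sequence`, `organ`, `phase`, `score`,
#'   or a character vector of scores.
#' @param sequence,organ,phase Optional filters when `scores` is a data frame.
#' @return List with `table` (tibble `score`, `n`, `percent`) and
#'   `not_fully_visible_percent`.
#' @export
summarize_visibility <- function(scores, sequence = NULL, organ = NULL,
                                 phase = NULL) {
  values <- if (is.data.frame(scores)) {
    keep <- rep(TRUE, nrow(scores))
    if (!is.null(sequence)) keep <- keep & scores$sequence == sequence
    if (!is.null(organ)) keep <- keep & scores$organ == organ
    if (!is.null(phase)) keep <- keep & scores$phase == phase
    scores$score[keep]
  } else scores
  tab <- .summarize_scale(values, visibility_levels(), "visibility")
  nfv <- sum(tab$n[tab$score != "fully_visible"])
  list(table = tab,
       not_fully_visible_percent = round_half_up(100 * nfv / sum(tab$n), 1))
}
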