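#' @title Wing-score categories
#' @description Ordinal wing-defect scores record how many of the five
#'   scoreable wing cells carry ectopic vein material (0 = wild type, 5 = all
#'   five cells affected). Blistered wings receive the special, unordered
#'   category `"B"` and are excluded from rank statistics.
#' @name wing-scores
NULL

SCORE_LEVELS <- c("0", "1", "2", "3", "4", "5", "B")
ORDINAL_LEVELS <- c("0", "1", "2", "3", "4", "5")

#' Validate a vector of wing-score tokens
#'
#' @param score character (or numeric) vector of score tokens.
#' @return character vector of normalized tokens in `{"0",...,"5","B"}`.
#' @keywords internal
normalize_scores <- function(score) {
  s <- trimws(as.character(score))
  bad <- which(!(s %in% SCORE_LEVELS))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid wing score %s at row %d (allowed: 0-5 or B)",
      dQuote(s[bad[1]]), bad[1]
    ), call. = FALSE)
  }
  s
}

#' Construct a per-genotype score table
#'
#' A score table holds the per-category wing counts for one genotype: the six
#' ordinal categories 0-5 plus the blister category B.
#'
#' @param genotype nonempty genotype label.
#' @param counts nonnegative integer vector of length 6 (categories 0-5) or 7
#'   (0-5 plus B); names, if present, must be `c("0",...,"5")` or
#'   `c("0",...,"5","B")`.
#' @param b blister count, used when `counts` has length 6. Default 0.
#' @return object of class `score_table` with elements `genotype`, `counts`
#'   (named length-7 integer), `n_scored` (all wings) and `n_analyzed` (wings
#'   entering rank statistics, i.e. excluding B).
#' @examples
#' score_table("ash1", c(0, 2, 8, 14, 6, 0))
#' @export
score_table <- function(genotype, counts, b = 0) {
  if (!is.character(genotype) || length(genotype) != 1L || !nzchar(genotype)) {
    stop("genotype must be a nonempty string", call. = FALSE)
  }
  if (length(counts) == 6L) counts <- c(counts, B = b)
  if (length(counts) != 7L) {
    stop("counts must have length 6 (scores 0-5) or 7 (plus B)", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  names(counts) <- SCORE_LEVELS
  structure(
    list(
      genotype = genotype,
      counts = counts,
      n_scored = sum(counts),
      n_analyzed = sum(counts[ORDINAL_LEVELS])
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(
    "<score_table> %s  [%s]  n_scored=%d n_analyzed=%d\n",
    x$genotype,
    paste(sprintf("%s:%d", names(x$counts), x$counts), collapse = " "),
    x$n_scored, x$n_analyzed
  ))
  invisible(x)
}

#' Tabulate per-wing records into per-genotype score tables
#'
#' @param records data frame with columns `genotype` (nonempty strings) and
#'   `score` (tokens in 0-5 or B); one row per scored wing. Extra columns
#'   (sex, cross id, ...) are ignored.
#' @return named list of [score_table] objects, one per genotype, in order of
#'   first appearance.
#' @examples
#' rec <- data.frame(genotype = "ash1",
#'                   score = rep(c("1", "2", "3", "4"), c(2, 8, 14, 6)))
#' tabulate_scores(rec)
#' @export
tabulate_scores <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("genotype", "score") %in% names(records))) {
    stop("records must have columns 'genotype' and 'score'", call. = FALSE)
  }
  if (nrow(records) == 0L) return(structure(list(), names = character(0)))
  geno <- as.character(records$genotype)
  if (any(is.na(geno) | !nzchar(trimws(geno)))) {
    stop(sprintf("empty genotype label at row %d",
                 which(is.na(geno) | !nzchar(trimws(geno)))[1]), call. = FALSE)
  }
  score <- normalize_scores(records$score)
  labels <- unique(geno)
  out <- lapply(labels, function(g) {
    cnt <- table(factor(score[geno == g], levels = SCORE_LEVELS))
    score_table(g, as.integer(cnt))
  })
  names(out) <- labels
  out
}

#' Drop blistered wings from a score table
#'
#' Blistered wings (category B) are scored but excluded from rank statistics;
#' this zeroes the B count and leaves the ordinal categories untouched.
#'
#' @param table a [score_table].
#' @return a [score_table] with `counts["B"] == 0`; its `n_scored` equals the
#'   input's `n_analyzed`.
#' @export
exclude_blistered <- function(table) {
  stopifnot(inherits(table, "score_table"))
  cnt <- table$counts
  cnt["B"] <- 0L
  score_table(table$genotype, cnt)
}

#' Expand a score table into its per-wing ordinal scores
#'
#' Blistered wings carry no ordinal value and are never expanded.
#'
#' @param table a [score_table].
#' @return integer vector of length `n_analyzed` with values in 0-5.
#' @export
expand_scores <- function(table) {
  stopifnot(inherits(table, "score_table"))
  rep(0:5, table$counts[ORDINAL_LEVELS])
}
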