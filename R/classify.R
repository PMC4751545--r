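#' Classify a candidate as enhancer, suppressor, blister interaction, or none
#'
#' A candidate whose scores are shifted significantly above the control is an
#' enhancer of the wing-defect phenotype; one shifted below is a suppressor.
#' A candidate with a large fraction of blistered wings is flagged as a
#' blister interaction regardless of the rank test, since blistered wings are
#' excluded from the rank statistics and a blister excess is itself evidence
#' of interaction.
#'
#' @param result a [rank_sum_result] for the candidate against the control.
#' @param table the candidate's [score_table] *before* blister exclusion
#'   (the blister fraction is B over all scored wings).
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @param blister_threshold minimum blister fraction to call a blister
#'   interaction; default 0.25.
#' @return object of class `interaction_call` with `label` (one of
#'   `"enhancer"`, `"suppressor"`, `"no_modification"`,
#'   `"blister_interaction"`), `alpha_used` and `blister_fraction`.
#' @export
classify_interaction <- function(result, table, alpha = 0.05,
                                 blister_threshold = 0.25) {
  stopifnot(inherits(result, "rank_sum_result"), inherits(table, "score_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  blister_fraction <- if (table$n_scored > 0) {
    as.numeric(table$counts["B"]) / table$n_scored
  } else 0
  label <- if (blister_fraction >= blister_threshold) {
    "blister_interaction"
  } else if (result$p_two_sided < alpha && result$direction == "higher") {
    "enhancer"
  } else if (result$p_two_sided < alpha && result$direction == "lower") {
    "suppressor"
  } else {
    "no_modification"
  }
  structure(
    list(label = label, alpha_used = alpha,
         blister_fraction = blister_fraction),
    class = "interaction_call"
  )
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s (alpha=%g, blister fraction=%.2f)\n",
              x$label, x$alpha_used, x$blister_fraction))
  invisible(x)
}

#' Full screen report against a named control
#'
#' Runs blister exclusion, the rank-sum test against the control, and
#' interaction classification for every candidate genotype, and assembles a
#' report mirroring the screen's tables: per-category counts, blister count,
#' p-value and call. The control row comes first (no p-value); candidates
#' follow in input order.
#'
#' @param tables named list of [score_table] objects (e.g. from
#'   [tabulate_scores()] or [read_score_csv()]).
#' @param control_label name of the control genotype; must be present.
#' @param alpha,blister_threshold passed to [classify_interaction()].
#' @param method passed to [rank_sum_test()].
#' @return data frame with columns `genotype`, `s0`..`s5`, `B`, `n_analyzed`,
#'   `p_value`, `call`.
#' @examples
#' tabs <- list(
#'   Luciferase = score_table("Luciferase", c(0, 5, 20, 35, 7, 0)),
#'   ash1 = score_table("ash1", c(0, 2, 8, 14, 6, 0))
#' )
#' screen_report(tabs, "Luciferase")
#' @export
screen_report <- function(tables, control_label, alpha = 0.05,
                          method = "normal_tie_corrected",
                          blister_threshold = 0.25) {
  stopifnot(is.list(tables), length(tables) > 0)
  if (!(control_label %in% names(tables))) {
    stop(sprintf("control genotype %s not found among score tables",
                 dQuote(control_label)), call. = FALSE)
  }
  control <- exclude_blistered(tables[[control_label]])
  order_labels <- c(control_label,
                    setdiff(names(tables), control_label))
  rows <- lapply(order_labels, function(g) {
    tab <- tables[[g]]
    cnt <- as.integer(tab$counts)
    row <- data.frame(
      genotype = g,
      s0 = cnt[1], s1 = cnt[2], s2 = cnt[3], s3 = cnt[4], s4 = cnt[5],
      s5 = cnt[6], B = cnt[7], n_analyzed = tab$n_analyzed,
      p_value = NA_real_, call = NA_character_,
      stringsAsFactors = FALSE
    )
    if (g != control_label) {
      if (tab$n_analyzed == 0L) {
        # all wings blistered: no rank test possible, call on blisters alone
        frac <- as.numeric(tab$counts["B"]) / max(tab$n_scored, 1L)
        row$call <- if (frac >= blister_threshold) "blister_interaction"
          else "no_modification"
      } else {
        res <- rank_sum_test(exclude_blistered(tab), control, method = method)
        call <- classify_interaction(res, tab, alpha = alpha,
                                     blister_threshold = blister_threshold)
        row$p_value <- res$p_two_sided
        row$call <- call$label
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
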