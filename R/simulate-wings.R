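#' Simulate per-wing ordinal scores under a proportional-odds shift
#'
#' Draws independent wings from a baseline ordinal score distribution shifted
#' on the cumulative-logit scale, the standard latent-shift model for ordinal
#' severity data. A positive `effect_delta` moves probability mass toward
#' higher (more defective) scores, emulating an enhancer; a negative delta
#' emulates a suppressor; `effect_delta = 0` is the null. Each wing is
#' independently blistered (category B, no ordinal score) with probability
#' `blister_prob`, mirroring how blistered wings are scored separately and
#' excluded from rank statistics.
#'
#' The default baseline is the empirical control distribution of the screen's
#' long-hairpin arm: counts (0, 5, 20, 35, 7, 0) over scores 0-5, i.e. 67
#' control wings.
#'
#' @param n_wings number of wings to simulate.
#' @param control_probs baseline probability vector over scores 0-5; must sum
#'   to 1 and have mass in more than one category.
#' @param effect_delta shift on the cumulative log-odds scale (0 = null).
#' @param blister_prob probability a wing is blistered, in \[0, 1\].
#' @param genotype genotype label stamped on every record.
#' @param seed optional integer seed for reproducibility.
#' @return data frame with columns `genotype` and `score` (character tokens
#'   `"0"`..`"5"` or `"B"`), one row per wing — ready for
#'   [tabulate_scores()].
#' @examples
#' sim <- simulate_wing_scores(30, effect_delta = 1.5, seed = 1)
#' table(sim$score)
#' @export
simulate_wing_scores <- function(n_wings,
                                 control_probs = c(0, 5, 20, 35, 7, 0) / 67,
                                 effect_delta = 0,
                                 blister_prob = 0,
                                 genotype = "sim",
                                 seed = NULL) {
  stopifnot(n_wings >= 1, length(control_probs) == 6)
  if (any(control_probs < 0) || abs(sum(control_probs) - 1) > 1e-9) {
    stop("control_probs must be nonnegative and sum to 1", call. = FALSE)
  }
  if (blister_prob < 0 || blister_prob > 1) {
    stop("blister_prob must lie in [0, 1]", call. = FALSE)
  }
  cum <- cumsum(control_probs)[1:5]
  if (all(cum <= 1e-12 | cum >= 1 - 1e-12)) {
    stop("degenerate control_probs: all mass in one category, ",
         "no cumulative cutpoint to shift", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # shift cumulative logits; delta > 0 lowers each F_j => mass moves up
  shifted_cum <- stats::plogis(stats::qlogis(cum) - effect_delta)
  probs <- diff(c(0, shifted_cum, 1))
  probs <- pmax(probs, 0)
  score <- as.character(sample(0:5, n_wings, replace = TRUE, prob = probs))
  blister <- stats::runif(n_wings) < blister_prob
  score[blister] <- "B"
  data.frame(genotype = genotype, score = score, stringsAsFactors = FALSE)
}
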