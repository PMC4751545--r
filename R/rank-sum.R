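#' Mann-Whitney U statistic for two score samples
#'
#' Computes the pair-count statistic for the candidate sample: one point per
#' candidate > control pair and half a point per tied pair. The midrank
#' formulation (rank-sum minus its minimum) is algebraically identical and is
#' provided as a cross-check route.
#'
#' @param x,y numeric vectors of ordinal scores (candidate, control).
#' @param method `"paircount"` (direct pair counting) or `"midrank"`
#'   (rank-sum identity).
#' @return the U statistic for `x` against `y`.
#' @export
u_statistic <- function(x, y, method = c("paircount", "midrank")) {
  method <- match.arg(method)
  if (method == "paircount") {
    cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
    sum(cmp)
  } else {
    r <- rank(c(x, y)) # midranks for ties
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
}

# U from per-category counts: sum_i c1_i * (#control strictly below i)
# + half credit for within-category ties.
u_from_counts <- function(c1, c2) {
  below <- c(0, cumsum(c2)[-length(c2)])
  sum(c1 * below) + 0.5 * sum(c1 * c2)
}

# Tie-corrected variance of U under the null: (n1*n2/12) *
# [(n+1) - sum(t^3 - t) / (n*(n-1))], tie groups t from the pooled sample.
tie_corrected_variance <- function(n1, n2, ties) {
  n <- n1 + n2
  if (n < 2) return(0)
  (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
}

#' Mann-Whitney rank-sum test on two score tables
#'
#' Compares candidate wing scores against a control using the Mann-Whitney
#' U test, either with the tie-corrected normal approximation (no continuity
#' correction) or by exact enumeration of all group assignments. Blistered
#' wings must already be excluded (see [exclude_blistered()]); a table with a
#' nonzero B count is refused.
#'
#' The exact mode enumerates allocations of the pooled per-category counts to
#' the candidate group, weighting each allocation by its multivariate
#' hypergeometric multiplicity, and reports the proportion of assignments at
#' least as extreme (in |U - n1*n2/2|) as observed. Ties carry the same
#' half-credit in both modes, so the two modes share one statistic.
#'
#' @param candidate,control [score_table] objects with `counts["B"] == 0`.
#' @param method `"normal_tie_corrected"` (default) or `"exact_permutation"`.
#' @return object of class `rank_sum_result`: `U_candidate`, `mean_U`
#'   (`n1*n2/2`), `variance_U` (tie-corrected; `NA` for exact mode), `z`,
#'   `p_two_sided`, `direction` (`"higher"`, `"lower"` or `"none"`),
#'   `method`, `n1`, `n2`.
#' @examples
#' luc <- score_table("Luciferase", c(0, 5, 20, 35, 7, 0))
#' ash1 <- score_table("ash1", c(0, 2, 8, 14, 6, 0))
#' rank_sum_test(ash1, luc)
#' @export
rank_sum_test <- function(candidate, control,
                          method = c("normal_tie_corrected",
                                     "exact_permutation")) {
  method <- match.arg(method)
  stopifnot(inherits(candidate, "score_table"), inherits(control, "score_table"))
  if (candidate$counts["B"] > 0 || control$counts["B"] > 0) {
    stop("blistered wings present; call exclude_blistered() first",
         call. = FALSE)
  }
  c1 <- as.numeric(candidate$counts[ORDINAL_LEVELS])
  c2 <- as.numeric(control$counts[ORDINAL_LEVELS])
  n1 <- sum(c1)
  n2 <- sum(c2)
  if (n1 < 1 || n2 < 1) {
    stop("empty group: both tables need at least one non-blistered wing",
         call. = FALSE)
  }
  u <- u_from_counts(c1, c2)
  mean_u <- n1 * n2 / 2
  pooled <- c1 + c2
  ties <- pooled[pooled > 0]

  if (method == "normal_tie_corrected") {
    var_u <- tie_corrected_variance(n1, n2, ties)
    if (var_u <= 0) {
      # every wing in one tied category: no information, defined null result
      z <- 0
      p <- 1
    } else {
      z <- (u - mean_u) / sqrt(var_u)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  } else {
    var_u <- NA_real_
    z <- NA_real_
    p <- exact_rank_sum_p(c1, c2, u, mean_u)
  }

  direction <- if (abs(u - mean_u) < 1e-9) "none" else
    if (u > mean_u) "higher" else "lower"
  structure(
    list(U_candidate = u, mean_U = mean_u, variance_U = var_u, z = z,
         p_two_sided = p, direction = direction, method = method,
         n1 = n1, n2 = n2),
    class = "rank_sum_result"
  )
}

# Exact two-sided p by enumeration of candidate count allocations over the
# pooled tied categories (multivariate hypergeometric weights).
exact_rank_sum_p <- function(c1, c2, u_obs, mean_u) {
  n1 <- sum(c1)
  pooled <- c1 + c2
  keep <- pooled > 0
  t <- pooled[keep]
  n_alloc <- prod(pmin(t, n1) + 1)
  if (n_alloc > 5e5) {
    stop("exact enumeration too large for this sample; ",
         "use method = 'normal_tie_corrected'", call. = FALSE)
  }
  grid <- as.matrix(expand.grid(lapply(t, function(ti) 0:min(ti, n1))))
  grid <- grid[rowSums(grid) == n1, , drop = FALSE]
  ctrl <- sweep(-grid, 2, t, "+") # t_j - c_j
  k <- length(t)
  below <- if (k == 1L) {
    matrix(0, nrow(grid), 1L)
  } else {
    cbind(0, t(apply(ctrl, 1, cumsum))[, -k, drop = FALSE])
  }
  u_all <- rowSums(grid * below) + 0.5 * rowSums(grid * ctrl)
  logw <- rowSums(lchoose(matrix(t, nrow(grid), k, byrow = TRUE), grid))
  w <- exp(logw - lchoose(sum(t), n1))
  extreme <- abs(u_all - mean_u) >= abs(u_obs - mean_u) - 1e-9
  min(1, sum(w[extreme]))
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf(
    "<rank_sum_result> U=%.1f (null mean %.1f), n1=%d n2=%d, %s\n  p=%.4g, direction=%s\n",
    x$U_candidate, x$mean_U, x$n1, x$n2, x$method, x$p_two_sided, x$direction
  ))
  invisible(x)
}
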