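#' Brute-force exact rank-sum p-value (testing oracle)
#'
#' Independent reference implementation of the exact two-sided Mann-Whitney
#' p-value: iterates over every assignment of the pooled observations into a
#' candidate group of the observed size, scores each assignment by direct
#' pairwise comparison (half-credit ties), and reports the proportion at
#' least as far from the null mean as the observed statistic. Shares no code
#' with [rank_sum_test()]; intended for validating it on small samples.
#'
#' @param candidate,control numeric vectors of raw scores.
#' @param max_n largest combined sample size accepted for full enumeration.
#' @return exact two-sided p-value in \[0, 1\].
#' @examples
#' exact_oracle_p(c(1, 2), c(3, 4)) # 2 of 6 assignments as extreme
#' @export
exact_oracle_p <- function(candidate, control, max_n = 20) {
  x <- as.numeric(candidate)
  y <- as.numeric(control)
  n1 <- length(x)
  n <- n1 + length(y)
  if (n1 < 1 || length(y) < 1) stop("empty group", call. = FALSE)
  if (n > max_n) {
    stop(sprintf(
      "combined n = %d exceeds enumeration cap %d; use a seeded Monte Carlo approximation instead",
      n, max_n), call. = FALSE)
  }
  z <- c(x, y)
  # pairwise win/tie matrix over the pooled sample
  g <- outer(z, z, ">") + 0.5 * outer(z, z, "==")
  mean_u <- n1 * (n - n1) / 2
  u_obs <- sum(g[seq_len(n1), -seq_len(n1), drop = FALSE])
  subsets <- utils::combn(n, n1)
  u_all <- apply(subsets, 2, function(idx) sum(g[idx, -idx, drop = FALSE]))
  mean(abs(u_all - mean_u) >= abs(u_obs - mean_u) - 1e-9)
}
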