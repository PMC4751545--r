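test_that("tie-corrected normal approximation reproduces screen p-values", {
  luc <- luciferase_table()
  ash1 <- score_table("ash1", c(0, 2, 8, 14, 6, 0))
  hp1c <- score_table("Hp1c", c(0, 0, 7, 25, 5, 0))
  expect_equal(round(rank_sum_test(ash1, luc)$p_two_sided, 3), 0.415)
  expect_equal(round(rank_sum_test(hp1c, luc)$p_two_sided, 3), 0.061)
})

test_that("identical distributions give the null result", {
  tab <- score_table("a", c(0, 3, 5, 2, 0, 0))
  tab2 <- score_table("b", c(0, 3, 5, 2, 0, 0))
  r <- rank_sum_test(tab, tab2)
  expect_equal(r$U_candidate, r$mean_U)
  expect_equal(r$z, 0)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$direction, "none")
})

test_that("exact enumeration matches hand-enumerated small cases", {
  # {1,2} vs {3,4}: U = 0, and 2 of the 6 assignments are as extreme
  cand <- scores_to_table(c(1, 2))
  ctrl <- scores_to_table(c(3, 4))
  r <- rank_sum_test(cand, ctrl, method = "exact_permutation")
  expect_equal(r$U_candidate, 0)
  expect_equal(r$p_two_sided, 2 / 6, tolerance = 1e-12)
  expect_equal(r$direction, "lower")
})

test_that("zero-variance (single tied category) yields the defined null", {
  a <- score_table("a", c(0, 0, 4, 0, 0, 0))
  b <- score_table("b", c(0, 0, 6, 0, 0, 0))
  r <- rank_sum_test(a, b)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$direction, "none")
})

test_that("tables with blistered wings are refused until excluded", {
  a <- score_table("a", c(0, 1, 2, 0, 0, 0), b = 2)
  expect_error(rank_sum_test(a, luciferase_table()), "exclude_blistered")
  expect_silent(rank_sum_test(exclude_blistered(a), luciferase_table()))
})

test_that("pair-count and midrank formulations of U agree", {
  set.seed(41)
  for (i in 1:100) {
    p <- random_score_pair()
    expect_equal(u_statistic(p$x, p$y, "paircount"),
                 u_statistic(p$x, p$y, "midrank"), tolerance = 1e-9)
  }
})

test_that("U_candidate + U_control equals n1*n2 and swap flips direction", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_score_pair()
    a <- scores_to_table(p$x, "a")
    b <- scores_to_table(p$y, "b")
    r1 <- rank_sum_test(a, b)
    r2 <- rank_sum_test(b, a)
    expect_equal(r1$U_candidate + r2$U_candidate,
                 length(p$x) * length(p$y), tolerance = 1e-9)
    expect_equal(r1$p_two_sided, r2$p_two_sided, tolerance = 1e-12)
    expect_true(
      (r1$direction == "none" && r2$direction == "none") ||
        (r1$direction == "higher" && r2$direction == "lower") ||
        (r1$direction == "lower" && r2$direction == "higher")
    )
  }
})

test_that("without ties the variance reduces to n1*n2*(n+1)/12", {
  # distinct scores across groups: each pooled tie group has size 1
  a <- scores_to_table(c(0, 2, 4), "a")
  b <- scores_to_table(c(1, 3, 5), "b")
  r <- rank_sum_test(a, b)
  expect_equal(r$variance_U, 3 * 3 * 7 / 12, tolerance = 1e-12)
})

test_that("blistered wings never influence the rank test after exclusion", {
  set.seed(43)
  for (i in 1:20) {
    p <- random_score_pair()
    a <- scores_to_table(p$x, "a")
    b <- scores_to_table(p$y, "b")
    a_b <- score_table("a", a$counts[1:6], b = sample(0:20, 1))
    r1 <- rank_sum_test(a, b)
    r2 <- rank_sum_test(exclude_blistered(a_b), b)
    expect_equal(r1$p_two_sided, r2$p_two_sided)
    expect_equal(r1$U_candidate, r2$U_candidate)
  }
})

test_that("normal approximation agrees with the standard reference", {
  # independent route: stats::wilcox.test tie-corrected normal approximation
  set.seed(44)
  for (i in 1:50) {
    p <- random_score_pair()
    if (length(unique(c(p$x, p$y))) < 2) next
    r <- rank_sum_test(scores_to_table(p$x), scores_to_table(p$y))
    ref <- suppressWarnings(
      stats::wilcox.test(p$x, p$y, exact = FALSE, correct = FALSE))
    expect_equal(r$p_two_sided, ref$p.value, tolerance = 1e-9)
    expect_equal(r$U_candidate, unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("exact mode and normal approximation agree for moderate samples", {
  # the exact null distribution is discrete, so individual tables can
  # deviate; the approximation must track the exact p on the bulk of
  # tables and almost always reach the same significance call
  set.seed(45)
  dev_ok <- logical(200)
  call_ok <- logical(200)
  for (i in 1:200) {
    n1 <- sample(4:10, 1)
    n2 <- sample(4:(14 - n1), 1)
    x <- sample(0:5, n1, replace = TRUE)
    y <- sample(0:5, n2, replace = TRUE)
    a <- scores_to_table(x)
    b <- scores_to_table(y)
    pe <- rank_sum_test(a, b, method = "exact_permutation")$p_two_sided
    pn <- rank_sum_test(a, b)$p_two_sided
    dev_ok[i] <- abs(pe - pn) <= 0.12
    call_ok[i] <- (pe < 0.05) == (pn < 0.05)
  }
  expect_gte(mean(dev_ok), 0.9)
  expect_gte(mean(call_ok), 0.9)
})

test_that("the brute-force oracle matches its hand-derived cases", {
  expect_equal(exact_oracle_p(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(exact_oracle_p(2, 2), 1)
  # {5} vs {0,0,0}: with half-credit ties the three candidate-zero
  # assignments have U = 1 (|U - 1.5| = 0.5), so only the observed
  # assignment is as extreme: p = 1/4
  expect_equal(exact_oracle_p(5, c(0, 0, 0)), 1 / 4, tolerance = 1e-12)
  expect_error(exact_oracle_p(rep(1, 15), rep(2, 10)), "Monte Carlo")
  expect_error(exact_oracle_p(numeric(0), 1), "empty group")
})
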