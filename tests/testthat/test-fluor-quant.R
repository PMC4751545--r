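make_image <- function(dapi, ..., image_id = "img", group = "g") {
  chromosome_image(c(list(dapi = dapi), list(...)), image_id, group)
}

square_mask <- function(n = 32, from = 9, to = 24) {
  px <- matrix(FALSE, n, n)
  px[from:to, from:to] <- TRUE
  chromosome_mask(px, "file")
}

test_that("identical antibody and DAPI channels give ratio 1", {
  d <- matrix(runif(32 * 32), 32, 32)
  img <- make_image(d, ab = d)
  r <- quantify_ratio(img, square_mask(), background_mode = "none")
  expect_equal(unname(r$ratios["ab"]), 1)
})

test_that("ratio is linear in the antibody channel", {
  set.seed(2)
  d <- matrix(runif(32 * 32, 0.2, 1), 32, 32)
  img <- make_image(d, ab = 0.5 * d)
  r <- quantify_ratio(img, square_mask(), background_mode = "none")
  expect_equal(unname(r$ratios["ab"]), 0.5, tolerance = 1e-12)
  # scale invariance: c times the channel means c times the ratio
  img3 <- make_image(d, ab = 3 * 0.5 * d)
  r3 <- quantify_ratio(img3, square_mask(), background_mode = "none")
  expect_equal(unname(r3$ratios["ab"]), 3 * unname(r$ratios["ab"]),
               tolerance = 1e-12)
})

test_that("off-mask pixels never affect the ratio", {
  set.seed(3)
  d <- matrix(runif(32 * 32, 0.2, 1), 32, 32)
  a <- matrix(runif(32 * 32, 0, 0.8), 32, 32)
  msk <- square_mask()
  img1 <- make_image(d, ab = a)
  a2 <- a
  a2[!msk$pixels] <- a2[!msk$pixels] + 0.15 # speckle outside the mask
  img2 <- make_image(d, ab = a2)
  r1 <- quantify_ratio(img1, msk, background_mode = "none")
  r2 <- quantify_ratio(img2, msk, background_mode = "none")
  expect_equal(r1$ratios, r2$ratios, tolerance = 1e-12)
})

test_that("zero masked DAPI is refused", {
  d <- matrix(0, 32, 32)
  d[1, 1] <- 1 # variance present, but nothing under the mask
  img <- make_image(d, ab = matrix(1, 32, 32))
  expect_error(quantify_ratio(img, square_mask(), background_mode = "none"),
               "zero denominator")
})

test_that("segmentation recovers a noiseless square exactly", {
  d <- matrix(0, 48, 48)
  d[11:30, 11:30] <- 1
  m <- segment_chromosomes(d, sigma = 0, min_area = 10)
  expect_equal(m$pixels, d > 0)
  expect_equal(m$provenance, "auto")
})

test_that("blank rasters are rejected by segmentation", {
  expect_error(segment_chromosomes(matrix(0, 64, 64)), "no chromosome signal")
  expect_error(segment_chromosomes(matrix(0.7, 64, 64)),
               "no chromosome signal")
})

test_that("batch quantification skips failing images without aborting", {
  cfg <- spread_sim_config()
  batch <- simulate_polytene_batch(cfg, c(g = 1), n_per_group = 3, seed = 3)
  imgs <- lapply(batch, function(s) s$image)
  blank <- chromosome_image(list(dapi = matrix(0, 128, 128),
                                 ab = matrix(0, 128, 128)), "blank", "g")
  res <- suppressMessages(batch_quantify(c(imgs, list(blank))))
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "skipped")$image_id, "blank")
  expect_error(batch_quantify(list()), "empty batch")
  # determinism: the same image quantifies identically
  res2 <- batch_quantify(list(imgs[[1]], imgs[[1]]))
  expect_equal(res2$ratio[1], res2$ratio[2])
})

test_that("file masks reproduce the manual-mask contract in batch mode", {
  cfg <- spread_sim_config()
  batch <- simulate_polytene_batch(cfg, c(g = 1), n_per_group = 2, seed = 9)
  imgs <- lapply(batch, function(s) s$image)
  masks <- lapply(batch, function(s) s$truth_mask)
  names(masks) <- vapply(imgs, function(i) i$image_id, character(1))
  res <- batch_quantify(imgs, masks = masks)
  expect_equal(res$mask_area,
               vapply(batch, function(s) sum(s$truth_mask$pixels), numeric(1)))
})

test_that("per-slide aggregation averages images within a slide", {
  df <- data.frame(
    image_id = sprintf("i%d", 1:6),
    group = rep(c("ctrl", "kd"), each = 3),
    slide = c("s1", "s1", "s2", "s3", "s3", "s4"),
    channel = "ab",
    ratio = c(1.0, 1.2, 0.8, 0.5, 0.7, 0.6),
    stringsAsFactors = FALSE)
  agg <- aggregate_by_slide(df)
  expect_equal(nrow(agg), 4)
  expect_equal(agg$ratio[agg$slide == "s1"], 1.1)
  expect_equal(agg$n_images[agg$slide == "s3"], 2)
  df$slide <- ""
  expect_error(aggregate_by_slide(df), "slide labels")
})

test_that("compare_groups matches a hand-computed pooled t-test", {
  ctrl <- c(1.0, 1.1, 0.9)
  test <- c(2.0, 2.1, 1.9)
  cmp <- compare_groups(ctrl, test)
  expect_equal(cmp$percent_change, 100)
  # closed form: equal n and variance, pooled sd = 0.1
  sp <- sqrt((var(ctrl) + var(test)) / 2)
  t_hand <- (mean(test) - mean(ctrl)) / (sp * sqrt(2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_two_sided, p_hand, tolerance = 1e-12)
})

test_that("compare_groups percent-change phrasing matches a 36% reduction", {
  cmp <- compare_groups(c(1, 1, 1, 1), c(0.64, 0.64, 0.64, 0.64))
  expect_equal(cmp$percent_change, -36)
})

test_that("identical groups give the null comparison", {
  cmp <- compare_groups(c(1, 1.2), c(1, 1.2))
  expect_equal(cmp$percent_change, 0)
  expect_equal(cmp$p_two_sided, 1, tolerance = 1e-12)
  # constant equal groups are defined, not an error
  cmp2 <- compare_groups(c(1, 1), c(1, 1))
  expect_equal(cmp2$t_statistic, 0)
  expect_equal(cmp2$p_two_sided, 1)
})

test_that("compare_groups sign flips under swap and p is unchanged", {
  set.seed(5)
  a <- runif(8, 0.8, 1.2)
  b <- runif(8, 0.4, 0.8)
  c1 <- compare_groups(a, b)
  c2 <- compare_groups(b, a)
  expect_equal(sign(c1$percent_change), -sign(c2$percent_change))
  expect_equal(c1$p_two_sided, c2$p_two_sided, tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("colocalization is 1 for identical channels, 0 for disjoint", {
  set.seed(6)
  base <- matrix(runif(40 * 40, 0, 0.2), 40, 40)
  base[10:15, 10:30] <- 1
  img <- make_image(matrix(1, 40, 40), a = base, b = base)
  msk <- chromosome_mask(matrix(TRUE, 40, 40), "file")
  co <- colocalization(img, msk, "a", "b")
  expect_equal(co$frac_a_in_b, 1)
  expect_equal(co$frac_b_in_a, 1)

  b2 <- matrix(runif(40 * 40, 0, 0.2), 40, 40)
  b2[25:30, 10:30] <- 1
  img2 <- make_image(matrix(1, 40, 40), a = base, b = b2)
  co2 <- colocalization(img2, msk, "a", "b")
  expect_equal(co2$frac_a_in_b, 0)
  expect_equal(co2$frac_b_in_a, 0)
  expect_equal(co2$frac_a_only, 1)
})

test_that("an empty channel yields zero overlap with a warning", {
  img <- make_image(matrix(1, 40, 40),
                    a = matrix(0, 40, 40),
                    b = matrix(runif(1600), 40, 40))
  msk <- chromosome_mask(matrix(TRUE, 40, 40), "file")
  expect_warning(co <- colocalization(img, msk, "a", "b"), "no positive")
  expect_equal(co$frac_a_in_b, 0)
})
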