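#' Multi-channel chromosome spread image
#'
#' Container for one chromosome-spread acquisition: up to three co-registered
#' grayscale channels of identical shape. The first channel is the DAPI (DNA)
#' reference by convention; remaining channels are antibody signals.
#'
#' @param channels named list of 1-3 numeric matrices (finite, nonnegative),
#'   all the same dimension; first entry is DAPI.
#' @param image_id identifier used in batch outputs.
#' @param group group/genotype label for downstream comparison.
#' @param slide optional slide (biological replicate) label, for per-slide
#'   aggregation before group comparison.
#' @return object of class `chromosome_image`.
#' @export
chromosome_image <- function(channels, image_id = "img", group = "",
                             slide = "") {
  stopifnot(is.list(channels), length(channels) >= 1, length(channels) <= 3)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("channels must be named (first = DAPI)", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m), logical(1)))) {
    stop("each channel must be a 2-D numeric matrix", call. = FALSE)
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must share one shape", call. = FALSE)
  }
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("channel %s has non-finite or negative intensities",
                   dQuote(nm)), call. = FALSE)
    }
  }
  structure(list(channels = channels, image_id = image_id, group = group,
                 slide = slide),
            class = "chromosome_image")
}

#' @export
print.chromosome_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<chromosome_image> %s (%s) %dx%d channels: %s\n",
              x$image_id, x$group, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Chromosome mask
#'
#' @param pixels logical matrix, TRUE on chromosome.
#' @param provenance `"auto"` (segmented), `"file"` (user-supplied) or
#'   `"truth"` (simulator ground truth).
#' @return object of class `chromosome_mask`.
#' @export
chromosome_mask <- function(pixels, provenance = c("auto", "file", "truth")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), is.logical(pixels))
  if (!any(pixels)) {
    stop("mask has no chromosome pixels", call. = FALSE)
  }
  structure(list(pixels = pixels, provenance = provenance),
            class = "chromosome_mask")
}

#' Segment polytene chromosomes from a DAPI channel
#'
#' Automates the chromosome mask: Gaussian smoothing, a global Otsu
#' threshold, removal of small connected components, and hole filling. A
#' user-drawn mask file (see [read_mask()]) can be used instead wherever a
#' mask is accepted, reproducing the original manual-mask workflow.
#'
#' @param dapi numeric matrix of DAPI intensities.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param min_area smallest connected component kept, in pixels.
#' @param threshold `"otsu"` or a numeric threshold on the smoothed,
#'   \[0, 1\]-normalized image.
#' @param fill_holes fill enclosed background holes in the mask.
#' @return a [chromosome_mask] with provenance `"auto"`.
#' @export
segment_chromosomes <- function(dapi, sigma = 1, min_area = 50,
                                threshold = "otsu", fill_holes = TRUE) {
  stopifnot(is.matrix(dapi))
  if (any(!is.finite(dapi))) stop("non-finite DAPI values", call. = FALSE)
  rng <- range(dapi)
  if (diff(rng) <= 0) {
    stop("no chromosome signal: DAPI channel has zero variance",
         call. = FALSE)
  }
  norm <- (dapi - rng[1]) / diff(rng)
  img <- EBImage::Image(norm)
  sm <- if (sigma > 0) EBImage::gblur(img, sigma = sigma) else img
  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    as.numeric(threshold)
  }
  bw <- EBImage::imageData(sm) > th
  if (min_area > 1 && any(bw)) {
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= min_area])
    bw <- matrix(EBImage::imageData(lab) %in% keep, nrow(bw), ncol(bw))
  }
  if (fill_holes && any(bw)) {
    filled <- EBImage::fillHull(EBImage::Image(bw * 1))
    bw <- EBImage::imageData(filled) > 0
  }
  if (!any(bw)) {
    stop("no chromosome signal: segmentation produced an empty mask",
         call. = FALSE)
  }
  chromosome_mask(bw, "auto")
}

#' Per-channel antibody/DAPI intensity ratio within the chromosome mask
#'
#' For each non-DAPI channel, computes the ratio of background-subtracted
#' masked signal to background-subtracted masked DAPI:
#' `sum(max(ch - b_ch, 0)) / sum(max(DAPI - b_DAPI, 0))` over mask pixels,
#' where `b` is the per-channel background estimate. Using sums over one
#' common mask makes the ratio insensitive to mask area.
#'
#' @param image a [chromosome_image].
#' @param mask a [chromosome_mask] of matching shape.
#' @param background_mode `"median_offmask"` (median of off-mask pixels,
#'   per channel) or `"none"` (no subtraction, matching a workflow in which
#'   off-chromosome signal is simply excluded by the mask).
#' @return object of class `fluor_quant_result`: `image_id`, `group`,
#'   `ratios` (named, one per non-DAPI channel), `mask_area`.
#' @export
quantify_ratio <- function(image, mask,
                           background_mode = c("median_offmask", "none")) {
  background_mode <- match.arg(background_mode)
  stopifnot(inherits(image, "chromosome_image"),
            inherits(mask, "chromosome_mask"))
  m <- mask$pixels
  if (!identical(dim(m), dim(image$channels[[1]]))) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  masked_sum <- function(ch) {
    b <- if (background_mode == "median_offmask" && any(!m)) {
      stats::median(ch[!m])
    } else 0
    sum(pmax(ch[m] - b, 0))
  }
  dapi_name <- names(image$channels)[1]
  dapi_sum <- masked_sum(image$channels[[1]])
  if (dapi_sum <= 0) {
    stop("zero denominator: no masked DAPI signal above background",
         call. = FALSE)
  }
  others <- setdiff(names(image$channels), dapi_name)
  ratios <- vapply(others, function(nm) {
    masked_sum(image$channels[[nm]]) / dapi_sum
  }, numeric(1))
  structure(
    list(image_id = image$image_id, group = image$group,
         ratios = ratios, mask_area = sum(m)),
    class = "fluor_quant_result"
  )
}

#' @export
print.fluor_quant_result <- function(x, ...) {
  cat(sprintf("<fluor_quant_result> %s (%s) mask_area=%d\n  %s\n",
              x$image_id, x$group, x$mask_area,
              paste(sprintf("%s/DAPI = %.4f", names(x$ratios), x$ratios),
                    collapse = "  ")))
  invisible(x)
}

#' Quantify a batch of chromosome images
#'
#' Runs [segment_chromosomes()] (unless a mask is supplied per image) and
#' [quantify_ratio()] over a batch. Per-image failures (blank images, empty
#' masks, zero DAPI) are recorded and skipped rather than aborting the batch.
#'
#' @param images list of [chromosome_image] objects.
#' @param masks optional named list of [chromosome_mask] objects keyed by
#'   `image_id`; images without an entry are segmented automatically.
#' @param background_mode passed to [quantify_ratio()].
#' @param sigma,min_area passed to [segment_chromosomes()].
#' @return data frame with one row per image and channel: `image_id`,
#'   `group`, `channel`, `ratio`, `mask_area`. Skipped images are listed in
#'   `attr(, "skipped")` (`image_id`, `reason`).
#' @export
batch_quantify <- function(images, masks = NULL,
                           background_mode = "median_offmask",
                           sigma = 1, min_area = 50) {
  if (length(images) == 0) stop("empty batch", call. = FALSE)
  rows <- list()
  skipped <- list()
  for (img in images) {
    res <- tryCatch({
      msk <- if (!is.null(masks) && img$image_id %in% names(masks)) {
        masks[[img$image_id]]
      } else {
        segment_chromosomes(img$channels[[1]], sigma = sigma,
                            min_area = min_area)
      }
      quantify_ratio(img, msk, background_mode = background_mode)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("skipping %s: %s", img$image_id, conditionMessage(res)))
      skipped[[length(skipped) + 1L]] <- data.frame(
        image_id = img$image_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = res$image_id, group = res$group,
        slide = if (is.null(img$slide)) "" else img$slide,
        channel = names(res$ratios), ratio = unname(res$ratios),
        mask_area = res$mask_area, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), group = character(0),
               slide = character(0), channel = character(0),
               ratio = numeric(0), mask_area = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(image_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  out
}

#' Aggregate per-image ratios to per-slide means
#'
#' When several spreads are imaged per slide (biological replicate), the
#' slide rather than the image can be taken as the replication unit; this
#' collapses a [batch_quantify()] result to one mean ratio per slide,
#' channel and group.
#'
#' @param ratios data frame from [batch_quantify()] with a nonempty `slide`
#'   column.
#' @return data frame with columns `group`, `slide`, `channel`, `ratio`
#'   (mean over the slide's images) and `n_images`.
#' @export
aggregate_by_slide <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("group", "slide", "channel", "ratio") %in% names(ratios)))
  if (any(!nzchar(ratios$slide))) {
    stop("slide labels are missing; supply a slide column to aggregate by",
         call. = FALSE)
  }
  agg <- stats::aggregate(ratio ~ group + slide + channel, data = ratios,
                          FUN = mean)
  cnt <- stats::aggregate(ratio ~ group + slide + channel, data = ratios,
                          FUN = length)
  agg$n_images <- cnt$ratio
  agg
}

#' Compare per-image ratios between two groups
#'
#' Two-sample two-sided t-test on per-image (or per-slide) fluorescence
#' ratios, with the percent change of the test group relative to the control
#' mean. Student's pooled-variance test is the default; Welch is available.
#'
#' @param control,test numeric vectors of ratios, at least 2 each.
#' @param var_equal pooled-variance Student's t (default) or Welch if FALSE.
#' @return object of class `group_comparison`: `mean_control`, `mean_test`,
#'   `sd_control`, `sd_test`, `n_control`, `n_test`, `percent_change`,
#'   `t_statistic`, `p_two_sided`.
#' @examples
#' compare_groups(c(1.0, 1.1, 0.9), c(0.6, 0.7, 0.62))
#' @export
compare_groups <- function(control, test, var_equal = TRUE) {
  control <- as.numeric(control)
  test <- as.numeric(test)
  if (length(control) < 2 || length(test) < 2) {
    stop("need at least 2 ratios per group for a t-test", call. = FALSE)
  }
  mc <- mean(control)
  mt <- mean(test)
  if (mc == 0) stop("control mean is zero; percent change undefined",
                    call. = FALSE)
  percent_change <- 100 * (mt - mc) / mc
  if (stats::sd(control) == 0 && stats::sd(test) == 0) {
    t_stat <- if (mt == mc) 0 else sign(mt - mc) * Inf
    p <- if (mt == mc) 1 else 0
  } else {
    tt <- stats::t.test(test, control, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(mean_control = mc, mean_test = mt,
         sd_control = stats::sd(control), sd_test = stats::sd(test),
         n_control = length(control), n_test = length(test),
         percent_change = percent_change, t_statistic = t_stat,
         p_two_sided = p),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> control %.4f (n=%d), test %.4f (n=%d)\n  change %+.1f%%, t=%.3f, p=%.3g\n",
    x$mean_control, x$n_control, x$mean_test, x$n_test,
    x$percent_change, x$t_statistic, x$p_two_sided
  ))
  invisible(x)
}

# Otsu threshold over an arbitrary set of values (normalized internally).
otsu_threshold_values <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) return(Inf) # constant: nothing is "positive"
  norm <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)), range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Two-channel overlap fractions within the chromosome mask
#'
#' Binarizes two channels inside the mask (per-channel Otsu threshold over
#' masked values by default) and reports what fraction of each channel's
#' positive pixels are also positive in the other, plus each channel's
#' exclusive fraction. Symmetric overlap near 1 indicates colocalization;
#' sites positive in only one channel show up in the exclusive fractions.
#'
#' @param image a [chromosome_image] with both channels present.
#' @param mask a [chromosome_mask].
#' @param ch_a,ch_b channel names to compare.
#' @param thresholds optional numeric length-2 vector of absolute thresholds
#'   for `ch_a` and `ch_b`, overriding Otsu.
#' @return list: `frac_a_in_b`, `frac_b_in_a`, `frac_a_only`, `frac_b_only`,
#'   `n_a`, `n_b` (positive pixel counts).
#' @export
colocalization <- function(image, mask, ch_a, ch_b, thresholds = NULL) {
  stopifnot(inherits(image, "chromosome_image"),
            inherits(mask, "chromosome_mask"))
  if (!all(c(ch_a, ch_b) %in% names(image$channels))) {
    stop("both channels must be present in the image", call. = FALSE)
  }
  m <- mask$pixels
  va <- image$channels[[ch_a]][m]
  vb <- image$channels[[ch_b]][m]
  th <- if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2)
    as.numeric(thresholds)
  } else {
    c(otsu_threshold_values(va), otsu_threshold_values(vb))
  }
  pos_a <- va > th[1]
  pos_b <- vb > th[2]
  n_a <- sum(pos_a)
  n_b <- sum(pos_b)
  if (n_a == 0 || n_b == 0) {
    warning("a channel has no positive pixels after thresholding; ",
            "overlap reported as 0", call. = FALSE)
  }
  frac_a_in_b <- if (n_a > 0) sum(pos_a & pos_b) / n_a else 0
  frac_b_in_a <- if (n_b > 0) sum(pos_a & pos_b) / n_b else 0
  list(frac_a_in_b = frac_a_in_b, frac_b_in_a = frac_b_in_a,
       frac_a_only = 1 - frac_a_in_b, frac_b_only = 1 - frac_b_in_a,
       n_a = n_a, n_b = n_b)
}
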