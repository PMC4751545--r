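#' Configuration for the polytene-spread simulator
#'
#' Defines the geometry and photometry of simulated chromosome spreads:
#' several smooth curvilinear arms radiating from a chromocenter-like origin,
#' a banded DAPI intensity profile along each arm, antibody channels that
#' light a subset of the bands, off-chromosome nonspecific speckle, and
#' acquisition noise. All intensities are on a \[0, 1\] scale.
#'
#' @param shape image dimensions in pixels (rows, cols), at least 64x64.
#' @param n_arms number of chromosome arms.
#' @param arm_length arm path length in pixels (one path point per pixel
#'   step).
#' @param arm_halfwidth arm half-width in pixels; the ground-truth mask is
#'   exactly the pixels within this distance of an arm path.
#' @param bands_per_arm DAPI bands per arm, placed on a jittered regular
#'   grid along the arc.
#' @param band_jitter band position jitter as a fraction of band spacing.
#' @param band_sd band profile sd along the arc, pixels.
#' @param dapi_interband baseline on-chromosome DAPI level between bands.
#' @param dapi_band_amp DAPI band amplitude above the interband baseline.
#' @param channels named list of antibody channels; each a list with
#'   `band_fraction` (fraction of bands carrying signal) and `scale` (peak
#'   intensity at a band, before any group multiplier).
#' @param shared_band_fraction for exactly two antibody channels, the
#'   fraction of each channel's bands shared with the other (colocalization
#'   ground truth); `NULL` draws each channel's bands independently.
#' @param speckle_rate expected number of off-chromosome nonspecific speckles
#'   per antibody channel.
#' @param speckle_amp,speckle_sd speckle peak intensity and radius sd.
#' @param noise_sd additive Gaussian noise sd per pixel.
#' @param poisson if TRUE, apply Poisson photon noise (at `photons` counts
#'   per unit intensity) before the Gaussian read noise.
#' @param photons photon count corresponding to intensity 1.0.
#' @return list of class `spread_sim_config`.
#' @export
spread_sim_config <- function(shape = c(128, 128),
                              n_arms = 4,
                              arm_length = 45,
                              arm_halfwidth = 3.5,
                              bands_per_arm = 7,
                              band_jitter = 0.3,
                              band_sd = 1.6,
                              dapi_interband = 0.35,
                              dapi_band_amp = 0.6,
                              channels = list(
                                ab = list(band_fraction = 0.6, scale = 0.8)
                              ),
                              shared_band_fraction = NULL,
                              speckle_rate = 15,
                              speckle_amp = 0.5,
                              speckle_sd = 1.2,
                              noise_sd = 0.02,
                              poisson = FALSE,
                              photons = 200) {
  stopifnot(length(shape) == 2, all(shape >= 64), n_arms >= 1,
            arm_length >= 10, arm_halfwidth > 0, bands_per_arm >= 1)
  if (!is.null(shared_band_fraction)) {
    stopifnot(length(channels) == 2,
              shared_band_fraction >= 0, shared_band_fraction <= 1)
  }
  for (ch in channels) {
    stopifnot(ch$band_fraction >= 0, ch$band_fraction <= 1, ch$scale >= 0)
  }
  structure(as.list(environment()), class = "spread_sim_config")
}

# Random smooth arm path from a start point: unit steps with a slowly
# drifting heading. Returns n x 2 matrix of (row, col) positions or NULL if
# the path leaves the allowed margin.
arm_path <- function(start, heading, n_steps, shape, margin) {
  curv <- stats::rnorm(n_steps, 0, 0.08)
  h <- heading + cumsum(curv)
  pts <- cbind(start[1] + cumsum(sin(h)), start[2] + cumsum(cos(h)))
  lo <- 1 + margin
  if (any(pts[, 1] < lo | pts[, 1] > shape[1] - margin |
          pts[, 2] < lo | pts[, 2] > shape[2] - margin)) {
    return(NULL)
  }
  pts
}

# Pick band subsets for each antibody channel, optionally forcing a shared
# fraction between exactly two channels.
pick_band_subsets <- function(config, n_bands) {
  chans <- config$channels
  ks <- vapply(chans, function(ch) round(ch$band_fraction * n_bands),
               numeric(1))
  if (!is.null(config$shared_band_fraction) && length(chans) == 2) {
    k <- ks[1]
    n_shared <- round(config$shared_band_fraction * min(ks))
    shared <- sample.int(n_bands, n_shared)
    rest <- setdiff(seq_len(n_bands), shared)
    extra1 <- sample(rest, min(ks[1] - n_shared, length(rest)))
    rest2 <- setdiff(rest, extra1)
    extra2 <- sample(rest2, min(ks[2] - n_shared, length(rest2)))
    out <- list(sort(c(shared, extra1)), sort(c(shared, extra2)))
  } else {
    out <- lapply(ks, function(k) sort(sample.int(n_bands, k)))
  }
  names(out) <- names(chans)
  out
}

# Soft arm-edge profile: ~1 inside the arm, 0.5 at the half-width boundary,
# ~0 one pixel beyond.
edge_profile <- function(d, halfwidth) stats::plogis(4 * (halfwidth - d))

#' Simulate one polytene chromosome spread
#'
#' Draws random arm geometry and band positions from the current RNG state
#' and renders the DAPI and antibody channels. Antibody intensities are
#' multiplied by `multiplier`, the knob used to emulate knockdown-induced
#' signal reduction between groups.
#'
#' @param config a [spread_sim_config].
#' @param multiplier group scale multiplier applied to every antibody
#'   channel (1 = control).
#' @param image_id,group labels stamped on the result.
#' @return list of class `synthetic_spread`: `image` (a
#'   [chromosome_image]), `truth_mask` (a [chromosome_mask], provenance
#'   `"truth"`), `band_arc` (arc positions of all bands), `band_subsets`
#'   (per-channel band indices), `scales` (effective per-channel scale),
#'   `multiplier`.
#' @export
simulate_polytene_spread <- function(config, multiplier = 1,
                                     image_id = "spread", group = "") {
  stopifnot(inherits(config, "spread_sim_config"))
  shape <- config$shape
  hw <- config$arm_halfwidth
  margin <- ceiling(hw) + 3
  center <- shape / 2

  # arm geometry: headings fanned around the chromocenter, with retries if a
  # path escapes the frame
  paths <- vector("list", config$n_arms)
  base_angles <- seq(0, 2 * pi, length.out = config$n_arms + 1)[-1]
  for (a in seq_len(config$n_arms)) {
    p <- NULL
    for (try in 1:50) {
      start <- center + stats::rnorm(2, 0, 2)
      heading <- base_angles[a] + stats::rnorm(1, 0, 0.3)
      p <- arm_path(start, heading, config$arm_length, shape, margin)
      if (!is.null(p)) break
    }
    if (is.null(p)) {
      stop("arm path does not fit the image shape after 50 retries; ",
           "increase shape or reduce arm_length", call. = FALSE)
    }
    paths[[a]] <- p
  }
  pts <- do.call(rbind, paths)
  n_pts <- nrow(pts)
  arc <- unlist(lapply(paths, function(p) seq_len(nrow(p)))) # arc pos per arm

  # band centers: jittered regular grid along each arm's arc
  spacing <- config$arm_length / config$bands_per_arm
  band_arm <- rep(seq_len(config$n_arms), each = config$bands_per_arm)
  band_arc <- rep((seq_len(config$bands_per_arm) - 0.5) * spacing,
                  config$n_arms) +
    stats::runif(config$n_arms * config$bands_per_arm,
                 -0.5, 0.5) * config$band_jitter * spacing
  n_bands <- length(band_arc)
  subsets <- pick_band_subsets(config, n_bands)

  # per-path-point band profiles (Gaussian bumps along the arc, same arm)
  pt_arm <- rep(seq_len(config$n_arms), vapply(paths, nrow, numeric(1)))
  gauss_profile <- function(band_idx) {
    prof <- numeric(n_pts)
    for (b in band_idx) {
      same <- pt_arm == band_arm[b]
      prof[same] <- prof[same] +
        exp(-(arc[same] - band_arc[b])^2 / (2 * config$band_sd^2))
    }
    pmin(prof, 1)
  }
  dapi_factor <- pmin(config$dapi_interband +
                        config$dapi_band_amp * gauss_profile(seq_len(n_bands)),
                      1)
  ab_factor <- lapply(names(config$channels), function(nm) {
    config$channels[[nm]]$scale * multiplier * gauss_profile(subsets[[nm]])
  })
  names(ab_factor) <- names(config$channels)

  # rasterize: nearest path point per pixel within a local window
  D <- matrix(Inf, shape[1], shape[2])
  NEAR <- matrix(NA_integer_, shape[1], shape[2])
  win <- ceiling(hw) + 3
  for (i in seq_len(n_pts)) {
    r0 <- max(1, floor(pts[i, 1]) - win); r1 <- min(shape[1], ceiling(pts[i, 1]) + win)
    c0 <- max(1, floor(pts[i, 2]) - win); c1 <- min(shape[2], ceiling(pts[i, 2]) + win)
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - pts[i, 1])^2, (cc - pts[i, 2])^2, "+"))
    upd <- d < D[rr, cc]
    D[rr, cc][upd] <- d[upd]
    NEAR[rr, cc][upd] <- i
  }
  truth <- D <= hw
  edge <- edge_profile(D, hw)
  edge[is.infinite(D)] <- 0
  near_ok <- !is.na(NEAR)

  render <- function(factor_per_pt) {
    img <- matrix(0, shape[1], shape[2])
    img[near_ok] <- edge[near_ok] * factor_per_pt[NEAR[near_ok]]
    img
  }
  dapi <- render(dapi_factor)
  abs_ <- lapply(ab_factor, render)

  # off-chromosome nonspecific speckle on antibody channels
  for (nm in names(abs_)) {
    n_spk <- stats::rpois(1, config$speckle_rate)
    if (n_spk > 0) {
      srow <- stats::runif(n_spk, 1, shape[1])
      scol <- stats::runif(n_spk, 1, shape[2])
      keep <- D[cbind(pmin(round(srow), shape[1]),
                      pmin(round(scol), shape[2]))] > hw + 2
      for (k in which(keep)) {
        r0 <- max(1, round(srow[k]) - 4); r1 <- min(shape[1], round(srow[k]) + 4)
        c0 <- max(1, round(scol[k]) - 4); c1 <- min(shape[2], round(scol[k]) + 4)
        rr <- r0:r1; cc <- c0:c1
        d2 <- outer((rr - srow[k])^2, (cc - scol[k])^2, "+")
        abs_[[nm]][rr, cc] <- abs_[[nm]][rr, cc] +
          config$speckle_amp * exp(-d2 / (2 * config$speckle_sd^2))
      }
    }
  }

  add_noise <- function(img) {
    if (config$poisson) {
      img <- stats::rpois(length(img), img * config$photons) / config$photons
      img <- matrix(img, shape[1], shape[2])
    }
    if (config$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, config$noise_sd)
    }
    pmax(img, 0)
  }
  channels <- c(list(dapi = add_noise(dapi)),
                lapply(abs_, add_noise))
  structure(
    list(
      image = chromosome_image(channels, image_id = image_id, group = group),
      truth_mask = chromosome_mask(truth, "truth"),
      band_arc = data.frame(arm = band_arm, arc = band_arc),
      band_subsets = subsets,
      scales = vapply(config$channels, function(ch) ch$scale * multiplier,
                      numeric(1)),
      multiplier = multiplier
    ),
    class = "synthetic_spread"
  )
}

#' Simulate a batch of spreads across groups
#'
#' @param config a [spread_sim_config].
#' @param groups named numeric vector of antibody scale multipliers, one per
#'   group (e.g. `c(control = 1, knockdown = 0.64)`).
#' @param n_per_group number of spreads per group; either a single value or
#'   one per group.
#' @param seed integer seed; the whole batch is reproducible from it.
#' @return list of `synthetic_spread` objects, grouped in `groups` order;
#'   image ids are `<group>_<i>`.
#' @examples
#' cfg <- spread_sim_config()
#' batch <- simulate_polytene_batch(cfg, c(control = 1, kd = 0.64),
#'                                  n_per_group = 2, seed = 1)
#' length(batch)
#' @export
simulate_polytene_batch <- function(config, groups, n_per_group, seed) {
  stopifnot(inherits(config, "spread_sim_config"),
            is.numeric(groups), !is.null(names(groups)),
            all(n_per_group >= 1))
  n_per_group <- rep(n_per_group, length.out = length(groups))
  set.seed(seed)
  out <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group[g])) {
      out[[length(out) + 1L]] <- simulate_polytene_spread(
        config, multiplier = groups[g],
        image_id = sprintf("%s_%02d", names(groups)[g], i),
        group = names(groups)[g])
    }
  }
  out
}
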