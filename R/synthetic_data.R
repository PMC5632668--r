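#' Synthetic 1/f texture image
#'
#' A grayscale stand-in for a natural photograph: Gaussian white noise
#' filtered to a `1/f^slope` amplitude spectrum (slope 1 approximates natural
#' image statistics; slope 0 is white noise), standardized and mapped to
#' strictly positive luminance `base * (1 + contrast * z)` with a small floor.
#'
#' @param seed RNG seed (mandatory: generation is fully deterministic).
#' @param width,height image size in pixels.
#' @param spectral_slope radial amplitude falls off as `1/f^slope`.
#' @param contrast luminance modulation depth around the base level.
#' @param base mean luminance (arbitrary linear units).
#' @param geometry optional [image_geometry()]; defaults to the standard
#'   18.6/481 deg-per-pixel scale.
#' @return A [luminance_image()].
#' @export
make_texture_image <- function(seed, width = 481L, height = 321L,
                               spectral_slope = 1, contrast = 0.2, base = 100,
                               geometry = NULL) {
  set.seed(seed)
  z <- matrix(stats::rnorm(height * width), height, width)
  fy <- ifelse(0:(height - 1) > height / 2, 0:(height - 1) - height,
               0:(height - 1)) / height
  fx <- ifelse(0:(width - 1) > width / 2, 0:(width - 1) - width,
               0:(width - 1)) / width
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- ifelse(fr > 0, fr^(-spectral_slope), 0)
  f <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / length(z)
  f <- (f - mean(f)) / stats::sd(f)
  vals <- pmax(base * (1 + contrast * f), 0.01 * base)
  if (is.null(geometry))
    geometry <- image_geometry(width, height, deg_per_px = 18.6 / 481)
  luminance_image(vals, geometry)
}

#' Synthetic multi-observer importance map
#'
#' Emulates averaged human label maps: a shared set of elliptical "object"
#' regions is drawn, and each of `n_observers` observers independently labels
#' each object with probability `label_prob`. The returned map is the mean of
#' the observers' binary maps, so its values are multiples of
#' `1/n_observers`. The individual binary maps are attached as the
#' `observer_maps` attribute.
#'
#' @param seed RNG seed.
#' @param width,height map size in pixels.
#' @param n_observers number of observers (default 5).
#' @param n_objects number of candidate object regions (0 gives an all-zero
#'   map).
#' @param label_prob probability that an observer labels a given object.
#' @param radius_range min/max object semi-axis in pixels.
#' @return An [importance_map()].
#' @export
make_importance_map <- function(seed, width = 481L, height = 321L,
                                n_observers = 5L, n_objects = 4L,
                                label_prob = 0.6, radius_range = c(20, 60)) {
  stopifnot(n_observers >= 1L)
  set.seed(seed)
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), width), height, width)
  objects <- replicate(n_objects, {
    cx <- stats::runif(1, 0, width - 1); cy <- stats::runif(1, 0, height - 1)
    rx <- stats::runif(1, radius_range[1], radius_range[2])
    ry <- stats::runif(1, radius_range[1], radius_range[2])
    ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  }, simplify = FALSE)
  observer_maps <- lapply(seq_len(n_observers), function(o) {
    m <- matrix(FALSE, height, width)
    if (n_objects > 0)
      for (j in seq_len(n_objects))
        if (stats::runif(1) < label_prob) m <- m | objects[[j]]
    m
  })
  avg <- Reduce(`+`, lapply(observer_maps, `+`, 0)) / n_observers
  out <- importance_map(avg, n_observers = n_observers)
  attr(out, "observer_maps") <- observer_maps
  out
}

#' Apply a programmatic manipulation to an image
#'
#' Alters a circular region of the image with a controllable magnitude and
#' returns both the manipulated image and the exact change mask. Modes:
#' `"contrast_scale"` multiplies luminance deviations from the region mean by
#' `2^magnitude` (0 leaves the image untouched); `"texture_replace"` blends
#' the region toward an independent texture with weight `min(magnitude, 1)`;
#' `"patch_delete"` blends the region toward its mean luminance (weight
#' `min(magnitude, 1)`), deleting structure.
#'
#' @param img a [luminance_image()].
#' @param mode manipulation mode (see Details).
#' @param magnitude manipulation strength; 0 means no change.
#' @param center_px `(x, y)` region center in 0-based pixels (random within
#'   bounds when `NULL`).
#' @param radius_px region radius in pixels.
#' @param seed RNG seed (used by `texture_replace` and random placement).
#' @param ecc_min_deg minimum eccentricity of the region center; placement
#'   respecting the central exclusion. An explicit `center_px` violating it
#'   is an error when `ecc_min_deg > 0`.
#' @return List with `image` (manipulated [luminance_image()]) and `region`
#'   (a [change_region()], or `NULL` when `magnitude = 0`).
#' @export
apply_manipulation <- function(img, mode = c("contrast_scale", "texture_replace",
                                             "patch_delete"),
                               magnitude = 1, center_px = NULL, radius_px = 20,
                               seed = 1L, ecc_min_deg = 0) {
  mode <- match.arg(mode)
  img <- as_luminance_image(img)
  geom <- img$geometry
  set.seed(seed)
  if (is.null(center_px)) {
    ecc_min_px <- degrees_to_pixels(ecc_min_deg, geom)
    for (try in 1:1000) {
      cx <- stats::runif(1, radius_px, geom$width_px - 1 - radius_px)
      cy <- stats::runif(1, radius_px, geom$height_px - 1 - radius_px)
      ecc <- sqrt((cx - geom$center_px[["x"]])^2 + (cy - geom$center_px[["y"]])^2)
      if (ecc >= ecc_min_px + radius_px) break
      if (try == 1000) stop("could not place region outside the exclusion zone",
                            call. = FALSE)
    }
    center_px <- c(cx, cy)
  } else {
    cx <- center_px[[1]]; cy <- center_px[[2]]
    if (cx - radius_px < 0 || cy - radius_px < 0 ||
        cx + radius_px > geom$width_px - 1 || cy + radius_px > geom$height_px - 1)
      stop("region extends outside the image bounds", call. = FALSE)
    if (ecc_min_deg > 0) {
      ecc <- sqrt((cx - geom$center_px[["x"]])^2 + (cy - geom$center_px[["y"]])^2)
      if (ecc < degrees_to_pixels(ecc_min_deg, geom) + radius_px)
        stop("region violates the central exclusion", call. = FALSE)
    }
  }
  xs <- matrix(rep(0:(geom$width_px - 1), each = geom$height_px),
               geom$height_px, geom$width_px)
  ys <- matrix(rep(0:(geom$height_px - 1), geom$width_px),
               geom$height_px, geom$width_px)
  mask <- (xs - center_px[[1]])^2 + (ys - center_px[[2]])^2 <= radius_px^2

  vals <- img$values
  if (magnitude != 0) {
    m <- mean(vals[mask])
    if (mode == "contrast_scale") {
      vals[mask] <- m + 2^magnitude * (vals[mask] - m)
    } else if (mode == "patch_delete") {
      w <- min(abs(magnitude), 1)
      vals[mask] <- (1 - w) * vals[mask] + w * m
    } else {
      w <- min(abs(magnitude), 1)
      s <- stats::sd(vals[mask]); if (s == 0) s <- 0.05 * m
      nz <- stats::rnorm(sum(mask))
      vals[mask] <- (1 - w) * vals[mask] + w * (m + 1.5 * s * nz)
    }
    vals <- pmax(vals, 0.01 * mean(img$values))
  }
  list(image = luminance_image(vals, geom),
       region = if (magnitude != 0) change_region(mask) else NULL)
}

#' Stimulus-pool generator configuration
#'
#' Defaults state the emulated world: 300 candidate manipulations over 100
#' source images on the standard 481 x 321 grid, the 19.4 px contrast-energy
#' window, the 1.6 degree central exclusion, and a target absolute
#' correlation below 0.2 between the achieved contrast-energy and
#' subjective-importance changes.
#'
#' @param n_pairs number of manipulations (image pairs).
#' @param n_sources number of distinct source images (pairs are dealt to
#'   sources round-robin).
#' @param width,height image size in pixels.
#' @param sigma_px contrast-energy window standard deviation.
#' @param ecc_min_deg central exclusion radius in degrees.
#' @param radius_range min/max manipulation radius in pixels.
#' @param magnitude_low,magnitude_high magnitude ranges for the low/high
#'   contrast-energy targeting arms.
#' @param decorrelation_target maximum tolerated `|cor(ce, si)|` before a
#'   warning.
#' @param seed RNG seed (mandatory).
#' @return A list of class `stimulus_gen_config`.
#' @export
stimulus_gen_config <- function(n_pairs = 300L, n_sources = 100L,
                                width = 481L, height = 321L, sigma_px = 19.4,
                                ecc_min_deg = 1.6, radius_range = c(15, 30),
                                magnitude_low = c(0.15, 0.45),
                                magnitude_high = c(0.9, 1.8),
                                decorrelation_target = 0.2, seed = 1L) {
  stopifnot(n_pairs >= 4L, n_sources >= 1L, width > 0L, height > 0L,
            !is.null(seed))
  structure(as.list(environment()), class = "stimulus_gen_config")
}

#' Generate a synthetic stimulus pool with known ground truth
#'
#' Builds `n_pairs` image-pair manipulations whose contrast-energy change and
#' subjective-importance change are near-independent: the SI level is driven
#' by placing the region on high- versus low-importance pixels, the CE level
#' by the manipulation magnitude, and the two targets are crossed
#' independently. Every region respects the central eccentricity exclusion.
#' Only the scores are kept in memory; any pair's images can be rebuilt
#' deterministically with [regenerate_pair()].
#'
#' @param cfg a [stimulus_gen_config()].
#' @return An object of class `stimulus_pool`: list with `scores`
#'   (`data.frame`: `pair_id`, `source_image_id`, `ce_change`, `si_change`,
#'   the balance covariates, and the per-pair generation parameters) and
#'   `config`.
#' @export
generate_stimulus_pool <- function(cfg = stimulus_gen_config()) {
  stopifnot(inherits(cfg, "stimulus_gen_config"))
  set.seed(cfg$seed)
  source_seeds <- sample.int(.Machine$integer.max, cfg$n_sources)
  pair_seeds <- sample.int(.Machine$integer.max, cfg$n_pairs)
  src_of <- ((seq_len(cfg$n_pairs) - 1L) %% cfg$n_sources) + 1L
  si_high <- seq_len(cfg$n_pairs) %% 2L == 0L
  ce_high <- (seq_len(cfg$n_pairs) %/% 2L) %% 2L == 0L
  spec <- window_spec(cfg$sigma_px)
  modes <- c("contrast_scale", "texture_replace", "patch_delete")

  rows <- vector("list", cfg$n_pairs)
  for (s in unique(src_of)) {
    img <- make_texture_image(source_seeds[s], cfg$width, cfg$height)
    imap <- make_importance_map(source_seeds[s] %% 1000000L + 7L,
                                cfg$width, cfg$height)
    for (j in which(src_of == s)) {
      p <- pair_params(cfg, pair_seeds[j], si_high[j], ce_high[j], imap,
                       img$geometry, modes)
      man <- apply_manipulation(img, mode = p$mode, magnitude = p$magnitude,
                                center_px = p$center, radius_px = p$radius,
                                seed = p$manip_seed,
                                ecc_min_deg = cfg$ecc_min_deg)
      cv <- region_covariates(img, man$image, man$region, spec, imap = imap)
      rows[[j]] <- cbind(
        data.frame(pair_id = sprintf("p%03d", j),
                   source_image_id = sprintf("s%03d", s)),
        cv,
        data.frame(mode = p$mode, magnitude = p$magnitude,
                   center_x = p$center[1], center_y = p$center[2],
                   radius_px = p$radius, manip_seed = p$manip_seed,
                   source_seed = source_seeds[s]))
    }
  }
  scores <- do.call(rbind, rows)
  r <- stats::cor(scores$ce_change, scores$si_change)
  if (abs(r) > cfg$decorrelation_target)
    warning(sprintf("ce/si decorrelation target missed: |r| = %.3f", abs(r)))
  structure(list(scores = scores, config = cfg, cor_ce_si = r),
            class = "stimulus_pool")
}

# internal: choose the placement and magnitude realizing one (SI, CE) target
pair_params <- function(cfg, seed, si_high, ce_high, imap, geom, modes) {
  set.seed(seed)
  radius <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
  mag_rng <- if (ce_high) cfg$magnitude_high else cfg$magnitude_low
  magnitude <- stats::runif(1, mag_rng[1], mag_rng[2])
  mode <- sample(modes, 1L)
  if (mode == "contrast_scale" && stats::runif(1) < 0.5)
    magnitude <- -magnitude
  ecc_min_px <- degrees_to_pixels(cfg$ecc_min_deg, geom)
  iv <- imap$values
  xs <- matrix(rep(0:(geom$width_px - 1), each = geom$height_px),
               geom$height_px, geom$width_px)
  ys <- matrix(rep(0:(geom$height_px - 1), geom$width_px),
               geom$height_px, geom$width_px)
  ecc <- sqrt((xs - geom$center_px[["x"]])^2 + (ys - geom$center_px[["y"]])^2)
  valid <- ecc >= ecc_min_px + radius &
    xs >= radius & xs <= geom$width_px - 1 - radius &
    ys >= radius & ys <= geom$height_px - 1 - radius
  target <- if (si_high) valid & iv >= 0.4 else valid & iv <= 0.1
  if (!any(target)) target <- valid
  w <- which(target)
  if (length(w) == 0L)
    stop("no admissible region placement for this geometry", call. = FALSE)
  pick <- if (length(w) == 1L) w else sample(w, 1L)
  list(center = c(xs[pick], ys[pick]), radius = radius, magnitude = magnitude,
       mode = mode, manip_seed = seed %% 1000000L + 13L)
}

#' Rebuild the images of one pool pair
#'
#' Deterministically regenerates the original image, importance map,
#' manipulated image and change region of a pair from its stored seeds.
#'
#' @param pool a [generate_stimulus_pool()] result.
#' @param pair_id pair identifier.
#' @return List with `orig`, `manip`, `region`, `imap`.
#' @export
regenerate_pair <- function(pool, pair_id) {
  stopifnot(inherits(pool, "stimulus_pool"))
  row <- pool$scores[pool$scores$pair_id == pair_id, ]
  if (nrow(row) != 1L) stop("unknown pair_id", call. = FALSE)
  cfg <- pool$config
  img <- make_texture_image(row$source_seed, cfg$width, cfg$height)
  imap <- make_importance_map(row$source_seed %% 1000000L + 7L,
                              cfg$width, cfg$height)
  man <- apply_manipulation(img, mode = row$mode, magnitude = row$magnitude,
                            center_px = c(row$center_x, row$center_y),
                            radius_px = row$radius_px, seed = row$manip_seed,
                            ecc_min_deg = cfg$ecc_min_deg)
  list(orig = img, manip = man$image, region = man$region, imap = imap)
}

#' @export
print.stimulus_pool <- function(x, ...) {
  cat(sprintf("<stimulus_pool> %d pairs over %d sources, cor(ce, si) = %.3f\n",
              nrow(x$scores), length(unique(x$scores$source_image_id)),
              x$cor_ce_si))
  invisible(x)
}

#' Reaction-time generator configuration
#'
#' The stated world of the RT simulator: shifted-Wald detection channels with
#' a common threshold of 4 (shape 16) and a 0.5 s non-decision shift. The
#' drifts (baseline 0.4845, contrast-energy channel 0.6777,
#' subjective-importance channel 0.7110) put the channel medians at 7.1, 5.5
#' and 5.3 s — the published per-condition medians of the flicker task.
#' Misses and false alarms are injected at 1.5% each (97% detection), and
#' RTs are censored at the 240 s trial deadline.
#'
#' @param architecture `"race"` (redundant condition = minimum of the two
#'   independent channel draws) or `"coactivation"` (single accumulator with
#'   summed drifts).
#' @param threshold common decision threshold.
#' @param shift non-decision time in seconds.
#' @param drift_baseline,drift_ce,drift_si channel drift rates.
#' @param n_subjects number of subjects (default 60).
#' @param subject_jitter_sd SD of the log-normal between-subject drift
#'   multiplier.
#' @param p_miss,p_false_alarm injection rates.
#' @param max_rt censoring deadline in seconds.
#' @param seed RNG seed (mandatory).
#' @return A list of class `rt_gen_config`.
#' @export
rt_gen_config <- function(architecture = c("race", "coactivation"),
                          threshold = 4, shift = 0.5,
                          drift_baseline = 0.4845, drift_ce = 0.6777,
                          drift_si = 0.7110, n_subjects = 60L,
                          subject_jitter_sd = 0.1, p_miss = 0.015,
                          p_false_alarm = 0.015, max_rt = 240, seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(threshold > 0, shift >= 0, drift_baseline > 0, drift_ce > 0,
            drift_si > 0, n_subjects >= 2L, p_miss >= 0, p_miss <= 1,
            p_false_alarm >= 0, p_false_alarm <= 1, !is.null(seed))
  structure(as.list(environment()), class = "rt_gen_config")
}

#' Simulate trial-level reaction times for a design
#'
#' Each subject sees one subset of image pairs (subjects are dealt to subsets
#' round-robin; a design without subsets is treated as a single subset of all
#' selected pairs). Per trial, the engaged channels follow the condition:
#' low-CE/low-SI runs the slow baseline channel, single-high conditions run
#' the corresponding channel, and the redundant high/high condition draws
#' either the minimum of both channels (race) or a single accumulator with
#' summed drifts (coactivation). Draws beyond the deadline are censored to
#' misses; additional misses and false alarms are injected at the configured
#' rates.
#'
#' @param design a `design_assignment` (with or without subsets).
#' @param cfg an [rt_gen_config()].
#' @return A trial `data.frame`: `subject_id`, `pair_id`, `condition`,
#'   `ce_change`, `si_change`, `rt_s`, `responded`, `outcome`, with the
#'   generating parameters attached as the `ground_truth` attribute.
#' @export
simulate_rts <- function(design, cfg = rt_gen_config()) {
  stopifnot(inherits(design, "design_assignment"), inherits(cfg, "rt_gen_config"))
  set.seed(cfg$seed)
  sel <- design$assignment[design$assignment$selected, , drop = FALSE]
  if (is.null(design$subsets)) {
    subsets <- list(sel)
  } else {
    subsets <- lapply(seq_len(ncol(design$subsets)),
                      function(s) subset_members(design, s))
  }
  n_sub <- length(subsets)
  rows <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    pairs <- subsets[[((i - 1L) %% n_sub) + 1L]]
    mult <- exp(stats::rnorm(1, 0, cfg$subject_jitter_sd))
    cond <- as.character(pairs$condition)
    nt <- nrow(pairs)
    rt <- numeric(nt)
    for (k in seq_len(nt)) {
      rt[k] <- switch(
        cond[k],
        "lowCE-lowSI" = rshifted_wald(1, cfg$drift_baseline * mult,
                                      cfg$threshold, cfg$shift),
        "highCE-lowSI" = rshifted_wald(1, cfg$drift_ce * mult,
                                       cfg$threshold, cfg$shift),
        "lowCE-highSI" = rshifted_wald(1, cfg$drift_si * mult,
                                       cfg$threshold, cfg$shift),
        "highCE-highSI" = if (cfg$architecture == "race")
          min(rshifted_wald(1, cfg$drift_ce * mult, cfg$threshold, cfg$shift),
              rshifted_wald(1, cfg$drift_si * mult, cfg$threshold, cfg$shift))
        else
          rshifted_wald(1, (cfg$drift_ce + cfg$drift_si) * mult,
                        cfg$threshold, cfg$shift),
        stop("unknown condition label: ", cond[k]))
    }
    u <- stats::runif(nt)
    outcome <- ifelse(u < cfg$p_miss, "miss",
                      ifelse(u < cfg$p_miss + cfg$p_false_alarm,
                             "false_alarm", "hit"))
    outcome[rt > cfg$max_rt] <- "miss"
    rt <- pmin(rt, cfg$max_rt)
    rows[[i]] <- data.frame(
      subject_id = sprintf("sub%02d", i),
      pair_id = as.character(pairs$pair_id),
      condition = cond,
      ce_change = pairs$ce_change, si_change = pairs$si_change,
      rt_s = rt,
      responded = outcome != "miss",
      outcome = outcome)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- cfg
  out
}
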