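# Independent oracles and fixture builders used across the suite.

# Literal double-sum evaluation of the Gaussian-windowed local contrast
# energy: for each pixel, loop over the (2r+1)^2 window, renormalize weights
# over the in-bounds support, and form the weighted relative variance.
bf_contrast_energy <- function(X, sigma, r, variant = "rms") {
  H <- nrow(X); W <- ncol(X)
  out <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc_w <- 0; acc_l <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
        acc_w <- acc_w + w
        acc_l <- acc_l + w * X[ii, jj]
      }
    }
    Lbar <- acc_l / acc_w
    if (Lbar <= 0) next
    acc_v <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
        acc_v <- acc_v + w * (X[ii, jj] - Lbar)^2 / Lbar^2
      }
    }
    v <- acc_v / acc_w
    out[i, j] <- if (variant == "rms") sqrt(v) else v
  }
  out
}

# A cheap synthetic scores pool (no images): independent lognormal ce/si and
# independent covariates, feasible for selection and subset construction.
make_scores_pool <- function(n = 300, n_sources = 100, seed = 1) {
  set.seed(seed)
  data.frame(
    pair_id = sprintf("p%03d", seq_len(n)),
    source_image_id = sprintf("s%03d", ((seq_len(n) - 1) %% n_sources) + 1),
    ce_change = exp(rnorm(n, -3, 0.8)),
    si_change = exp(rnorm(n, 3, 1)),
    size_px = round(runif(n, 400, 3000)),
    eccentricity_deg = runif(n, 0.2, 8),
    mean_contrast = runif(n, 0.05, 0.5),
    max_contrast = runif(n, 0.5, 1.5),
    min_contrast = runif(n, 0, 0.05),
    luminance_change = abs(rnorm(n, 0, 5)),
    sf_change = rnorm(n, 0, 2))
}

# A complete paper-layout design built from the cheap pool (fast; reused by
# the RT and race tests).
make_test_design <- function(seed = 1) {
  design <- select_balanced_set(make_scores_pool(seed = seed), seed = seed)
  build_subsets(design, seed = seed)
}

# Null RT table: every condition draws from one inverse-Gaussian channel.
make_null_trials <- function(n_subjects = 60, per_cond = 9, seed = 1,
                             mean = 5, shape = 16, shift = 0.5) {
  set.seed(seed)
  tab <- expand.grid(subject_id = sprintf("sub%02d", seq_len(n_subjects)),
                     condition = condition_levels(),
                     trial = seq_len(per_cond),
                     stringsAsFactors = FALSE)
  tab$rt_s <- shift + statmod::rinvgauss(nrow(tab), mean = mean, shape = shape)
  tab$ce_change <- runif(nrow(tab))
  tab$si_change <- runif(nrow(tab))
  tab$outcome <- "hit"
  tab$responded <- TRUE
  tab
}

# Independent-race RT table: the redundant condition is the minimum of two
# independent channel draws whose marginals match the single conditions, so
# the Miller bound holds by construction.
make_race_trials <- function(n_subjects = 60, per_cond = 9, seed = 1,
                             drift_ce = 0.6777, drift_si = 0.7110,
                             drift_base = 0.4845, threshold = 4, shift = 0.5) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(i) {
    draw <- function(nu, n) rshifted_wald(n, nu, threshold, shift)
    data.frame(
      subject_id = sprintf("sub%02d", i),
      condition = rep(condition_levels(), each = per_cond),
      rt_s = c(draw(drift_base, per_cond), draw(drift_ce, per_cond),
               draw(drift_si, per_cond),
               pmin(draw(drift_ce, per_cond), draw(drift_si, per_cond))),
      outcome = "hit")
  })
  do.call(rbind, rows)
}
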