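test_that("trial classification: hit radius, bounds, misses", {
  geom <- image_geometry(100, 100, deg_per_px = 0.05)  # 0.75 deg = 15 px
  mask <- matrix(FALSE, 100, 100); mask[41:60, 41:60] <- TRUE
  region <- change_region(mask)

  expect_equal(classify_trial(c(50, 50), region, geom), "hit")
  # nearest mask pixel to a click right of the block is at x = 59 (0-based)
  d_hit <- 0.74 / geom$deg_per_px
  d_fa <- 0.76 / geom$deg_per_px
  expect_equal(classify_trial(c(59 + d_hit, 50), region, geom), "hit")
  expect_equal(classify_trial(c(59 + d_fa, 50), region, geom), "false_alarm")
  expect_equal(classify_trial(NULL, region, geom, responded = FALSE), "miss")
  expect_warning(out <- classify_trial(c(500, 50), region, geom),
                 "outside")
  expect_equal(out, "false_alarm")

  tab <- data.frame(pair_id = "p1", responded = c(TRUE, TRUE, FALSE),
                    click_x = c(50, 5, NA), click_y = c(50, 5, NA))
  got <- classify_trials(tab, list(p1 = region), geom)
  expect_equal(got$outcome, c("hit", "false_alarm", "miss"))
})

test_that("exclusion filter keeps hits, reports counts, is idempotent", {
  set.seed(31)
  tab <- make_null_trials(n_subjects = 60, per_cond = 9, seed = 31)
  bad <- sample(nrow(tab), 61)
  tab$outcome[bad] <- sample(c("miss", "false_alarm"), 61, replace = TRUE)
  filt <- exclusion_filter(tab)
  expect_equal(filt$n_total, 2160L)
  expect_equal(filt$n_retained, 2099L)
  expect_equal(filt$n_excluded, 61L)
  # per-condition counts equal a brute tally
  for (cond in condition_levels()) {
    expect_equal(filt$summary$n_hit[filt$summary$condition == cond],
                 sum(tab$outcome == "hit" & tab$condition == cond))
  }
  again <- exclusion_filter(filt$trials)
  expect_identical(again$trials, filt$trials)
  expect_equal(again$n_excluded, 0L)

  allbad <- tab; allbad$outcome <- "miss"
  expect_error(exclusion_filter(allbad), class = "changescope_no_data")
})

test_that("proportions ANOVA: degrees of freedom and the flat case", {
  tab <- make_null_trials(n_subjects = 60, per_cond = 9, seed = 5)
  pa <- proportions_anova(tab)
  expect_equal(pa$df1, c(3L, 3L))
  expect_equal(pa$df2, c(236L, 236L))  # 60 subjects x 4 conditions, between cells
  paw <- proportions_anova(tab, convention = "within_subject")
  expect_equal(paw$df2, c(177L, 177L))

  # identical proportions across conditions for every subject: F = 0
  flat <- expand.grid(subject_id = 1:10, condition = condition_levels(),
                      trial = 1:4, stringsAsFactors = FALSE)
  flat$outcome <- rep(c("hit", "hit", "hit", "false_alarm"),
                      each = nrow(flat) / 4)
  pf <- proportions_anova(flat)
  expect_equal(pf$F, c(0, 0))
  expect_equal(pf$p, c(1, 1))

  unb <- tab[!(tab$subject_id == "sub01" & tab$condition == "lowCE-lowSI"), ]
  expect_error(proportions_anova(unb), class = "changescope_unbalanced_design")
})

test_that("KS non-normality check: bounds, power on skewed RTs, conservatism", {
  # power: inverse-Gaussian RT samples are flagged as non-normal
  for (s in 1:20) {
    set.seed(s)
    x <- statmod::rinvgauss(2000, mean = 5, shape = 6)
    k <- ks_nonnormality(x)
    expect_lt(k$p, 0.001)
    expect_gte(k$D, 0); expect_lte(k$D, 1)
  }
  # plug-in reference: D small and rejections rare under the null
  ps <- vapply(1:50, function(s) {
    set.seed(s); ks_nonnormality(rnorm(500, 5, 1))$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.05)
  expect_error(ks_nonnormality(rep(1, 50)), "variance")
  expect_error(ks_nonnormality(rnorm(5)), "at least")
})

test_that("inverse-Gaussian GLM: df bookkeeping, order invariance, recovery", {
  tab <- make_null_trials(n_subjects = 60, per_cond = 9, seed = 13)
  tab$outcome[sample(nrow(tab), 61)] <- "miss"
  filt <- exclusion_filter(tab)
  fit <- fit_rt_glm(filt$trials, coding = "split")
  expect_equal(fit$n, 2099L)
  expect_equal(fit$df_residual, 2095L)
  expect_equal(unname(fit$coefficients[, "t"]),
               unname(fit$coefficients[, "estimate"] / fit$coefficients[, "se"]))

  # bit-identical under row reordering (balanced cells)
  shuffled <- filt$trials[sample(nrow(filt$trials)), ]
  fit2 <- fit_rt_glm(shuffled, coding = "split")
  expect_identical(fit$coefficients, fit2$coefficients)

  # recovery on one coactivation run at paper scale
  design <- make_test_design(seed = 17)
  trials <- simulate_rts(design, rt_gen_config(architecture = "coactivation",
                                               seed = 17))
  co <- fit_rt_glm(exclusion_filter(trials)$trials, coding = "split")
  expect_true(all(co$coefficients[c("ce", "si", "ce_si"), "estimate"] < 0))
  expect_true(all(co$coefficients[c("ce", "si", "ce_si"), "p"] < 0.001))

  ranked <- fit_rt_glm(exclusion_filter(trials)$trials, coding = "ranked")
  expect_equal(ranked$coding, "ranked")
  expect_lt(ranked$coefficients["ce", "estimate"], 0)

  one_level <- filt$trials[filt$trials$condition == "lowCE-lowSI", ]
  expect_error(fit_rt_glm(one_level, coding = "split"), "vary")
})

test_that("inverse-Gaussian CDF fit: recovery, quality bar, degenerate input", {
  stats <- t(vapply(1:100, function(s) {
    set.seed(s)
    x <- statmod::rinvgauss(500, mean = 3, shape = 8)
    f <- fit_ig_cdf(x)
    c(f$mean, f$shape, f$r_squared)
  }, numeric(3)))
  expect_lt(abs(median(stats[, 1]) - 3) / 3, 0.1)
  expect_lt(abs(median(stats[, 2]) - 8) / 8, 0.1)
  expect_gte(mean(stats[, 3] >= 0.97), 0.95)

  # shifted variant: recovers a genuine shift direction
  set.seed(123)
  x <- 2 + statmod::rinvgauss(1000, mean = 2, shape = 10)
  fs <- fit_ig_cdf(x, shifted = TRUE)
  expect_gt(fs$shift, 1)
  expect_lt(fs$shift, min(x))
  expect_gt(fs$r_squared, 0.97)

  expect_error(fit_ig_cdf(rep(2, 50)), "degenerate|constant")
  expect_error(fit_ig_cdf(statmod::rinvgauss(10, 1, 1)), "at least")

  fits <- fit_ig_by_condition(make_null_trials(n_subjects = 20, seed = 9))
  expect_named(fits, condition_levels(), ignore.order = TRUE)
  expect_true(all(vapply(fits, function(f) f$mean > 0 && f$shape > 0,
                         logical(1))))
})
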