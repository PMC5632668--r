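test_that("median split labels, tie rule, and degenerate input", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(5, 5, 1, 9))),
               c("low", "low", "low", "high"))
  expect_error(median_split(rep(2, 10)),
               class = "changescope_degenerate_split")
  expect_error(median_split(3))

  pool <- make_scores_pool(n = 108, seed = 2)
  s <- median_split(pool$ce_change)
  expect_equal(as.integer(table(s)), c(54L, 54L))
})

test_that("condition assignment crosses the two splits", {
  corners <- data.frame(ce_change = c(1, 10, 1, 10),
                        si_change = c(1, 1, 10, 10))
  a <- assign_conditions(corners)
  expect_equal(as.character(a$condition), condition_levels())

  # independent uniforms: near-equal cell counts (chi-square quiet for the
  # vast majority of seeded pools)
  sig <- vapply(1:100, function(s) {
    set.seed(s)
    d <- assign_conditions(data.frame(ce_change = runif(100),
                                      si_change = runif(100)))
    suppressWarnings(stats::chisq.test(table(d$condition))$p.value) < 0.05
  }, logical(1))
  expect_lte(sum(sig), 10)
})

test_that("internal group tests agree with stats::aov and stats::kruskal.test", {
  set.seed(21)
  for (i in 1:5) {
    v <- rnorm(60, sd = runif(1, 0.5, 3))
    g <- factor(sample(letters[1:4], 60, replace = TRUE))
    a <- changescope:::fast_oneway(v, g)
    ref <- anova(stats::lm(v ~ g))
    expect_equal(a$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(a$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    k <- changescope:::fast_kruskal(v, g)
    refk <- stats::kruskal.test(v, g)
    expect_equal(k$H, unname(refk$statistic), tolerance = 1e-10)
    expect_equal(k$p, refk$p.value, tolerance = 1e-10)
  }
})

test_that("balance report: degrees of freedom, edge cases, pass flag", {
  pool <- assign_conditions(make_scores_pool(n = 108, seed = 4))
  rep <- balance_report(pool)
  expect_equal(rep$df1, rep(3L, nrow(rep)))
  expect_equal(rep$df2, rep(104L, nrow(rep)))
  expect_true(all(rep$p_anova >= 0 & rep$p_anova <= 1))

  # identical covariate values everywhere: F = 0, H = 0, p = 1
  flat <- pool
  for (cv in balance_covariates()) flat[[cv]] <- 1
  repf <- balance_report(flat)
  expect_true(all(repf$F == 0) && all(repf$H == 0))
  expect_true(all(repf$p_anova == 1) && all(repf$p_kruskal == 1))
  expect_true(attr(repf, "pass"))

  tiny <- pool[pool$condition == "lowCE-lowSI", ][1:3, ]
  expect_error(balance_report(tiny), class = "changescope_degenerate_report")
})

test_that("balanced selection returns the paper layout and honors exclusions", {
  pool <- make_scores_pool(n = 300, seed = 7)
  design <- select_balanced_set(pool, seed = 7)
  sel <- design$assignment[design$assignment$selected, ]
  expect_equal(nrow(sel), 108L)
  expect_equal(as.integer(table(sel$condition)), rep(27L, 4))
  expect_true(attr(design$report, "pass"))
  expect_true(all(sel$eccentricity_deg >= 1.6))

  # determinism: same seed and pool give an identical selection
  design2 <- select_balanced_set(pool, seed = 7)
  expect_identical(design$assignment, design2$assignment)

  # partition invariant: each selected pair has exactly one condition
  expect_false(anyNA(sel$condition))

  # size perfectly confounded with the CE split cannot be balanced
  confounded <- pool
  confounded$size_px <- ifelse(confounded$ce_change >
                                 median(confounded$ce_change), 10000, 10)
  expect_error(select_balanced_set(confounded, seed = 1, max_iter = 300),
               class = "changescope_infeasible_design")
  err <- tryCatch(select_balanced_set(confounded, seed = 1, max_iter = 300),
                  error = function(e) e)
  expect_s3_class(err$report, "balance_report")
})

test_that("eccentricity exclusion equals the 41.4 px radius on the standard grid", {
  geom <- default_geometry()
  pool <- make_scores_pool(n = 400, seed = 9)
  # recast eccentricities as pixel radii around the boundary
  pool$ecc_px <- runif(400, 20, 80)
  pool$eccentricity_deg <- pixels_to_degrees(pool$ecc_px, geom)
  design <- select_balanced_set(pool, seed = 9)
  sel <- design$assignment[design$assignment$selected, ]
  expect_true(all(sel$ecc_px >= 41.3))
  expect_true(all(pool$ecc_px[pool$eccentricity_deg < 1.6] < 41.4 + 1e-6))
})

test_that("subset construction: paper layout, small partition, infeasibility", {
  design <- make_test_design(seed = 3)
  m <- design$subsets
  expect_equal(dim(m), c(108L, 6L))
  expect_equal(colSums(m), rep(36, 6), ignore_attr = TRUE)
  expect_equal(rowSums(m), rep(2, 108), ignore_attr = TRUE)  # each pair used twice
  sel <- design$assignment[design$assignment$selected, ]
  for (s in 1:6) {
    mem <- subset_members(design, s)
    expect_equal(nrow(mem), 36L)
    expect_equal(as.integer(table(mem$condition)), rep(9L, 4))
    expect_false(any(duplicated(mem$source_image_id)))
  }

  # 8 pairs over 2 conditions into 2 subsets of 4: a genuine partition,
  # checked exhaustively
  mini <- data.frame(pair_id = sprintf("m%d", 1:8),
                     source_image_id = sprintf("src%d", 1:8),
                     condition = factor(rep(c("lowCE-lowSI", "highCE-highSI"),
                                            each = 4)),
                     selected = TRUE)
  mini_design <- structure(list(assignment = mini, subsets = NULL),
                           class = "design_assignment")
  mini_design <- build_subsets(mini_design, n_subsets = 2, per_subset = 4,
                               seed = 5)
  mm <- mini_design$subsets
  expect_equal(rowSums(mm), rep(1, 8), ignore_attr = TRUE)   # partition
  expect_equal(colSums(mm), rep(4, 2), ignore_attr = TRUE)
  for (s in 1:2)
    expect_false(any(duplicated(subset_members(mini_design, s)$source_image_id)))

  # two pairs sharing one source forced into a single subset of 2
  clash <- data.frame(pair_id = c("a", "b"),
                      source_image_id = c("s", "s"),
                      condition = factor(c("lowCE-lowSI", "highCE-highSI")),
                      selected = TRUE)
  clash_design <- structure(list(assignment = clash, subsets = NULL),
                            class = "design_assignment")
  expect_error(build_subsets(clash_design, n_subsets = 1, per_subset = 2,
                             max_restarts = 5),
               class = "changescope_infeasible_subsets")
})

test_that("subset construction is deterministic under the seed", {
  d1 <- make_test_design(seed = 11)
  d2 <- make_test_design(seed = 11)
  expect_identical(d1$subsets, d2$subsets)
})
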