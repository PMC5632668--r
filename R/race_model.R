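#' Empirical CDF with interpolated quantiles
#'
#' Stores the sorted sample. `F(t)` is the right-continuous step function
#' `#\{x <= t\} / n`; quantiles are computed by linear interpolation between
#' order statistics (type-7 rule: `quantile(0.5)` of `c(1,2,3,4)` is 2.5).
#'
#' @param rts numeric vector (`n >= 1`).
#' @return An object of class `empirical_cdf`.
#' @export
empirical_cdf <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) < 1L || anyNA(rts)) stop("need non-empty, non-NA input",
                                           call. = FALSE)
  structure(list(sorted = sort(rts), n = length(rts)),
            class = "empirical_cdf")
}

#' @rdname empirical_cdf
#' @param cdf an `empirical_cdf`.
#' @param t evaluation time(s).
#' @return `cdf_eval`: `F(t)` values in `[0, 1]`.
#' @export
cdf_eval <- function(cdf, t) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  findInterval(t, cdf$sorted) / cdf$n
}

#' @rdname empirical_cdf
#' @param q probability level(s) in `[0, 1]`.
#' @return `cdf_quantile`: interpolated quantile(s).
#' @export
cdf_quantile <- function(cdf, q) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  quantile7(cdf$sorted, q)
}

# internal: type-7 quantile from an already-sorted vector
quantile7 <- function(xs, q) {
  n <- length(xs)
  if (n == 1L) return(rep(xs, length(q)))
  h <- (n - 1) * q + 1
  lo <- pmax(floor(h), 1)
  hi <- pmin(lo + 1, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

#' Race-model (Miller) bound
#'
#' The upper bound of statistical facilitation for the redundant condition:
#' `B(t) = F1(t) + F2(t)`, left uncapped (beyond both sample maxima it
#' reaches 2; values above 1 are never the binding part of the test).
#'
#' @param cdf1,cdf2 [empirical_cdf()] objects of the two single-property
#'   conditions.
#' @param t_grid evaluation times.
#' @return Numeric vector `B(t_grid)`.
#' @export
race_bound <- function(cdf1, cdf2, t_grid) {
  cdf_eval(cdf1, t_grid) + cdf_eval(cdf2, t_grid)
}

#' @rdname race_bound
#' @param q probability level(s).
#' @return `race_bound_quantile`: the time at which the bound reaches `q`,
#'   by linear interpolation across the pooled jump points.
#' @export
race_bound_quantile <- function(cdf1, cdf2, q) {
  knots <- sort(c(cdf1$sorted, cdf2$sorted))
  B <- cdf_eval(cdf1, knots) + cdf_eval(cdf2, knots)
  vapply(q, function(qq) {
    i <- which(B >= qq)[1]
    if (is.na(i)) return(knots[length(knots)])
    if (i == 1L || B[i] == qq) return(knots[i])
    b0 <- B[i - 1L]
    knots[i - 1L] + (qq - b0) / (B[i] - b0) * (knots[i] - knots[i - 1L])
  }, numeric(1))
}

#' Race-model inequality test with subject bootstrap
#'
#' Compares the redundant (high-CE/high-SI) condition against the race bound
#' built from the two single-property conditions at the deciles 0.10 to 0.90.
#' In the default quantile domain the violation at level `q` is
#' `bound_RT(q) - observed_RT(q)` in seconds (positive means the redundant
#' condition is faster than any race of independent channels). The
#' probability-domain variant reports `F_redundant(t) - B(t)` at the observed
#' redundant decile RTs. Subjects are resampled with replacement (`n_boot`
#' replicates), their hit trials pooled per condition and both sides
#' recomputed; one-sided p-values are the fraction of replicates with
#' violation `<= 0`, tested against the Bonferroni-corrected threshold
#' `alpha / length(quantiles)`. Only positive observed violations are
#' eligible for significance.
#'
#' @param table trial `data.frame` with `subject_id`, `condition`, `rt_s`
#'   (rows with an `outcome` column are filtered to hits).
#' @param quantiles probability levels tested (default deciles 0.1 to 0.9).
#' @param n_boot bootstrap replicates (default 10000).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed RNG seed (required for reproducibility).
#' @param domain `"quantile"` (seconds, default) or `"probability"`.
#' @param conditions named character vector mapping `redundant`, `single1`,
#'   `single2` to condition labels.
#' @return An object of class `race_test_result`: `data.frame` with one row
#'   per quantile (`quantile`, `observed_rt`, `bound_rt`, `violation`,
#'   `ci_lo`, `ci_hi`, `p`, `significant`) plus attributes `alpha`,
#'   `corrected_alpha`, `n_boot`, `domain`, `seed`.
#' @export
race_test <- function(table, quantiles = seq(0.1, 0.9, by = 0.1),
                      n_boot = 10000L, alpha = 0.05, seed = 1L,
                      domain = c("quantile", "probability"),
                      conditions = c(redundant = "highCE-highSI",
                                     single1 = "highCE-lowSI",
                                     single2 = "lowCE-highSI")) {
  domain <- match.arg(domain)
  if ("outcome" %in% names(table)) table <- table[table$outcome == "hit", ]
  stopifnot(all(c("subject_id", "condition", "rt_s") %in% names(table)))
  table <- table[as.character(table$condition) %in% conditions, , drop = FALSE]
  have <- table(factor(as.character(table$condition), levels = conditions))
  if (any(have == 0L))
    stop(structure(class = c("changescope_missing_condition", "error", "condition"),
                   list(message = paste("no hit trials in condition(s):",
                                        paste(conditions[have == 0], collapse = ", ")),
                        call = NULL)))
  subj <- unique(as.character(table$subject_id))
  if (length(subj) < 2L) stop("need at least 2 subjects", call. = FALSE)

  # per-subject RT pools per role, for fast bootstrap resampling
  role_of <- stats::setNames(names(conditions), conditions)
  table$role <- role_of[as.character(table$condition)]
  pools <- lapply(c("redundant", "single1", "single2"), function(rl) {
    d <- table[table$role == rl, ]
    sp <- split(d$rt_s, factor(as.character(d$subject_id), levels = subj))
    sp
  })
  names(pools) <- c("redundant", "single1", "single2")

  measure <- function(idx) {
    rr <- sort(unlist(pools$redundant[idx], use.names = FALSE))
    s1 <- empirical_cdf(unlist(pools$single1[idx], use.names = FALSE))
    s2 <- empirical_cdf(unlist(pools$single2[idx], use.names = FALSE))
    if (domain == "quantile") {
      obs <- quantile7(rr, quantiles)
      bnd <- race_bound_quantile(s1, s2, quantiles)
      list(observed = obs, bound = bnd, violation = bnd - obs)
    } else {
      red <- empirical_cdf(rr)
      tq <- quantile7(rr, quantiles)
      fb <- race_bound(s1, s2, tq)
      fr <- cdf_eval(red, tq)
      list(observed = fr, bound = fb, violation = fr - fb)
    }
  }

  all_idx <- seq_along(subj)
  obs <- measure(all_idx)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(quantiles))
  for (b in seq_len(n_boot))
    boot[b, ] <- measure(sample(all_idx, replace = TRUE))$violation
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  p <- colMeans(boot <= 0)
  corrected <- alpha / length(quantiles)
  res <- data.frame(quantile = quantiles,
                    observed_rt = obs$observed, bound_rt = obs$bound,
                    violation = obs$violation,
                    ci_lo = ci[1, ], ci_hi = ci[2, ], p = p,
                    significant = p < corrected & obs$violation > 0)
  structure(res, alpha = alpha, corrected_alpha = corrected,
            n_boot = n_boot, domain = domain, seed = seed,
            n_subjects = length(subj),
            class = c("race_test_result", "data.frame"))
}

#' @export
print.race_test_result <- function(x, ...) {
  cat(sprintf("<race_test_result> domain=%s, %d quantiles, corrected alpha=%.4g, %d bootstrap reps over %d subjects\n",
              attr(x, "domain"), nrow(x), attr(x, "corrected_alpha"),
              attr(x, "n_boot"), attr(x, "n_subjects")))
  print.data.frame(round(as.data.frame(x)[1:7], 4), row.names = FALSE)
  cat("significant:", paste(x$quantile[x$significant], collapse = " "), "\n")
  invisible(x)
}

#' Largest significant race-model violation
#'
#' The maximum violation (in seconds for the quantile domain) over the
#' Bonferroni-corrected significant quantiles; 0 when none is significant.
#'
#' @param result a [race_test()] result.
#' @return Non-negative scalar.
#' @export
violation_summary <- function(result) {
  stopifnot(inherits(result, "race_test_result"))
  if (!any(result$significant)) return(0)
  max(result$violation[result$significant])
}
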