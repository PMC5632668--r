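#' Shifted-Wald (shifted inverse-Gaussian) random draws
#'
#' First-passage times of a unit-variance drift-diffusion process with drift
#' `drift` to threshold `threshold`, plus a non-decision shift:
#' `shift + IG(mean = threshold/drift, shape = threshold^2)`.
#'
#' @param n number of draws.
#' @param drift drift rate (`> 0`), evidence units per second.
#' @param threshold decision threshold (`> 0`), evidence units.
#' @param shift non-decision time in seconds (`>= 0`).
#' @return Numeric vector of RTs in seconds.
#' @export
rshifted_wald <- function(n, drift, threshold, shift = 0) {
  stopifnot(all(drift > 0), all(threshold > 0), all(shift >= 0))
  shift + statmod::rinvgauss(n, mean = threshold / drift, shape = threshold^2)
}

#' @rdname rshifted_wald
#' @param q quantile(s) in seconds.
#' @export
pshifted_wald <- function(q, drift, threshold, shift = 0) {
  statmod::pinvgauss(pmax(q - shift, 0), mean = threshold / drift,
                     shape = threshold^2)
}

#' Maximum-likelihood inverse-Gaussian fit with CDF quality
#'
#' Fits an inverse-Gaussian (Wald) distribution to a sample by maximum
#' likelihood. The unshifted fit uses the closed-form estimators
#' `mean = mean(x)` and `shape = n / sum(1/x - 1/mean(x))`. The optional
#' 3-parameter variant profiles a non-decision shift over `[0, min(x))`.
#' Fit quality is the variance explained (R squared) between the fitted CDF
#' and the empirical CDF evaluated at the sorted sample.
#'
#' @param rts numeric vector of reaction times in seconds (`n >= 20`).
#' @param shifted fit the 3-parameter shifted variant (default `FALSE`).
#' @return An object of class `ig_fit`: list with `mean`, `shape`, `shift`,
#'   `r_squared`, `loglik`, `n`.
#' @export
fit_ig_cdf <- function(rts, shifted = FALSE) {
  rts <- as.numeric(rts)
  n <- length(rts)
  if (n < 20L) stop("need at least 20 reaction times", call. = FALSE)
  if (any(rts <= 0)) stop("reaction times must be positive", call. = FALSE)
  if (stats::sd(rts) == 0)
    stop("degenerate (constant) reaction times: cannot fit", call. = FALSE)

  mle_at <- function(theta) {
    x <- rts - theta
    mu <- mean(x)
    lambda <- n / sum(1 / x - 1 / mu)
    ll <- sum(statmod::dinvgauss(x, mean = mu, shape = lambda, log = TRUE))
    list(mean = mu, shape = lambda, loglik = ll)
  }
  if (shifted) {
    hi <- min(rts) * (1 - 1e-6)
    opt <- stats::optimize(function(th) mle_at(th)$loglik, c(0, hi),
                           maximum = TRUE, tol = 1e-6)
    shift <- opt$maximum
    # the boundary shift = 0 case: keep whichever likelihood is higher
    if (mle_at(0)$loglik >= opt$objective) shift <- 0
  } else shift <- 0
  fit <- mle_at(shift)
  if (!is.finite(fit$loglik) || fit$shape <= 0 || fit$mean <= 0)
    stop("inverse-Gaussian fit failed to converge", call. = FALSE)

  xs <- sort(rts)
  f_emp <- seq_len(n) / n
  f_fit <- statmod::pinvgauss(xs - shift, mean = fit$mean, shape = fit$shape)
  r2 <- 1 - sum((f_emp - f_fit)^2) / sum((f_emp - mean(f_emp))^2)
  structure(list(mean = fit$mean, shape = fit$shape, shift = shift,
                 r_squared = r2, loglik = fit$loglik, n = n),
            class = "ig_fit")
}

#' @export
print.ig_fit <- function(x, ...) {
  cat(sprintf("<ig_fit> mean=%.3f shape=%.3f shift=%.3f  R^2=%.4f (n=%d)\n",
              x$mean, x$shape, x$shift, x$r_squared, x$n))
  invisible(x)
}

#' Per-condition inverse-Gaussian CDF fits
#'
#' @param table trial `data.frame` with `rt_s` and `condition` (hits only or
#'   an `outcome` column, in which case only hits are used).
#' @param shifted see [fit_ig_cdf()].
#' @return Named list of `ig_fit` objects, one per condition.
#' @export
fit_ig_by_condition <- function(table, shifted = FALSE) {
  if ("outcome" %in% names(table)) table <- table[table$outcome == "hit", ]
  lapply(split(table$rt_s, factor(table$condition)), fit_ig_cdf,
         shifted = shifted)
}
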