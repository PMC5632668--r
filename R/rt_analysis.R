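#' Classify a response as hit, false alarm, or miss
#'
#' A trial is a `hit` when the observer responded and clicked within
#' `radius_deg` (default 0.75 degrees) of any pixel of the change region, a
#' `false_alarm` when the response landed outside that radius, and a `miss`
#' when no response occurred before the deadline. Clicks outside the image
#' bounds are treated as false alarms with a warning.
#'
#' @param click_px numeric `(x, y)` click position in 0-based pixel
#'   coordinates, or `NULL` for no response.
#' @param region a [change_region()].
#' @param geom an [image_geometry()].
#' @param radius_deg hit radius in degrees of visual angle.
#' @param responded did the observer respond at all?
#' @return One of `"hit"`, `"false_alarm"`, `"miss"`.
#' @export
classify_trial <- function(click_px, region, geom, radius_deg = 0.75,
                           responded = !is.null(click_px)) {
  if (!responded) return("miss")
  if (is.null(click_px) || anyNA(click_px))
    stop("responded trials must carry click coordinates", call. = FALSE)
  stopifnot(inherits(region, "change_region"), inherits(geom, "image_geometry"))
  x <- click_px[[1]]; y <- click_px[[2]]
  if (x < 0 || y < 0 || x > geom$width_px - 1 || y > geom$height_px - 1) {
    warning("click outside image bounds: classified as false_alarm")
    return("false_alarm")
  }
  ij <- which(region$mask, arr.ind = TRUE)
  d2 <- (ij[, 2] - 1 - x)^2 + (ij[, 1] - 1 - y)^2
  radius_px <- degrees_to_pixels(radius_deg, geom)
  if (min(d2) <= radius_px^2) "hit" else "false_alarm"
}

#' Classify all trials of a table against their change regions
#'
#' @param table trial `data.frame` with columns `pair_id`, `responded`,
#'   `click_x`, `click_y`.
#' @param regions named list of [change_region()] objects, indexed by
#'   `pair_id`.
#' @param geom an [image_geometry()].
#' @param radius_deg hit radius in degrees.
#' @return `table` with an `outcome` column.
#' @export
classify_trials <- function(table, regions, geom, radius_deg = 0.75) {
  stopifnot(is.data.frame(table))
  table$outcome <- vapply(seq_len(nrow(table)), function(i) {
    if (!isTRUE(table$responded[i])) return("miss")
    classify_trial(c(table$click_x[i], table$click_y[i]),
                   regions[[as.character(table$pair_id[i])]],
                   geom, radius_deg)
  }, character(1))
  table
}

#' Exclude misses and false alarms from a trial table
#'
#' Retains hits only and reports the exclusion bookkeeping per condition.
#' Idempotent: filtering a filtered table changes nothing.
#'
#' @param table trial `data.frame` with `condition` and `outcome` columns.
#' @return List with `trials` (hits only), `summary` (per-condition counts of
#'   hits, false alarms, misses), `n_total`, `n_retained`, `n_excluded`.
#' @export
exclusion_filter <- function(table) {
  stopifnot(is.data.frame(table), all(c("condition", "outcome") %in% names(table)))
  keep <- table$outcome == "hit"
  if (!any(keep))
    stop(structure(class = c("changescope_no_data", "error", "condition"),
                   list(message = "no hit trials remain after exclusion",
                        call = NULL)))
  cond <- factor(table$condition)
  summary <- as.data.frame.matrix(table(cond, factor(
    table$outcome, levels = c("hit", "false_alarm", "miss"))))
  names(summary) <- c("n_hit", "n_false_alarm", "n_miss")
  summary <- cbind(condition = rownames(summary), summary,
                   n_total = as.integer(table(cond)))
  rownames(summary) <- NULL
  list(trials = table[keep, , drop = FALSE], summary = summary,
       n_total = nrow(table), n_retained = sum(keep),
       n_excluded = sum(!keep))
}

#' ANOVA on per-subject outcome proportions
#'
#' Tests whether the proportion of false alarms (and of misses) differs
#' across the four conditions. Proportions are aggregated per subject and
#' condition. The default `"between_cells"` convention treats the
#' subject-by-condition proportions as independent cells, giving
#' `F(k-1, n_subjects*k - k)` — `F(3, 236)` for 60 subjects and 4 conditions.
#' The `"within_subject"` convention is the classical repeated-measures
#' error term with `F(k-1, (k-1)(n_subjects-1))`.
#'
#' @param table trial `data.frame` with `subject_id`, `condition`, `outcome`.
#' @param convention degrees-of-freedom convention (see Details).
#' @return A `data.frame` with one row per outcome type (`false_alarm`,
#'   `miss`): `F`, `df1`, `df2`, `p`.
#' @export
proportions_anova <- function(table,
                              convention = c("between_cells", "within_subject")) {
  convention <- match.arg(convention)
  stopifnot(all(c("subject_id", "condition", "outcome") %in% names(table)))
  subj <- factor(table$subject_id)
  cond <- factor(table$condition)
  if (nlevels(subj) < 2L) stop("need at least 2 subjects", call. = FALSE)
  n_cell <- table(subj, cond)
  if (any(n_cell == 0L))
    stop(structure(class = c("changescope_unbalanced_design", "error", "condition"),
                   list(message = "a subject has no trials in some condition",
                        call = NULL)))
  out <- lapply(c("false_alarm", "miss"), function(oc) {
    prop <- tapply(table$outcome == oc, list(subj, cond), mean)
    d <- data.frame(prop = as.vector(prop),
                    condition = factor(rep(colnames(prop), each = nrow(prop))),
                    subject = factor(rep(rownames(prop), ncol(prop))))
    if (convention == "between_cells") {
      a <- fast_oneway(d$prop, d$condition)
      data.frame(outcome = oc, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p)
    } else {
      k <- nlevels(d$condition); s <- nlevels(d$subject)
      gm <- mean(d$prop)
      cm <- tapply(d$prop, d$condition, mean)
      sm <- tapply(d$prop, d$subject, mean)
      ss_cond <- s * sum((cm - gm)^2)
      ss_err <- sum((d$prop - cm[as.integer(d$condition)] -
                       sm[as.integer(d$subject)] + gm)^2)
      df1 <- k - 1L; df2 <- (k - 1L) * (s - 1L)
      Fv <- if (ss_cond <= 0) 0 else (ss_cond / df1) / (ss_err / df2)
      data.frame(outcome = oc, F = Fv, df1 = df1, df2 = df2,
                 p = if (ss_cond <= 0) 1 else
                   stats::pf(Fv, df1, df2, lower.tail = FALSE))
    }
  })
  do.call(rbind, out)
}

#' Kolmogorov-Smirnov check of RT non-normality
#'
#' One-sample KS statistic of the pooled RTs against a normal reference with
#' the sample mean and standard deviation (plug-in).
#'
#' @param rts numeric vector of reaction times (`n >= 10`).
#' @return List with `D`, `p`, `n`.
#' @export
ks_nonnormality <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) < 10L) stop("need at least 10 RTs", call. = FALSE)
  if (stats::sd(rts) == 0) stop("zero-variance input", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(rts, "pnorm", mean(rts), stats::sd(rts)))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(rts))
}

#' Inverse-Gaussian GLM of reaction times
#'
#' Fits `rt ~ CE + SI + CE:SI` with an inverse-Gaussian response family.
#' Under `coding = "split"` the regressors are the binary low/high levels of
#' the condition labels (high = 1). Under `coding = "ranked"` they are the
#' within-experiment average ranks of the underlying `ce_change` and
#' `si_change` values (rescaled to `[0, 1]`; ties get average ranks), with
#' the interaction as their product. The default log link is used for
#' numerical stability; the canonical `1/mu^2` and identity links are
#' selectable.
#'
#' @param table filtered trial `data.frame` with `rt_s`, `condition`, and
#'   (for ranked coding) `ce_change`, `si_change` columns. Rows with an
#'   `outcome` column are filtered to hits.
#' @param coding `"split"` or `"ranked"`.
#' @param link `"log"`, `"inverse_squared"` (canonical), or `"identity"`.
#' @return An object of class `rt_glm`: list with `coefficients` (matrix with
#'   estimate, std. error, t, p per regressor), `df_residual`, `coding`,
#'   `link`, `family`, `n`, and the underlying `glm` fit.
#' @export
fit_rt_glm <- function(table, coding = c("split", "ranked"),
                       link = c("log", "inverse_squared", "identity")) {
  coding <- match.arg(coding)
  link <- match.arg(link)
  if ("outcome" %in% names(table)) table <- table[table$outcome == "hit", ]
  stopifnot(nrow(table) > 8L, all(c("rt_s", "condition") %in% names(table)))
  cond <- as.character(table$condition)
  if (coding == "split") {
    ce <- as.numeric(grepl("highCE", cond))
    si <- as.numeric(grepl("highSI", cond))
  } else {
    if (!all(c("ce_change", "si_change") %in% names(table)))
      stop("ranked coding needs ce_change and si_change columns", call. = FALSE)
    n <- nrow(table)
    ce <- rank(table$ce_change, ties.method = "average") / n
    si <- rank(table$si_change, ties.method = "average") / n
  }
  if (stats::sd(ce) == 0 || stats::sd(si) == 0)
    stop("both factors must vary in the table", call. = FALSE)
  link_str <- switch(link, log = "log", inverse_squared = "1/mu^2",
                     identity = "identity")
  d <- data.frame(rt = table$rt_s, ce = ce, si = si)
  # canonical row order: the fit is then invariant to how the table was sorted
  d <- d[order(d$ce, d$si, d$rt), , drop = FALSE]
  fit <- tryCatch(
    stats::glm(rt ~ ce * si, data = d,
               family = stats::inverse.gaussian(link = link_str),
               control = stats::glm.control(maxit = 100)),
    error = function(e) stop(structure(
      class = c("changescope_fit_error", "error", "condition"),
      list(message = paste("inverse-Gaussian GLM failed:",
                           conditionMessage(e)), call = NULL))))
  if (!fit$converged)
    stop(structure(class = c("changescope_fit_error", "error", "condition"),
                   list(message = "inverse-Gaussian GLM did not converge",
                        call = NULL)))
  cf <- summary(fit)$coefficients
  rownames(cf) <- c("intercept", "ce", "si", "ce_si")
  colnames(cf) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = cf, df_residual = fit$df.residual,
                 coding = coding, link = link_str,
                 family = "inverse.gaussian", n = nrow(d), fit = fit),
            class = "rt_glm")
}

#' @export
print.rt_glm <- function(x, ...) {
  cat(sprintf("<rt_glm> inverse-Gaussian family, link=%s, coding=%s, n=%d, residual df=%d\n",
              x$link, x$coding, x$n, x$df_residual))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}
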