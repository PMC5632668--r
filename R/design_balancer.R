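#' Median split of a continuous score
#'
#' Dichotomizes values at their 50th percentile. Values less than or equal to
#' the median (ties included) are labeled `"low"`, values above it `"high"`.
#'
#' @param values numeric vector, length `>= 2`.
#' @return A factor with levels `c("low", "high")`.
#' @examples
#' median_split(c(1, 2, 3, 4))   # low low high high
#' median_split(c(5, 5, 1, 9))   # ties at the median go to low
#' @export
median_split <- function(values) {
  if (length(values) < 2L || anyNA(values))
    stop("need at least 2 non-missing values", call. = FALSE)
  if (all(values == values[1]))
    stop(structure(class = c("changescope_degenerate_split", "error", "condition"),
                   list(message = "all values identical: degenerate median split",
                        call = NULL)))
  med <- stats::quantile(values, 0.5, type = 7, names = FALSE)
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

#' The four condition labels of the 2x2 design
#' @export
condition_levels <- function() {
  c("lowCE-lowSI", "highCE-lowSI", "lowCE-highSI", "highCE-highSI")
}

#' Assign pairs to the 2x2 median-split conditions
#'
#' Crosses the median splits of contrast-energy change and
#' subjective-importance change. Every pair receives exactly one of the four
#' labels `lowCE-lowSI`, `highCE-lowSI`, `lowCE-highSI`, `highCE-highSI`.
#'
#' @param scores `data.frame` with columns `ce_change` and `si_change` (one
#'   row per image pair).
#' @return `scores` with an added factor column `condition`.
#' @export
assign_conditions <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("ce_change", "si_change") %in% names(scores)))
  ce <- median_split(scores$ce_change)
  si <- median_split(scores$si_change)
  scores$condition <- factor(
    paste0(ifelse(ce == "high", "highCE", "lowCE"), "-",
           ifelse(si == "high", "highSI", "lowSI")),
    levels = condition_levels())
  scores
}

# ---- internal closed-form group tests -------------------------------------
# One-way ANOVA and Kruskal-Wallis computed directly. Needed because the
# greedy selector evaluates them thousands of times, and because the all-equal
# edge case must yield F = 0 / H = 0 with p = 1 rather than NaN. Verified
# against stats::aov / stats::kruskal.test in the test suite.

fast_oneway <- function(values, grp) {
  grp <- as.factor(grp)
  k <- nlevels(grp); n <- length(values)
  gm <- tapply(values, grp, mean)
  gn <- tabulate(grp, nbins = k)
  mu <- mean(values)
  ssb <- sum(gn * (gm - mu)^2)
  ssw <- sum((values - gm[as.integer(grp)])^2)
  df1 <- k - 1L; df2 <- n - k
  if (ssb <= 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  if (ssw <= 0) return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

fast_kruskal <- function(values, grp) {
  grp <- as.factor(grp)
  k <- nlevels(grp); n <- length(values)
  if (all(values == values[1])) return(list(H = 0, df = k - 1L, p = 1))
  r <- rank(values)
  rs <- tapply(r, grp, sum)
  gn <- tabulate(grp, nbins = k)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / gn) - 3 * (n + 1)
  ties <- table(values)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(H = H, df = k - 1L, p = stats::pchisq(H, k - 1L, lower.tail = FALSE))
}

#' Default balancing covariates
#' @export
balance_covariates <- function() {
  c("size_px", "eccentricity_deg", "mean_contrast", "max_contrast",
    "min_contrast", "luminance_change", "sf_change")
}

#' Covariate balance report across the four conditions
#'
#' For each covariate, a one-way ANOVA (`F`, `p`) and a Kruskal-Wallis test
#' (`H`, `p`) across the four condition groups. The design passes when every
#' p-value (both tests, all covariates) exceeds `alpha`.
#'
#' @param scores `data.frame` with a `condition` column (4 levels, each with
#'   `>= 2` rows) and the covariate columns.
#' @param alpha significance threshold for the pass flag (default 0.05).
#' @param covariates character vector of covariate column names.
#' @return An object of class `balance_report`: a `data.frame` with one row
#'   per covariate (`F`, `df1`, `df2`, `p_anova`, `H`, `p_kruskal`) and
#'   attributes `pass` and `alpha`.
#' @export
balance_report <- function(scores, alpha = 0.05,
                           covariates = balance_covariates()) {
  stopifnot(is.data.frame(scores), "condition" %in% names(scores))
  covariates <- intersect(covariates, names(scores))
  if (length(covariates) == 0L)
    stop("no covariate columns found in scores", call. = FALSE)
  grp <- if (is.factor(scores$condition)) scores$condition
         else factor(scores$condition)
  cnt <- table(grp)
  if (nlevels(grp) < 2L || any(cnt < 2L))
    stop(structure(class = c("changescope_degenerate_report", "error", "condition"),
                   list(message = "every condition needs at least 2 pairs",
                        call = NULL)))
  rows <- lapply(covariates, function(cv) {
    a <- fast_oneway(scores[[cv]], grp)
    k <- fast_kruskal(scores[[cv]], grp)
    data.frame(covariate = cv, F = a$F, df1 = a$df1, df2 = a$df2,
               p_anova = a$p, H = k$H, p_kruskal = k$p)
  })
  rep <- do.call(rbind, rows)
  structure(rep, pass = all(rep$p_anova > alpha & rep$p_kruskal > alpha),
            alpha = alpha, class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> alpha = %.3g, pass = %s\n",
              attr(x, "alpha"), attr(x, "pass")))
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}

infeasible_design_error <- function(msg, report = NULL) {
  structure(class = c("changescope_infeasible_design", "error", "condition"),
            list(message = msg, call = NULL, report = report))
}

#' Select a covariate-balanced stimulus set
#'
#' Greedy randomized search for a subset of the candidate pool with exactly
#' `n_per_cell` pairs in each of the four median-split conditions and a
#' passing [balance_report()]. Pairs whose change region lies closer to the
#' image center than `ecc_min_deg` are dropped first. Starting from a random
#' selection, the search repeatedly swaps a selected pair against an
#' unselected pair of the same condition and keeps the swap when it raises the
#' smallest balance p-value; it stops as soon as the report passes.
#'
#' Condition labels are recomputed by median split over the selected set (the
#' single 50th-percentile line of the final design); with equal numbers
#' selected from both sides of the pool split this preserves the labels.
#'
#' @param pool `data.frame` of pair scores: `pair_id`, `ce_change`,
#'   `si_change`, the [balance_covariates()], optionally `source_image_id`
#'   and `eccentricity_deg`.
#' @param n_total number of pairs to select (default 108).
#' @param n_per_cell pairs per condition (default 27; `4 * n_per_cell` must
#'   equal `n_total`).
#' @param alpha balance threshold (default 0.05).
#' @param ecc_min_deg central exclusion radius in degrees (default 1.6).
#' @param seed RNG seed for the randomized search.
#' @param max_iter swap budget (default 10000).
#' @return An object of class `design_assignment`: list with `assignment`
#'   (`data.frame`: pool columns plus `condition`, `selected`), `report`
#'   (the final [balance_report()]), `n_iter`, `subsets` (`NULL` until
#'   [build_subsets()] is run), and the call parameters.
#' @export
select_balanced_set <- function(pool, n_total = 108L, n_per_cell = 27L,
                                alpha = 0.05, ecc_min_deg = 1.6, seed = 1L,
                                max_iter = 10000L) {
  stopifnot(is.data.frame(pool), 4L * n_per_cell == n_total)
  if (!"pair_id" %in% names(pool)) pool$pair_id <- seq_len(nrow(pool))
  if ("eccentricity_deg" %in% names(pool) && ecc_min_deg > 0)
    pool <- pool[pool$eccentricity_deg >= ecc_min_deg, , drop = FALSE]
  if (nrow(pool) < n_total)
    stop(infeasible_design_error(
      "pool smaller than n_total after the eccentricity exclusion"))
  pool <- assign_conditions(pool)
  covs <- intersect(balance_covariates(), names(pool))

  set.seed(seed)
  cells <- split(seq_len(nrow(pool)), pool$condition)
  if (any(vapply(cells, length, 1L) < n_per_cell))
    stop(infeasible_design_error("a condition cell has fewer pairs than n_per_cell"))
  sel <- lapply(cells, function(ix) sample(ix, n_per_cell))

  objective <- function(sel_idx) {
    s <- pool[sel_idx, , drop = FALSE]
    ps <- unlist(lapply(covs, function(cv) {
      c(fast_oneway(s[[cv]], s$condition)$p,
        fast_kruskal(s[[cv]], s$condition)$p)
    }))
    min(ps)
  }

  sel_idx <- unlist(sel, use.names = FALSE)
  best <- objective(sel_idx)
  n_iter <- 0L
  while (best <= alpha && n_iter < max_iter) {
    n_iter <- n_iter + 1L
    cell <- sample(names(cells), 1L)
    inside <- sel[[cell]]
    outside <- setdiff(cells[[cell]], inside)
    if (length(outside) == 0L) next
    drop_i <- sample(length(inside), 1L)
    cand <- sample(outside, 1L)
    trial <- sel
    trial[[cell]][drop_i] <- cand
    trial_idx <- unlist(trial, use.names = FALSE)
    val <- objective(trial_idx)
    if (val > best) {
      sel <- trial; sel_idx <- trial_idx; best <- val
    }
  }

  assignment <- pool
  assignment$selected <- seq_len(nrow(pool)) %in% sel_idx
  selected <- assignment[assignment$selected, , drop = FALSE]
  # recompute the split on the selected set; verify cell counts survive
  selected <- assign_conditions(selected)
  if (!all(table(selected$condition) == n_per_cell))
    stop(infeasible_design_error(
      "median split over the selected set does not preserve the cell counts"))
  assignment$condition[assignment$selected] <- selected$condition
  report <- balance_report(selected, alpha = alpha, covariates = covs)
  if (!attr(report, "pass"))
    stop(infeasible_design_error(
      sprintf("no balanced selection found within %d swaps (best min p = %.4g)",
              max_iter, best),
      report = report))
  structure(list(assignment = assignment, report = report, n_iter = n_iter,
                 n_total = n_total, n_per_cell = n_per_cell, alpha = alpha,
                 ecc_min_deg = ecc_min_deg, seed = seed, subsets = NULL),
            class = "design_assignment")
}

#' @export
print.design_assignment <- function(x, ...) {
  sel <- x$assignment[x$assignment$selected, ]
  cat(sprintf("<design_assignment> %d selected of %d pool pairs; %d swap iterations\n",
              nrow(sel), nrow(x$assignment), x$n_iter))
  print(table(sel$condition))
  if (!is.null(x$subsets))
    cat(sprintf("subsets: %d x %d pairs (usage %d per pair)\n",
                ncol(x$subsets), sum(x$subsets[, 1]),
                sum(x$subsets) / nrow(x$subsets)))
  invisible(x)
}

#' Build per-subject stimulus subsets
#'
#' Partitions (or, when `n_subsets * per_subset > n_selected`, evenly
#' re-uses) the selected pairs into `n_subsets` subsets of `per_subset`
#' pairs, with `per_subset / n_conditions` pairs per condition per subset and
#' no repeated `source_image_id` within a subset. Every pair is used in
#' exactly `n_subsets * per_subset / n_selected` subsets, which must be an
#' integer (1 makes the subsets a partition; the 108-pair, 6 x 36 layout uses
#' each pair twice).
#'
#' @param design a `design_assignment` from [select_balanced_set()].
#' @param n_subsets number of subsets (default 6).
#' @param per_subset pairs per subset (default 36).
#' @param seed RNG seed.
#' @param max_restarts restart budget of the randomized constructor.
#' @return The `design_assignment` with a logical `subsets` membership matrix
#'   (selected pairs x subsets; rownames are `pair_id`s) and a `subset_id`
#'   column on the assignment (first membership, for flat CSV export).
#' @export
build_subsets <- function(design, n_subsets = 6L, per_subset = 36L,
                          seed = 1L, max_restarts = 100L) {
  stopifnot(inherits(design, "design_assignment"))
  sel <- design$assignment[design$assignment$selected, , drop = FALSE]
  n_sel <- nrow(sel)
  conds <- levels(droplevels(factor(sel$condition)))
  k <- length(conds)
  if (per_subset %% k != 0L)
    stop(infeasible_subsets_error("per_subset not divisible by the number of conditions"))
  per_cond <- per_subset %/% k
  usage_target <- n_subsets * per_subset / n_sel
  if (usage_target != round(usage_target))
    stop(infeasible_subsets_error(
      "n_subsets * per_subset must be a multiple of the number of selected pairs"))
  usage_target <- as.integer(usage_target)
  if (!"source_image_id" %in% names(sel))
    sel$source_image_id <- sel$pair_id
  cond_idx <- split(seq_len(n_sel), factor(sel$condition, levels = conds))
  if (any(vapply(cond_idx, length, 1L) * usage_target != n_subsets * per_cond))
    stop(infeasible_subsets_error("condition cells incompatible with the subset layout"))

  src <- as.character(sel$source_image_id)
  set.seed(seed)
  for (restart in seq_len(max_restarts)) {
    usage <- integer(n_sel)
    member <- matrix(FALSE, n_sel, n_subsets)
    ok <- TRUE
    for (s in seq_len(n_subsets)) {
      remaining <- n_subsets - s + 1L
      # a source can contribute at most one pair per subset, so the summed
      # remaining need of its pairs must not exceed the remaining subsets;
      # most-constrained-first ordering keeps the end game feasible
      need <- usage_target - usage
      src_need <- tapply(need, src, sum)
      if (any(src_need > remaining)) { ok <- FALSE; break }
      used_sources <- character(0)
      for (cond in sample(conds)) {
        cand <- cond_idx[[cond]]
        cand <- cand[need[cand] > 0L]
        pick <- integer(0)
        for (t in seq_len(per_cond)) {
          cand <- cand[!(src[cand] %in% used_sources)]
          if (length(cand) == 0L) { ok <- FALSE; break }
          slack <- pmin(remaining - src_need[src[cand]],
                        remaining - need[cand])
          cand <- cand[order(slack, stats::runif(length(cand)))]
          pick <- c(pick, cand[1L])
          used_sources <- c(used_sources, src[cand[1L]])
          cand <- cand[-1L]
        }
        if (!ok) break
        member[pick, s] <- TRUE
        usage[pick] <- usage[pick] + 1L
        need <- usage_target - usage
        src_need <- tapply(need, src, sum)
      }
      if (!ok) break
    }
    if (ok && all(usage == usage_target)) {
      rownames(member) <- as.character(sel$pair_id)
      design$subsets <- member
      first <- apply(member, 1, which.max)
      design$assignment$subset_id <- NA_integer_
      design$assignment$subset_id[design$assignment$selected] <- as.integer(first)
      return(design)
    }
  }
  stop(infeasible_subsets_error(
    sprintf("no valid subset layout found in %d restarts", max_restarts)))
}

infeasible_subsets_error <- function(msg) {
  structure(class = c("changescope_infeasible_subsets", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Pairs belonging to one subset
#'
#' @param design a `design_assignment` with subsets built.
#' @param subset subset index.
#' @return The assignment rows of that subset's pairs.
#' @export
subset_members <- function(design, subset) {
  stopifnot(inherits(design, "design_assignment"), !is.null(design$subsets))
  ids <- rownames(design$subsets)[design$subsets[, subset]]
  a <- design$assignment
  a[a$selected & as.character(a$pair_id) %in% ids, , drop = FALSE]
}
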