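#' Neuron-to-cell ratios and group summaries
#'
#' Per-sample ratio of neuron count to total cell count (the whole-body
#' neuron fraction, around 10% in small animals), with mean and standard
#' error per group when a grouping column is given.
#'
#' @param table data.frame with columns `neurons` and `cells` (positive).
#' @param group optional name of a grouping column in `table`.
#' @return list with `ratios` (per-sample) and `summary` (data.frame of
#'   group, n, mean, sem).
#' @export
neuronCellRatio <- function(table, group = NULL) {
  if (any(table$cells <= 0)) stop("cell counts must be positive")
  ratios <- table$neurons / table$cells
  g <- if (is.null(group)) rep("all", length(ratios)) else table[[group]]
  agg <- do.call(rbind, lapply(split(ratios, g), function(r) {
    data.frame(n = length(r), mean = mean(r),
               sem = if (length(r) > 1) sd(r) / sqrt(length(r)) else 0)
  }))
  agg <- data.frame(group = rownames(agg), agg, row.names = NULL)
  list(ratios = ratios, summary = agg)
}

#' Allometric scaling fit with an optional breakpoint
#'
#' Ordinary least squares of `y` on `x` with one segment, or a broken-stick
#' (continuous piecewise-linear) fit with the breakpoint chosen by exhaustive
#' grid search over the observed `x` values (each candidate must leave at
#' least `min_per_segment` points per side), minimising the residual sum of
#' squares of `y ~ x + (x - c)+`. Continuity at the breakpoint is imposed
#' because counts drawn from one animal cannot jump as size crosses the
#' breakpoint; it also identifies the breakpoint far more sharply than two
#' unlinked trendlines, whose residual surface is nearly flat along the
#' split. If the two-segment fit improves the one-segment residual sum of
#' squares by less than `tolerance` (relative), no breakpoint is supported
#' and the single-segment fit is returned with `breakpoint = NA`.
#'
#' @param table data.frame containing `x` and `y` columns.
#' @param segments 1 or 2.
#' @param x,y column names (defaults `cells`, `neurons`).
#' @param min_per_segment minimum points per segment (default 5).
#' @param tolerance relative RSS improvement below which a breakpoint is
#'   rejected (default 0.10; the hinge term can soak up roughly `4/n` of the
#'   RSS on truly linear data, so the default stays above that overfitting
#'   floor for the sample sizes this package targets).
#' @return A [ScalingFit-class].
#' @export
fitScaling <- function(table, segments = 1, x = "cells", y = "neurons",
                       min_per_segment = 5, tolerance = 0.10) {
  xv <- table[[x]]; yv <- table[[y]]
  n <- length(xv)
  if (n < segments * min_per_segment)
    stop("insufficient points: need at least ", segments * min_per_segment)
  ord <- order(xv)
  xv <- xv[ord]; yv <- yv[ord]
  fit1 <- lm(yv ~ xv)
  rss1 <- sum(fit1$residuals^2)
  one <- function() new("ScalingFit",
      slopes = unname(coef(fit1)[2]), intercepts = unname(coef(fit1)[1]),
      breakpoint = NA_real_,
      residualSD = sqrt(rss1 / max(n - 2, 1)), n = as.integer(n))
  if (segments == 1) return(one())
  if (segments != 2) stop("segments must be 1 or 2")

  best <- NULL
  for (k in seq(min_per_segment, n - min_per_segment)) {
    if (xv[k] == xv[k + 1]) next   # split between distinct x only
    cand <- (xv[k] + xv[k + 1]) / 2
    hinge <- pmax(xv - cand, 0)
    f <- lm(yv ~ xv + hinge)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, bp = cand, fit = f)
    }
  }
  if (is.null(best) || (rss1 - best$rss) / max(rss1, 1e-300) < tolerance) {
    message("fitScaling: no breakpoint supported; returning single segment")
    return(one())
  }
  b <- unname(coef(best$fit))
  new("ScalingFit",
      slopes = c(b[2], b[2] + b[3]),
      intercepts = c(b[1], b[1] - b[3] * best$bp),
      breakpoint = best$bp,
      residualSD = sqrt(best$rss / max(n - 4, 1)), n = as.integer(n))
}

#' Two-sample comparison by Student's t-test
#'
#' Classical unpaired two-tailed t-test with pooled variance, plus the usual
#' significance stars (* p < 0.05, ** p < 0.01, *** p < 0.001). Two groups
#' with zero pooled variance and equal means give t = 0, p = 1 by
#' convention; zero variance with unequal means is an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `stars`, and the group means.
#' @examples
#' compareGroups(c(10, 11, 12, 13), c(20, 21, 22, 23))$t  # -12.649
#' @export
compareGroups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1, stars = "ns",
                  mean_a = mean(a), mean_b = mean(b)))
    }
    stop("zero pooled variance with unequal means: t is undefined")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       stars = stars, mean_a = mean(a), mean_b = mean(b))
}

#' Regeneration time-course summary with plateau detection
#'
#' Per-day mean and SEM of counts, and a descriptive phase annotation: with
#' per-day mean slopes `s_i` between consecutive days, the plateau phase
#' starts at the first day from which every later slope stays below
#' `slope_fraction` of the maximal early slope. Strictly linear growth has
#' no plateau (`NA`); constant counts plateau from the first day.
#'
#' @param counts data.frame with columns `day` (sortable numeric) and
#'   `count`, replicates as repeated days.
#' @param slope_fraction fraction of the maximal slope defining the plateau
#'   (default 0.1).
#' @return list with `summary` (day, n, mean, sem), `plateau_onset` (a day,
#'   or `NA`), and `phases` (increasing / plateau label per day).
#' @export
regenerationTimecourse <- function(counts, slope_fraction = 0.1) {
  days <- sort(unique(counts$day))
  if (length(days) < 3) stop("need at least 3 days")
  summ <- do.call(rbind, lapply(days, function(d) {
    v <- counts$count[counts$day == d]
    data.frame(day = d, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0)
  }))
  s <- diff(summ$mean) / diff(summ$day)
  smax <- max(s)
  if (smax <= 0) {
    onset <- days[1]
  } else {
    # plateau onset: the first day from which the slope fitted over all the
    # remaining days drops below the flatness fraction (fitting over the
    # tail averages out per-day sampling noise)
    onset <- NA_real_
    for (j in 2:(length(days) - 1)) {
      tail_days <- days[j:length(days)]
      tail_mean <- summ$mean[j:length(days)]
      fitted <- unname(coef(lm(tail_mean ~ tail_days))[2])
      if (fitted < slope_fraction * smax) { onset <- days[j]; break }
    }
  }
  phases <- ifelse(!is.na(onset) & days >= onset, "plateau", "increasing")
  list(summary = summ, plateau_onset = onset, phases = phases)
}
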