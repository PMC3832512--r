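#' Inclusion statistics of a rectangular region
#'
#' Counts the points falling inside an axis-aligned rectangle with inclusive
#' bounds and the proportion of them with a positive outcome.
#'
#' @param x,y Numeric coordinates of the points (e.g. the two predictors of
#'   the `LH-` space, in dB).
#' @param outcomes Binary outcomes (0/1), one per point.
#' @param x_lo,x_hi,y_lo,y_hi Region bounds (inclusive), `x_lo <= x_hi`,
#'   `y_lo <= y_hi`.
#' @return An object of class `region`: list with the bounds, `n_inside`,
#'   `n_positive` and `rate` (`NA` when the region is empty).
#' @export
region_stats <- function(x, y, outcomes, x_lo, x_hi, y_lo, y_hi) {
  if (x_lo > x_hi || y_lo > y_hi) stop("region bounds must be ordered")
  if (length(x) != length(y) || length(x) != length(outcomes)) {
    stop("x, y and outcomes must have the same length")
  }
  inside <- x >= x_lo & x <= x_hi & y >= y_lo & y <= y_hi
  n_in <- sum(inside)
  n_pos <- sum(outcomes[inside] == 1)
  structure(list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi,
                 n_inside = n_in, n_positive = n_pos,
                 rate = if (n_in > 0) n_pos / n_in else NA_real_),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region x: [%g, %g]  y: [%g, %g]  (%g±%g / %g±%g)\n",
              x$x_lo, x$x_hi, x$y_lo, x$y_hi,
              (x$x_lo + x$x_hi) / 2, (x$x_hi - x$x_lo) / 2,
              (x$y_lo + x$y_hi) / 2, (x$y_hi - x$y_lo) / 2))
  cat(sprintf("  n inside: %d, positive: %d, rate: %s\n",
              x$n_inside, x$n_positive,
              if (is.na(x$rate)) "undefined" else format(x$rate, digits = 3)))
  invisible(x)
}

#' Exhaustive search for the highest-yield rectangle
#'
#' Enumerates every axis-aligned rectangle whose four bounds lie on a
#' `step_db` grid (anchored at multiples of `step_db`) spanning the data
#' range, and returns, among those containing at least
#' `ceiling(min_fraction * N)` points, the one with the highest proportion of
#' positive outcomes. Ties are broken by larger `n_inside`, then smaller
#' area, then lexicographically smallest bounds, so the result is unique and
#' deterministic.
#'
#' @inheritParams region_stats
#' @param min_fraction Minimum fraction of all points the region must
#'   contain, in (0, 1\].
#' @param step_db Grid step for the candidate bounds (dB), default 5.
#' @param force Allow grids with more than 60 lines per axis (the enumeration
#'   is O(G^4) in the number of grid lines G).
#' @return The optimal `region` (see [region_stats()]).
#' @export
search_regions <- function(x, y, outcomes, min_fraction = 0.05, step_db = 5,
                           force = FALSE) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  if (step_db <= 0) stop("step_db must be positive")
  n <- length(x)
  if (n == 0) stop("no points")
  grid_lines <- function(v) {
    lo <- floor(min(v) / step_db) * step_db
    hi <- ceiling(max(v) / step_db) * step_db
    seq(lo, hi, by = step_db)
  }
  gx <- grid_lines(x)
  gy <- grid_lines(y)
  if (max(length(gx), length(gy)) > 60 && !force) {
    stop("grid has ", max(length(gx), length(gy)), " lines per axis (> 60); ",
         "increase step_db or pass force = TRUE")
  }
  need <- ceiling(min_fraction * n)
  pos <- outcomes == 1
  Gx <- length(gx)
  Gy <- length(gy)
  best <- NULL
  best_key <- NULL
  for (i in seq_len(Gx)) {
    for (j in i:Gx) {
      in_x <- x >= gx[i] & x <= gx[j]
      if (sum(in_x) < need) next
      ys <- sort(y[in_x])
      yps <- sort(y[in_x & pos])
      # counts of points (and positives) with y <= g and y < g
      nle <- findInterval(gy, ys)
      nlt <- findInterval(gy, ys, left.open = TRUE)
      ple <- findInterval(gy, yps)
      plt <- findInterval(gy, yps, left.open = TRUE)
      for (k in seq_len(Gy)) {
        n_in_col <- nle - nlt[k]          # counts for [gy[k], gy[l]], all l
        feas <- which(n_in_col >= need & seq_len(Gy) >= k)
        if (length(feas) == 0) next
        n_in <- n_in_col[feas]
        n_pos <- ple[feas] - plt[k]
        rate <- n_pos / n_in
        area <- (gx[j] - gx[i]) * (gy[feas] - gy[k])
        for (m in seq_along(feas)) {
          key <- c(-rate[m], -n_in[m], area[m], gx[i], gx[j], gy[k],
                   gy[feas[m]])
          if (is.null(best_key) || key_less(key, best_key)) {
            best_key <- key
            best <- list(i = i, j = j, k = k, l = feas[m],
                         n_in = n_in[m], n_pos = n_pos[m])
          }
        }
      }
    }
  }
  if (is.null(best)) {
    stop("infeasible: no rectangle on the grid contains at least ", need,
         " points")
  }
  structure(list(x_lo = gx[best$i], x_hi = gx[best$j],
                 y_lo = gy[best$k], y_hi = gy[best$l],
                 n_inside = best$n_in, n_positive = best$n_pos,
                 rate = best$n_pos / best$n_in),
            class = "region")
}

# lexicographic comparison of numeric keys
key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Proportions of ATR criteria met inside a region
#'
#' Given per-patient ATR values and a region in a 2-D predictor space,
#' reports the probability that the ATR reaches each criterion among the
#' patients inside — the lower half of a Table-1-style summary.
#'
#' @param x,y Point coordinates.
#' @param atr Per-patient ATR values (dB).
#' @param region A `region` object.
#' @param criteria ATR criteria in dB, default `c(30, 50, 125)`.
#' @return Named numeric vector of proportions.
#' @export
region_atr_rates <- function(x, y, atr, region, criteria = c(30, 50, 125)) {
  inside <- x >= region$x_lo & x <= region$x_hi &
    y >= region$y_lo & y <= region$y_hi
  if (sum(inside) == 0) {
    return(stats::setNames(rep(NA_real_, length(criteria)),
                           paste0("atr_ge_", criteria)))
  }
  vapply(stats::setNames(criteria, paste0("atr_ge_", criteria)),
         function(cr) mean(atr[inside] >= cr), numeric(1))
}
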