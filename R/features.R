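#' Canonical names of the 15 curve descriptors
#'
#' Ten descriptors summarize the Euler-characteristic curve and five the
#' contour-length curve; see \code{\link{extract_features}} for definitions.
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("euler_min", "euler_argmin", "euler_max", "euler_argmax",
    "euler_zero_cross", "euler_max_slope", "euler_max_slope_pos",
    "euler_area_neg", "euler_area_pos", "euler_area_total",
    "contour_max", "contour_argmax", "contour_fwhm",
    "contour_area", "contour_centroid")
}

#' Reduce a Minkowski curve to 15 scalar descriptors
#'
#' Compresses the 256-level Euler-characteristic and contour-length curves to
#' the geometric quantities that carry the grading signal: extremum values and
#' positions, the zero crossing, a steepness measure, and areas under the
#' curves.
#'
#' From the Euler curve e(t): \describe{
#'   \item{euler_min / euler_argmin}{minimum value and its gray level}
#'   \item{euler_max / euler_argmax}{maximum value and its gray level}
#'   \item{euler_zero_cross}{first level t > argmin with e(t) >= 0;
#'     255 if none (saturation convention)}
#'   \item{euler_max_slope / euler_max_slope_pos}{largest forward difference
#'     of the smoothed curve between argmin and argmax, and its level; the
#'     curve is smoothed with a centered moving average of
#'     \code{smooth_window} levels before differencing so the slope position
#'     is not noise-dominated}
#'   \item{euler_area_neg / euler_area_pos / euler_area_total}{sum of the
#'     negative part, of the positive part, and the total signed sum}
#' }
#' From the contour curve P(t): maximum value and its gray level, full width
#' at half maximum (distance between the first and last level with
#' P >= max/2), total area, and centroid sum(t * P(t)) / sum(P(t)).
#'
#' Ties in extrema resolve to the lowest gray level. Degenerate all-zero
#' curves yield 0 for all descriptors of that curve.
#'
#' @param curve A \code{\link{minkowski_curve}}.
#' @param smooth_window Moving-average window (gray levels) applied before
#'   the slope features; default 5.
#' @return Named numeric vector of length 15 (see \code{\link{feature_names}}).
#' @export
extract_features <- function(curve, smooth_window = 5L) {
  if (!inherits(curve, "minkowski_curve")) stop("expected a minkowski_curve")
  e <- curve$euler
  p <- curve$contour_length
  f <- stats::setNames(numeric(15L), feature_names())

  if (any(e != 0)) {
    amin <- which.min(e) - 1L
    amax <- which.max(e) - 1L
    f["euler_min"] <- min(e)
    f["euler_argmin"] <- amin
    f["euler_max"] <- max(e)
    f["euler_argmax"] <- amax
    after <- if (amin < 255L) which(e[(amin + 2L):256L] >= 0)[1L] else NA
    f["euler_zero_cross"] <- if (is.na(after)) 255 else amin + after
    es <- moving_average(e, smooth_window)
    d <- diff(es)                     # d[i] = slope at level t = i - 1
    rng <- if (amin < amax) (amin + 1L):amax else seq_along(d)
    f["euler_max_slope"] <- max(d[rng])
    f["euler_max_slope_pos"] <- rng[which.max(d[rng])] - 1L
    f["euler_area_neg"] <- sum(pmin(e, 0))
    f["euler_area_pos"] <- sum(pmax(e, 0))
    f["euler_area_total"] <- sum(e)
  }

  if (any(p != 0)) {
    pmax_val <- max(p)
    f["contour_max"] <- pmax_val
    f["contour_argmax"] <- which.max(p) - 1L
    at_half <- which(p >= pmax_val / 2)
    f["contour_fwhm"] <- max(at_half) - min(at_half)
    f["contour_area"] <- sum(p)
    f["contour_centroid"] <- sum((0:255) * p) / sum(p)
  }
  f
}

# centered moving average with shrunken windows at the edges
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Feature table for a set of curves
#'
#' @param curves List of \code{\link{minkowski_curve}} objects.
#' @param labels Optional vector of class labels (\code{"gradeII"} /
#'   \code{"gradeIV"}), recycled against the curves; NA for unlabeled.
#' @param smooth_window Passed to \code{\link{extract_features}}.
#' @return Data frame with columns sample_id, label and the 15 features.
#' @export
extract_feature_table <- function(curves, labels = NULL, smooth_window = 5L) {
  curves <- as_curve_list(curves)
  if (is.null(labels)) labels <- NA_character_
  labels <- rep_len(as.character(labels), length(curves))
  rows <- lapply(seq_along(curves), function(i) {
    f <- extract_features(curves[[i]], smooth_window)
    cbind(data.frame(sample_id = curves[[i]]$sample_id,
                     label = labels[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}

#' Per-level group statistics of Minkowski curves
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' Euler and contour-length curves across a group of images, per gray level.
#' The mean +/- 1 sd envelope is the "1 sigma band" used to locate gray-level
#' regions where two tumor grades do not overlap.
#'
#' @param curves List of at least two \code{\link{minkowski_curve}} objects.
#' @param label Group label string.
#' @return Object of class \code{group_curve_stats} with per-level
#'   \code{euler_mean}, \code{euler_sd}, \code{contour_mean},
#'   \code{contour_sd}, the group size \code{n}, and the extrema of the mean
#'   curves with their positions.
#' @export
group_stats <- function(curves, label = "group") {
  curves <- as_curve_list(curves)
  if (length(curves) < 2L) {
    stop("group_stats needs at least 2 curves (sd undefined otherwise)")
  }
  em <- vapply(curves, function(cv) cv$euler, numeric(256L))
  pm <- vapply(curves, function(cv) cv$contour_length, numeric(256L))
  euler_mean <- rowMeans(em)
  contour_mean <- rowMeans(pm)
  structure(
    list(label = label,
         n = length(curves),
         level = 0:255,
         euler_mean = euler_mean,
         euler_sd = apply(em, 1L, stats::sd),
         contour_mean = contour_mean,
         contour_sd = apply(pm, 1L, stats::sd),
         euler_min = min(euler_mean),
         euler_min_level = which.min(euler_mean) - 1L,
         euler_max = max(euler_mean),
         euler_max_level = which.max(euler_mean) - 1L,
         contour_max = max(contour_mean),
         contour_max_level = which.max(contour_mean) - 1L),
    class = "group_curve_stats")
}

#' @export
print.group_curve_stats <- function(x, ...) {
  cat(sprintf("Group '%s' (n = %d curves)\n", x$label, x$n))
  cat(sprintf("  mean Euler minimum %s at gray level %d\n",
              format(round(x$euler_min)), x$euler_min_level))
  cat(sprintf("  mean Euler maximum %s at gray level %d\n",
              format(round(x$euler_max)), x$euler_max_level))
  cat(sprintf("  mean contour-length maximum %s at gray level %d\n",
              format(signif(x$contour_max, 3)), x$contour_max_level))
  invisible(x)
}

#' Ratios of the mean-curve Euler extremes between two groups
#'
#' Divides the signed extremes of the two groups' mean Euler curves:
#' \code{min_ratio = min_a / min_b} and \code{max_ratio = max_a / max_b}.
#' Like-signed extremes give positive ratios. The report rounds to 2 decimals.
#'
#' @param a,b \code{group_curve_stats} objects.
#' @return List with \code{min_ratio}, \code{max_ratio} (raw), a 2-decimal
#'   \code{report} data frame, and \code{undefined} = TRUE when a denominator
#'   extreme is zero (ratios are NA in that case).
#' @export
compare_group_extremes <- function(a, b) {
  stopifnot(inherits(a, "group_curve_stats"), inherits(b, "group_curve_stats"))
  undefined <- (b$euler_min == 0) || (b$euler_max == 0)
  min_ratio <- if (b$euler_min == 0) NA_real_ else a$euler_min / b$euler_min
  max_ratio <- if (b$euler_max == 0) NA_real_ else a$euler_max / b$euler_max
  list(
    min_ratio = min_ratio,
    max_ratio = max_ratio,
    undefined = undefined,
    report = data.frame(
      group_a = a$label, group_b = b$label,
      min_a = a$euler_min, min_b = b$euler_min,
      min_ratio = round(min_ratio, 2),
      max_a = a$euler_max, max_b = b$euler_max,
      max_ratio = round(max_ratio, 2)))
}

#' Gray-level bands where two groups' 1-sigma Euler bands do not overlap
#'
#' Finds the maximal contiguous runs of gray levels t where the intervals
#' [mean_a - sd_a, mean_a + sd_a] and [mean_b - sd_b, mean_b + sd_b] of the
#' Euler curves are disjoint. Such a band marks levels at which a single mean
#' Euler value already separates the groups.
#'
#' @param a,b \code{group_curve_stats} objects.
#' @return Data frame with columns \code{start}, \code{end} (inclusive gray
#'   levels), zero rows when the bands always intersect. Intervals are
#'   disjoint, sorted, and within \code{[0, 255]}.
#' @export
find_nonoverlap_band <- function(a, b) {
  stopifnot(inherits(a, "group_curve_stats"), inherits(b, "group_curve_stats"))
  lo_a <- a$euler_mean - a$euler_sd
  hi_a <- a$euler_mean + a$euler_sd
  lo_b <- b$euler_mean - b$euler_sd
  hi_b <- b$euler_mean + b$euler_sd
  disjoint <- (lo_a > hi_b) | (lo_b > hi_a)
  r <- rle(disjoint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

#' Mean Euler value over a gray-level band
#'
#' The scalar used for single-feature classification: the average of the Euler
#' curve over the levels of a (typically non-overlap) band.
#'
#' @param curve A \code{\link{minkowski_curve}}.
#' @param band Length-2 integer vector \code{c(start, end)}, inclusive, within
#'   \code{[0, 255]} and non-empty.
#' @return Mean Euler value over the band.
#' @export
band_feature <- function(curve, band) {
  if (!inherits(curve, "minkowski_curve")) stop("expected a minkowski_curve")
  if (length(band) != 2L || anyNA(band) || band[1L] > band[2L] ||
      band[1L] < 0 || band[2L] > 255 || any(band != round(band))) {
    stop("band must be a non-empty integer interval within [0, 255]")
  }
  mean(curve$euler[(band[1L]:band[2L]) + 1L])
}

#' Plot the mean Euler curves of two groups with 1-sigma bands
#'
#' @param a,b \code{group_curve_stats} objects.
#' @param which \code{"euler"} or \code{"contour"}.
#' @return Invisibly, NULL. Base-graphics side effect.
#' @export
plot_group_curves <- function(a, b, which = c("euler", "contour")) {
  which <- match.arg(which)
  m_a <- a[[paste0(which, "_mean")]]; s_a <- a[[paste0(which, "_sd")]]
  m_b <- b[[paste0(which, "_mean")]]; s_b <- b[[paste0(which, "_sd")]]
  ylim <- range(m_a - s_a, m_a + s_a, m_b - s_b, m_b + s_b)
  t <- 0:255
  plot(t, m_a, type = "l", col = "red", ylim = ylim, xlab = "gray level",
       ylab = if (which == "euler") "Euler characteristic"
              else "contour length [pixel edges]")
  graphics::lines(t, m_a - s_a, col = "red", lty = 2)
  graphics::lines(t, m_a + s_a, col = "red", lty = 2)
  graphics::lines(t, m_b, col = "darkgreen")
  graphics::lines(t, m_b - s_b, col = "darkgreen", lty = 2)
  graphics::lines(t, m_b + s_b, col = "darkgreen", lty = 2)
  graphics::legend("topright", legend = c(a$label, b$label),
                   col = c("red", "darkgreen"), lty = 1, bty = "n")
  invisible(NULL)
}
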