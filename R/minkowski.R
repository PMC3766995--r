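#' Threshold a gray image into a binary level set
#'
#' A pixel is foreground iff its gray value is >= t. Bright (raised) structure
#' is therefore foreground and dark cavities are background, so cavity
#' formation drives holes and components in the Euler characteristic.
#'
#' @param img Integer gray-image matrix with values in \code{[0, 255]}.
#' @param t Threshold level, integer in \code{[0, 255]}.
#' @return Logical matrix, TRUE = foreground.
#' @export
threshold_level_set <- function(img, t) {
  check_gray_image(img)
  if (length(t) != 1L || is.na(t) || t != round(t) || t < 0 || t > 255) {
    stop("threshold t must be a single integer in [0, 255]")
  }
  img >= t
}

#' Covered area of a binary image
#'
#' First 2-D Minkowski functional: the number of foreground pixels.
#'
#' @param mask Logical matrix.
#' @return Integer pixel count.
#' @export
area <- function(mask) {
  check_mask(mask)
  sum(mask)
}

#' Contour length of a binary image
#'
#' Second 2-D Minkowski functional: the number of unit pixel edges separating
#' a foreground pixel from a background pixel. The image exterior counts as
#' background, so foreground pixels on the border contribute their outward
#' edges. No Crofton-type correction is applied; the unit is pixel edges.
#'
#' @param mask Logical matrix.
#' @return Integer edge count.
#' @export
contour_length <- function(mask) {
  check_mask(mask)
  p <- pad_false(mask)
  nr <- nrow(p)
  nc <- ncol(p)
  horiz <- sum(xor(p[, -nc], p[, -1L]))
  vert <- sum(xor(p[-nr, ], p[-1L, ]))
  as.integer(horiz + vert)
}

#' Euler characteristic of a binary image
#'
#' Third 2-D Minkowski functional: the number of connected foreground objects
#' minus the number of holes inside them, under the standard complementary
#' connectivity pair (foreground 8-connected, background/holes 4-connected).
#' Background connected to the image exterior is never a hole.
#'
#' Computed by 2x2 quad-pattern counting on the background-padded mask:
#' chi = (Q1 - Q3 - 2 * Qd) / 4, where Q1/Q3 count quads with exactly one /
#' three foreground pixels and Qd counts diagonal quads. This equals the
#' labeling definition (8-connected components minus 4-connected interior
#' background components) on every input.
#'
#' @param mask Logical matrix.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  check_mask(mask)
  p <- pad_false(mask)
  nr <- nrow(p)
  nc <- ncol(p)
  a <- p[-nr, -nc]
  b <- p[-nr, -1L]
  cc <- p[-1L, -nc]
  d <- p[-1L, -1L]
  s <- a + b + cc + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a & d) | (b & cc)))
  chi4 <- q1 - q3 - 2L * qd
  if (chi4 %% 4L != 0L) stop("internal error: quad count not divisible by 4")
  as.integer(chi4 %/% 4L)
}

#' Minkowski functional curves over all 256 threshold levels
#'
#' Thresholds the gray image at every level t = 0..255 (foreground = gray
#' >= t) and records the three functionals of the resulting level set,
#' producing the area, contour-length and Euler-characteristic curves. The
#' result is identical to calling \code{\link{threshold_level_set}},
#' \code{\link{area}}, \code{\link{contour_length}} and
#' \code{\link{euler_characteristic}} per level, but is computed in a single
#' O(N) sweep: every pixel, pixel adjacency and 2x2 quad contributes to a
#' contiguous threshold interval, accumulated with difference arrays.
#'
#' By construction area[0] = n_rows * n_cols, euler[0] = 1 and
#' contour[0] = 2 * (n_rows + n_cols); area is non-increasing in t.
#'
#' @param img Integer gray-image matrix with values in \code{[0, 255]}.
#' @param sample_id Identifier stored in the curve object.
#' @return A \code{\link{minkowski_curve}}.
#' @export
minkowski_curves <- function(img, sample_id = "sample") {
  check_gray_image(img)
  nr <- nrow(img)
  nc <- ncol(img)

  # area(t) = #pixels with value >= t
  h <- tabulate(as.vector(img) + 1L, nbins = 256L)
  area_curve <- rev(cumsum(rev(h)))

  # exterior modeled as value -1: always background, never contributes edges
  p <- matrix(-1L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- img

  # contour: adjacent pair (a,b) is a boundary edge for t in [min+1, max]
  pr <- nrow(p)
  pc <- ncol(p)
  ha <- p[, -pc]; hb <- p[, -1L]
  va <- p[-pr, ]; vb <- p[-1L, ]
  mn <- c(pmin(ha, hb), pmin(va, vb))
  mx <- c(pmax(ha, hb), pmax(va, vb))
  contour_curve <- interval_counts(mn + 1L, mx)

  # euler: per 2x2 quad, the pattern changes only at the 4 sorted cell values
  a <- p[-pr, -pc]
  b <- p[-pr, -1L]
  cc <- p[-1L, -pc]
  d <- p[-1L, -1L]
  lo1 <- pmin(a, b); hi1 <- pmax(a, b)
  lo2 <- pmin(cc, d); hi2 <- pmax(cc, d)
  s1 <- pmin(lo1, lo2)
  s4 <- pmax(hi1, hi2)
  m1 <- pmax(lo1, lo2)
  m2 <- pmin(hi1, hi2)
  s2 <- pmin(m1, m2)
  s3 <- pmax(m1, m2)
  # exactly one fg: t in [s3+1, s4]; exactly three: t in [s1+1, s2];
  # diagonal pair: t in [s2+1, s3] and the two top cells lie on a diagonal
  n1 <- interval_counts(s3 + 1L, s4)
  n3 <- interval_counts(s1 + 1L, s2)
  diag_quad <- (a >= s3 & d >= s3) | (b >= s3 & cc >= s3)
  nd <- interval_counts(s2[diag_quad] + 1L, s3[diag_quad])
  euler_curve <- (n1 - n3 - 2 * nd) / 4

  minkowski_curve(sample_id,
                  area = area_curve,
                  contour_length = contour_curve,
                  euler = euler_curve)
}

# For integer interval bounds, count per t in 0..255 how many intervals
# [start_i, end_i] cover t. Empty intervals (start > end) contribute nothing.
interval_counts <- function(starts, ends) {
  keep <- starts <= ends
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0L) return(numeric(256L))
  # shift t=0..255 to bins 1..256; removal at end+2 may fall off the table
  delta <- tabulate(pmax(starts, 0L) + 1L, nbins = 256L) -
    tabulate(ends + 2L, nbins = 256L)
  cumsum(delta)
}

pad_false <- function(mask) {
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  p
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask)) {
    stop("mask must be a logical matrix without NAs")
  }
  invisible(mask)
}
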