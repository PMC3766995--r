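#' First-order flattening of a height map
#'
#' Removes the instrument background slope before gray-level analysis. The
#' default fits a single global plane z = a + b*col + c*row by ordinary least
#' squares over all pixels and returns the residual grid, which has zero mean
#' up to floating-point error. \code{method = "line"} instead levels each scan
#' line (image row) independently with its own first-order fit, the way many
#' AFM packages do; \code{method = "none"} returns the input unchanged.
#'
#' Flattening with \code{method = "plane"} is invariant to adding any plane to
#' the input.
#'
#' @param hm Numeric height-map matrix (see \code{\link{as_height_map}}).
#' @param method \code{"plane"} (default), \code{"line"} or \code{"none"}.
#' @return Height-map matrix of residuals, same shape as the input.
#' @export
flatten_first_order <- function(hm, method = c("plane", "line", "none")) {
  method <- match.arg(method)
  hm <- as_height_map(hm)
  if (method == "none") return(hm)
  nr <- nrow(hm)
  nc <- ncol(hm)
  if (method == "plane") {
    # 0-based pixel coordinates; design matrix [1, col, row]
    col_idx <- rep(0:(nc - 1L), each = nr)
    row_idx <- rep(0:(nr - 1L), times = nc)
    X <- cbind(1, col_idx, row_idx)
    fit <- stats::lm.fit(X, as.vector(hm))
    res <- matrix(fit$residuals, nrow = nr, ncol = nc)
  } else {
    cols <- 0:(nc - 1L)
    res <- t(apply(hm, 1L, function(z) stats::lm.fit(cbind(1, cols), z)$residuals))
  }
  keep_hm_attrs(res, hm)
}

#' Histogram equalization to 256 gray levels
#'
#' Spreads the (typically Gaussian-shaped) height histogram over the full
#' dynamic range of 256 gray levels with a rank-based cumulative mapping: a
#' pixel of height v maps to \code{floor(256 * C(v) / N)} clipped to 255,
#' where C(v) is the number of pixels with height <= v and N is the pixel
#' count. The mapping is monotone non-decreasing in v, so level sets of the
#' output are level sets of the input. A constant image maps to all 255 by
#' this convention. Heights are ranked at full numeric precision.
#'
#' @param hm Numeric height-map matrix.
#' @return Integer matrix of gray levels in \code{[0, 255]}, same shape.
#' @export
equalize_histogram <- function(hm) {
  hm <- as_height_map(hm)
  n <- length(hm)
  cum_count <- rank(as.vector(hm), ties.method = "max")
  g <- pmin(255L, as.integer(256 * cum_count / n))
  keep_hm_attrs(matrix(g, nrow = nrow(hm), ncol = ncol(hm)), hm)
}

# carry provenance attributes through preprocessing
keep_hm_attrs <- function(out, src) {
  for (a in c("source_path", "pixel_size")) {
    if (!is.null(attr(src, a))) attr(out, a) <- attr(src, a)
  }
  out
}

# validate a gray image: integer matrix in [0, 255]
check_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) stop("gray image must be a numeric matrix")
  if (anyNA(img) || any(img != round(img)) || min(img) < 0 || max(img) > 255) {
    stop("gray image values must be integers in [0, 255]")
  }
  invisible(img)
}
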