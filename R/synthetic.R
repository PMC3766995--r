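#' Parameters for the synthetic tissue-texture generator
#'
#' Builds the parameter set describing one synthetic AFM-like height map. The
#' two grade presets emulate the morphologies that drive the grading signal:
#' \describe{
#'   \item{gradeII}{a dense meshwork of fine fibrous ridges (the neuropil)
#'     with many small nucleus-like bumps and small, sparse cavities}
#'   \item{gradeIV}{a pulpy mass: few fibers, fewer nuclei, and a handful of
#'     irregular large-scale cavities from necrotic tissue loss}
#' }
#' Counts are stated for a 512 x 512 frame and scale with the imaged area
#' (\code{(image_size/512)^2}) so that smaller frames emulate a smaller field
#' of view over the same tissue; feature sizes in pixels stay fixed, except
#' that cavity radii are capped at a quarter of the frame. Heights are in
#' arbitrary instrument units; only their ordering matters after rank
#' equalization.
#'
#' @param grade \code{"gradeII"} or \code{"gradeIV"}.
#' @param image_size Side length in pixels (square frame), default 512.
#' @param filament_count Number of fibrous ridges (at 512 scale).
#' @param filament_thickness Ridge thickness in pixels.
#' @param filament_height Ridge height.
#' @param nuclei_count Number of nucleus bumps (at 512 scale).
#' @param nucleus_radius Length-2 range of bump radii in pixels.
#' @param nucleus_height Bump peak height.
#' @param cavity_count Number of cavities (at 512 scale).
#' @param cavity_radius Length-2 range of cavity base radii in pixels.
#' @param cavity_depth Cavity depth.
#' @param slope_range Maximum background plane relief per axis across the
#'   frame (height units).
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise.
#' @param seed Seed for this image.
#' @return List of class \code{texture_params}.
#' @export
texture_params <- function(grade = c("gradeII", "gradeIV"),
                           image_size = 512L,
                           filament_count = NULL,
                           filament_thickness = NULL,
                           filament_height = NULL,
                           nuclei_count = NULL,
                           nucleus_radius = NULL,
                           nucleus_height = NULL,
                           cavity_count = NULL,
                           cavity_radius = NULL,
                           cavity_depth = NULL,
                           slope_range = 1.5,
                           noise_sd = 0.03,
                           seed = 1L) {
  grade <- match.arg(grade)
  defaults <- if (grade == "gradeII") {
    list(filament_count = 140, filament_thickness = 3, filament_height = 0.6,
         nuclei_count = 90, nucleus_radius = c(4, 8), nucleus_height = 0.9,
         cavity_count = 28, cavity_radius = c(4, 12), cavity_depth = 1.0)
  } else {
    list(filament_count = 20, filament_thickness = 4, filament_height = 0.4,
         nuclei_count = 24, nucleus_radius = c(5, 10), nucleus_height = 0.7,
         cavity_count = 12, cavity_radius = c(25, 70), cavity_depth = 1.2)
  }
  p <- list(grade = grade,
            image_size = as.integer(image_size),
            filament_count = filament_count %||% defaults$filament_count,
            filament_thickness = filament_thickness %||% defaults$filament_thickness,
            filament_height = filament_height %||% defaults$filament_height,
            nuclei_count = nuclei_count %||% defaults$nuclei_count,
            nucleus_radius = nucleus_radius %||% defaults$nucleus_radius,
            nucleus_height = nucleus_height %||% defaults$nucleus_height,
            cavity_count = cavity_count %||% defaults$cavity_count,
            cavity_radius = cavity_radius %||% defaults$cavity_radius,
            cavity_depth = cavity_depth %||% defaults$cavity_depth,
            slope_range = slope_range,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  stopifnot(p$image_size >= 8L,
            p$filament_count >= 0, p$nuclei_count >= 0, p$cavity_count >= 0,
            length(p$nucleus_radius) == 2L, all(p$nucleus_radius >= 1),
            length(p$cavity_radius) == 2L, all(p$cavity_radius >= 1),
            p$noise_sd >= 0)
  class(p) <- "texture_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic tissue-texture height map
#'
#' Composes, on a tilted plane background: fibrous ridges laid down as
#' persistent (correlated) random walks of fixed thickness and positive
#' height, so that dense fiber populations form a junction-rich meshwork;
#' smooth positive Gaussian bumps for nuclei; irregular negative depressions
#' for cavities, whose outline radius varies around the polygon by random
#' low-order harmonics; and additive i.i.d. Gaussian pixel noise. Raised
#' structure combines by elementwise maximum (a ridge crossing a bump does
#' not stack), cavities subtract from the result. Deterministic given
#' \code{params$seed}.
#'
#' @param params A \code{\link{texture_params}}.
#' @return Height-map matrix of size \code{image_size x image_size}.
#' @export
generate_tissue_image <- function(params) {
  stopifnot(inherits(params, "texture_params"))
  n <- params$image_size
  set.seed(params$seed)
  area_scale <- (n / 512)^2

  # tilted plane background
  bx <- stats::runif(1L, -params$slope_range, params$slope_range) / n
  by <- stats::runif(1L, -params$slope_range, params$slope_range) / n
  cols <- matrix(rep(0:(n - 1L), each = n), n, n)
  rows <- matrix(rep(0:(n - 1L), times = n), n, n)
  hm <- bx * cols + by * rows

  relief <- matrix(0, n, n)

  # fibrous ridges: correlated random walks stamped with a disc footprint
  n_fil <- round(params$filament_count * area_scale)
  if (n_fil > 0 && params$filament_height > 0) {
    disc <- disc_offsets(params$filament_thickness / 2)
    n_steps <- round(1.5 * n)
    for (i in seq_len(n_fil)) {
      x0 <- stats::runif(1L, 1, n)
      y0 <- stats::runif(1L, 1, n)
      theta <- stats::runif(1L, 0, 2 * pi) +
        cumsum(stats::rnorm(n_steps, 0, 0.15))
      xs <- round(x0 + cumsum(cos(theta)))
      ys <- round(y0 + cumsum(sin(theta)))
      h <- params$filament_height * stats::runif(1L, 0.8, 1.2)
      relief <- stamp_max(relief, xs, ys, disc, h)
    }
  }

  # nuclei: smooth positive bumps
  n_nuc <- round(params$nuclei_count * area_scale)
  for (i in seq_len(n_nuc)) {
    r <- stats::runif(1L, params$nucleus_radius[1L], params$nucleus_radius[2L])
    cx <- stats::runif(1L, 1, n)
    cy <- stats::runif(1L, 1, n)
    h <- params$nucleus_height * stats::runif(1L, 0.8, 1.2)
    bump <- gaussian_bump(n, cx, cy, r, h)
    relief[bump$idx] <- pmax(relief[bump$idx], bump$val)
  }

  hm <- hm + relief

  # cavities: irregular depressions with randomized polar outline
  n_cav <- round(params$cavity_count * area_scale)
  r_cap <- n / 4
  for (i in seq_len(n_cav)) {
    r0 <- min(stats::runif(1L, params$cavity_radius[1L],
                           params$cavity_radius[2L]), r_cap)
    cx <- stats::runif(1L, 1, n)
    cy <- stats::runif(1L, 1, n)
    depth <- params$cavity_depth * stats::runif(1L, 0.8, 1.2)
    hm <- hm - cavity_field(n, cx, cy, r0, depth)
  }

  if (params$noise_sd > 0) {
    hm <- hm + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
  }
  hm
}

# integer offsets of a filled disc of the given radius (at least one pixel)
disc_offsets <- function(radius) {
  r <- max(0L, ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= max(radius, 0.5)^2, , drop = FALSE]
  g
}

# set relief[path + disc] to at least h (rows = y, cols = x)
stamp_max <- function(relief, xs, ys, disc, h) {
  n <- nrow(relief)
  px <- rep(xs, each = nrow(disc)) + disc$dx
  py <- rep(ys, each = nrow(disc)) + disc$dy
  ok <- px >= 1 & px <= n & py >= 1 & py <= n
  idx <- py[ok] + (px[ok] - 1L) * n
  relief[idx] <- pmax(relief[idx], h)
  relief
}

gaussian_bump <- function(n, cx, cy, r, h) {
  ext <- ceiling(3 * r)
  x <- max(1, floor(cx - ext)):min(n, ceiling(cx + ext))
  y <- max(1, floor(cy - ext)):min(n, ceiling(cy + ext))
  dx <- matrix(rep(x - cx, each = length(y)), length(y))
  dy <- matrix(rep(y - cy, times = length(x)), length(y))
  val <- h * exp(-(dx^2 + dy^2) / (2 * r^2))
  idx <- as.vector(outer(y, (x - 1L) * n, "+"))
  list(idx = idx, val = as.vector(val))
}

# depression with irregular outline: radius modulated by low-order harmonics,
# depth tapering smoothly (raised cosine) from the center to the rim
cavity_field <- function(n, cx, cy, r0, depth) {
  amp <- stats::runif(3L, 0, 0.15)
  phase <- stats::runif(3L, 0, 2 * pi)
  rmax <- r0 * (1 + sum(amp))
  ext <- ceiling(rmax)
  x <- max(1, floor(cx - ext)):min(n, ceiling(cx + ext))
  y <- max(1, floor(cy - ext)):min(n, ceiling(cy + ext))
  dx <- matrix(rep(x - cx, each = length(y)), length(y))
  dy <- matrix(rep(y - cy, times = length(x)), length(y))
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  r_out <- r0 * (1 + amp[1L] * cos(2 * th + phase[1L]) +
                   amp[2L] * cos(3 * th + phase[2L]) +
                   amp[3L] * cos(4 * th + phase[3L]))
  frac <- pmin(r / r_out, 1)
  field <- matrix(0, n, n)
  local <- depth * 0.5 * (1 + cos(pi * frac)) * (frac < 1)
  idx <- as.vector(outer(y, (x - 1L) * n, "+"))
  field[idx] <- as.vector(local)
  field
}

#' Generate a labeled synthetic dataset
#'
#' Produces \code{n_gradeII + n_gradeIV} height maps with per-image seeds
#' derived from the master seed and per-image jitter of +/-20 percent
#' (uniform) on structure counts and radii, creating within-class variance.
#' Deterministic given \code{seed}.
#'
#' @param n_gradeII,n_gradeIV Images per class; the reference study sizes are
#'   54 and 59.
#' @param seed Master seed.
#' @param image_size Side length in pixels.
#' @param ... Further overrides passed to \code{\link{texture_params}}.
#' @return List with \code{images} (list of height maps), \code{manifest}
#'   (data frame: sample_id, label, seed, params JSON string).
#' @export
generate_dataset <- function(n_gradeII = 54L, n_gradeIV = 59L, seed = 1L,
                             image_size = 512L, ...) {
  stopifnot(n_gradeII >= 0L, n_gradeIV >= 0L)
  labels <- c(rep("gradeII", n_gradeII), rep("gradeIV", n_gradeIV))
  n_tot <- length(labels)
  set.seed(seed)
  img_seeds <- if (n_tot > 0L) sample.int(2^31 - 1L, n_tot) else integer(0L)
  jitter <- function(v) v * stats::runif(length(v), 0.8, 1.2)

  images <- vector("list", n_tot)
  manifest <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    base <- texture_params(grade = labels[i], image_size = image_size,
                           seed = img_seeds[i], ...)
    base$filament_count <- jitter(base$filament_count)
    base$nuclei_count <- jitter(base$nuclei_count)
    base$cavity_count <- jitter(base$cavity_count)
    base$nucleus_radius <- sort(jitter(base$nucleus_radius))
    base$cavity_radius <- sort(jitter(base$cavity_radius))
    images[[i]] <- generate_tissue_image(base)
    manifest[[i]] <- data.frame(
      sample_id = sprintf("%s_%03d", labels[i], i),
      label = labels[i],
      seed = img_seeds[i],
      params = as.character(jsonlite::toJSON(unclass(base),
                                             auto_unbox = TRUE, digits = 6)),
      stringsAsFactors = FALSE)
  }
  manifest <- if (n_tot > 0L) do.call(rbind, manifest) else
    data.frame(sample_id = character(0L), label = character(0L),
               seed = integer(0L), params = character(0L))
  names(images) <- manifest$sample_id
  list(images = images, manifest = manifest)
}
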