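#' Read a height map from a raster image or text matrix
#'
#' Reads a 2-D grid of surface heights from either a single-channel grayscale
#' raster image (PNG or TIFF, 8- or 16-bit) or a whitespace-delimited numeric
#' text matrix in the style of AFM ASCII exports. Raster integer samples are
#' used as heights verbatim (no rescaling); text values are parsed as doubles.
#' Lines starting with \code{#} in text files are treated as comments.
#'
#' The grid follows the usual raster convention: row 0 of the file is the top
#' image row (R index 1), column 0 the left column. Reading never transposes
#' or flips the grid.
#'
#' @param path Path to the input file.
#' @param format One of \code{"auto"} (decide from the file extension),
#'   \code{"raster"} or \code{"text"}.
#' @param pixel_size Optional physical pixel edge length in micrometers,
#'   attached as an attribute.
#' @return A numeric matrix of heights with attributes \code{source_path} and
#'   (if given) \code{pixel_size}. At least 8 rows and 8 columns are required.
#' @export
read_height_map <- function(path, format = c("auto", "raster", "text"),
                            pixel_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read height map: file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("png", "tif", "tiff")) "raster" else "text"
  }
  values <- if (format == "raster") {
    read_raster_matrix(path)
  } else {
    read_text_matrix(path)
  }
  as_height_map(values, source_path = path, pixel_size = pixel_size)
}

#' Write a height map to disk
#'
#' Text output (`.txt`, `.dat`, `.asc` or anything non-raster) is a
#' whitespace-delimited matrix printed with 10 significant digits, one image
#' row per line. Raster output requires non-negative integer heights and
#' stores the samples verbatim: PNG is written 8-bit (values in
#' \code{[0, 255]}), TIFF at the requested bit depth (8 or 16).
#'
#' @param hm Numeric height-map matrix.
#' @param path Output path; the extension selects the format.
#' @param bits Bit depth for TIFF output (8 or 16); PNG is always 8-bit.
#' @return \code{path}, invisibly.
#' @export
write_height_map <- function(hm, path, bits = 8) {
  hm <- as_height_map(hm)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff")) {
    if (any(hm != round(hm)) || min(hm) < 0) {
      stop("raster output requires non-negative integer heights")
    }
    maxval <- if (ext != "png" && bits == 16) 65535 else 255
    if (max(hm) > maxval) stop("heights exceed the raster range (", maxval, ")")
    if (ext == "png") {
      png::writePNG(hm / maxval, target = path)
    } else {
      tiff::writeTIFF(hm / maxval, path,
                      bits.per.sample = if (maxval == 65535) 16L else 8L)
    }
  } else {
    lines <- apply(hm, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

# Raster input: single-channel grayscale PNG/TIFF, raw integer samples.
read_raster_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 26L)
    bit_depth <- as.integer(hdr[25L])
    color_type <- as.integer(hdr[26L])
    if (color_type != 0L) {
      stop("format error: PNG is not single-channel grayscale (color type ",
           color_type, ")")
    }
    img <- png::readPNG(path)
    if (length(dim(img)) != 2L) {
      stop("format error: multi-channel raster input")
    }
    round(img * (2^bit_depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L) {
      stop("format error: multi-channel raster input")
    }
    img + 0.0
  } else {
    stop("unsupported raster extension: ", ext)
  }
}

# Text-matrix input: whitespace-delimited rows, '#' comment lines ignored.
read_text_matrix <- function(path) {
  raw_lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw_lines)
  lines <- raw_lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("format error: no data rows in ", path)
  rows <- strsplit(trimws(lines), "\\s+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("format error: ragged row at line ", line_no[bad], " of ", path,
         " (", widths[bad], " values, expected ", widths[1L], ")")
  }
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1L)))
  if (length(bad) > 0L) {
    stop("format error: non-numeric token at line ", line_no[bad[1L]],
         " of ", path)
  }
  matrix(unlist(vals), nrow = length(vals), ncol = widths[1L], byrow = TRUE)
}

#' Validate and tag a height-map matrix
#'
#' @param values Numeric matrix, at least 8 x 8, all values finite.
#' @param source_path,pixel_size Optional provenance attributes.
#' @return The validated matrix.
#' @export
as_height_map <- function(values, source_path = NULL, pixel_size = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("height map must be a numeric matrix")
  }
  if (nrow(values) < 8L || ncol(values) < 8L) {
    stop("height map must be at least 8 x 8 (got ",
         nrow(values), " x ", ncol(values), ")")
  }
  if (!all(is.finite(values))) stop("height map contains non-finite values")
  if (!is.null(source_path)) attr(values, "source_path") <- source_path
  if (!is.null(pixel_size)) attr(values, "pixel_size") <- pixel_size
  values
}

#' Construct a Minkowski curve object
#'
#' Bundles the three per-threshold functional sequences for one image. Each
#' sequence has exactly 256 entries indexed by threshold level t = 0..255.
#'
#' @param sample_id Sample identifier string.
#' @param area Covered area (foreground pixel count) per level.
#' @param contour_length Boundary length (pixel-edge count) per level.
#' @param euler Euler characteristic per level.
#' @return An object of class \code{minkowski_curve}.
#' @export
minkowski_curve <- function(sample_id, area, contour_length, euler) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  for (nm in c("area", "contour_length", "euler")) {
    v <- get(nm)
    if (length(v) != 256L || anyNA(v)) {
      stop("curve component '", nm, "' must have exactly 256 finite entries")
    }
  }
  if (any(area < 0) || any(contour_length < 0)) {
    stop("area and contour_length must be non-negative")
  }
  structure(
    list(sample_id = sample_id,
         area = as.numeric(area),
         contour_length = as.numeric(contour_length),
         euler = as.numeric(euler)),
    class = "minkowski_curve")
}

#' @export
print.minkowski_curve <- function(x, ...) {
  cat("Minkowski curve for sample '", x$sample_id, "' (256 levels)\n", sep = "")
  cat(sprintf("  area:    %d at t=0, %d at t=255\n", x$area[1L], x$area[256L]))
  cat(sprintf("  contour: max %g at t=%d\n",
              max(x$contour_length), which.max(x$contour_length) - 1L))
  cat(sprintf("  euler:   min %g at t=%d, max %g at t=%d\n",
              min(x$euler), which.min(x$euler) - 1L,
              max(x$euler), which.max(x$euler) - 1L))
  invisible(x)
}

#' Write Minkowski curves to a CSV table
#'
#' One row per sample and gray level: columns \code{sample_id},
#' \code{gray_level} (0-255), \code{area}, \code{contour_length},
#' \code{euler}; 256 rows per sample. Reading the file back with
#' \code{\link{read_curve_table}} reproduces the curves exactly.
#'
#' @param curves A \code{minkowski_curve} or list of them.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_curve_table <- function(curves, path) {
  curves <- as_curve_list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id,
               gray_level = 0:255,
               area = cv$area,
               contour_length = cv$contour_length,
               euler = cv$euler)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a curve table written by \code{write_curve_table}
#'
#' @param path CSV path.
#' @return Named list of \code{minkowski_curve} objects, in file order.
#' @export
read_curve_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gray_level", "area", "contour_length", "euler")
  if (!all(need %in% names(df))) {
    stop("curve table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  ids <- unique(df$sample_id)
  curves <- lapply(ids, function(id) {
    sub <- df[df$sample_id == id, ]
    sub <- sub[order(sub$gray_level), ]
    if (nrow(sub) != 256L || !identical(sub$gray_level, 0:255)) {
      stop("sample '", id, "' does not cover gray levels 0..255 exactly once")
    }
    minkowski_curve(id, sub$area, sub$contour_length, sub$euler)
  })
  names(curves) <- ids
  curves
}

as_curve_list <- function(curves) {
  if (inherits(curves, "minkowski_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, logical(1L),
                                     "minkowski_curve"))) {
    stop("expected a minkowski_curve or a list of them")
  }
  curves
}

#' Write a feature table to CSV
#'
#' @param features Data frame from \code{\link{extract_feature_table}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by \code{write_feature_table}
#'
#' @param path CSV path.
#' @return Data frame with sample_id, label and the 15 feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing) > 0L) {
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write an R object as pretty JSON
#'
#' Small helper used for band reports, classification reports, resolved
#' pipeline configurations and serialized models.
#'
#' @param x List-like object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
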