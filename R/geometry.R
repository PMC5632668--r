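#' Image geometry: the pixel-to-degree mapping
#'
#' Bundles the pixel grid dimensions with the angular resolution of the
#' display. All coordinates use the 0-based pixel-center convention, so the
#' image center sits at `((width_px - 1)/2, (height_px - 1)/2)`. The angular
#' scale is derived from the horizontal extent; the vertical mapping is assumed
#' equal (for the default 481 x 321 grid spanning 18.6 x 12.4 degrees the two
#' differ by less than 0.2%).
#'
#' @param width_px,height_px image dimensions in pixels (positive integers).
#' @param deg_width horizontal extent in degrees of visual angle. Ignored when
#'   `deg_per_px` is supplied directly.
#' @param deg_per_px degrees of visual angle per pixel; defaults to
#'   `deg_width / width_px`.
#' @return An object of class `image_geometry` with fields `width_px`,
#'   `height_px`, `deg_per_px` and `center_px` (x, y).
#' @examples
#' g <- image_geometry(481, 321, deg_width = 18.6)
#' pixels_to_degrees(19.4, g)  # 0.75 deg
#' @export
image_geometry <- function(width_px, height_px, deg_width = NULL,
                           deg_per_px = NULL) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (length(width_px) != 1L || length(height_px) != 1L ||
      is.na(width_px) || is.na(height_px) || width_px < 1L || height_px < 1L)
    stop("width_px and height_px must be positive integers", call. = FALSE)
  if (is.null(deg_per_px)) {
    if (is.null(deg_width))
      stop("supply either deg_width or deg_per_px", call. = FALSE)
    deg_per_px <- deg_width / width_px
  }
  if (!is.finite(deg_per_px) || deg_per_px <= 0)
    stop("deg_per_px must be positive", call. = FALSE)
  structure(
    list(width_px = width_px, height_px = height_px,
         deg_per_px = deg_per_px,
         center_px = c(x = (width_px - 1) / 2, y = (height_px - 1) / 2)),
    class = "image_geometry")
}

#' Default experiment geometry
#'
#' The 481 x 321 pixel grid spanning 18.6 x 12.4 degrees of visual angle used
#' throughout the pipeline defaults.
#' @return An `image_geometry`.
#' @export
default_geometry <- function() image_geometry(481L, 321L, deg_width = 18.6)

#' Convert pixels to degrees of visual angle (and back)
#'
#' @param px distance(s) in pixels.
#' @param geom an [image_geometry()].
#' @return Distance(s) in degrees.
#' @export
pixels_to_degrees <- function(px, geom) {
  stopifnot(inherits(geom, "image_geometry"))
  px * geom$deg_per_px
}

#' @rdname pixels_to_degrees
#' @param deg distance(s) in degrees of visual angle.
#' @export
degrees_to_pixels <- function(deg, geom) {
  stopifnot(inherits(geom, "image_geometry"))
  deg / geom$deg_per_px
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d px, %.5f deg/px (%.2f x %.2f deg)\n",
              x$width_px, x$height_px, x$deg_per_px,
              x$width_px * x$deg_per_px, x$height_px * x$deg_per_px))
  invisible(x)
}

#' Luminance image
#'
#' A 2-D grid of non-negative luminance values (arbitrary linear units) tied to
#' an [image_geometry()]. Matrices are stored height x width (rows index y,
#' columns index x).
#'
#' @param values numeric matrix of luminance values, all `>= 0`.
#' @param geometry an [image_geometry()]; defaults to one matching the matrix
#'   dimensions at the standard 18.6/481 deg-per-pixel scale.
#' @return An object of class `luminance_image` with fields `values` and
#'   `geometry`.
#' @export
luminance_image <- function(values, geometry = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop("luminance values must be numeric and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("luminance values must be non-negative", call. = FALSE)
  if (is.null(geometry))
    geometry <- image_geometry(ncol(values), nrow(values),
                               deg_per_px = 18.6 / 481)
  stopifnot(inherits(geometry, "image_geometry"))
  if (nrow(values) != geometry$height_px || ncol(values) != geometry$width_px)
    stop("image dimensions do not match geometry", call. = FALSE)
  structure(list(values = values, geometry = geometry),
            class = "luminance_image")
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("<luminance_image> %d x %d px, range [%.3g, %.3g]\n",
              x$geometry$width_px, x$geometry$height_px,
              min(x$values), max(x$values)))
  invisible(x)
}

# internal: coerce a luminance_image or bare matrix to a luminance_image
as_luminance_image <- function(img, geometry = NULL) {
  if (inherits(img, "luminance_image")) img else luminance_image(img, geometry)
}

# internal: check two images share a geometry
check_same_geometry <- function(a, b) {
  if (a$geometry$width_px != b$geometry$width_px ||
      a$geometry$height_px != b$geometry$height_px)
    stop("images have mismatched geometries", call. = FALSE)
  invisible(TRUE)
}
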