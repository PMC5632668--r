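#' Gaussian spatial window specification
#'
#' The local contrast-energy computation weights each neighborhood with an
#' isotropic Gaussian, `w(dx, dy) = exp(-(dx^2 + dy^2) / (2 sigma^2))`, with
#' peak weight 1 at the center. The default sigma of 19.4 px corresponds to
#' 0.75 degrees of visual angle on the standard geometry. The window is
#' truncated at `truncation_radius_px` (at least `ceiling(3 * sigma)`) and the
#' weights are renormalized over the in-bounds support.
#'
#' @param sigma_px Gaussian standard deviation in pixels (`> 0`).
#' @param truncation_radius_px integer support half-width; defaults to
#'   `ceiling(3 * sigma_px)`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(sigma_px = 19.4,
                        truncation_radius_px = ceiling(3 * sigma_px)) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L ||
      !is.finite(sigma_px) || sigma_px <= 0)
    stop("sigma_px must be a positive scalar", call. = FALSE)
  truncation_radius_px <- as.integer(truncation_radius_px)
  if (is.na(truncation_radius_px) ||
      truncation_radius_px < ceiling(3 * sigma_px))
    stop("truncation_radius_px must be >= ceiling(3 * sigma_px)",
         call. = FALSE)
  structure(list(sigma_px = sigma_px,
                 truncation_radius_px = truncation_radius_px),
            class = "window_spec")
}

#' Evaluate the Gaussian window on its support grid
#'
#' @param spec a [window_spec()].
#' @return A `(2r+1) x (2r+1)` matrix of weights with value 1 at the center.
#' @examples
#' w <- gaussian_window(window_spec(1, 3))
#' w[4, 4]      # 1
#' w[4, 5]      # exp(-0.5)
#' @export
gaussian_window <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  r <- spec$truncation_radius_px
  d <- (-r):r
  k <- exp(-d^2 / (2 * spec$sigma_px^2))
  outer(k, k)
}

# internal: 1-D truncated-Gaussian windowed sum along rows (axis = 1) or
# columns (axis = 2), by shift-and-add. Deliberately BLAS-free: the separable
# convolution is the package's hot path and must not depend on BLAS
# threading behavior.
# internal: windowed sum over both axes by FFT convolution. Zero-padding to
# composite sizes >= n + r prevents circular wrap-around; the kernel is
# separable, so its 2-D transform is the outer product of two 1-D
# transforms. Deliberately BLAS-free (thread-count independent).
conv_sep <- function(X, k, r) {
  H <- nrow(X); W <- ncol(X)
  H2 <- stats::nextn(H + r, c(2, 3, 5))
  W2 <- stats::nextn(W + r, c(2, 3, 5))
  P <- matrix(0, H2, W2)
  P[seq_len(H), seq_len(W)] <- X
  pad_kernel <- function(n2) {
    kv <- numeric(n2)
    kv[1L] <- k[r + 1L]
    d <- seq_len(r)
    kv[1L + d] <- k[r + 1L + d]
    kv[n2 + 1L - d] <- k[r + 1L - d]
    stats::fft(kv)
  }
  K <- pad_kernel(H2) %o% pad_kernel(W2)
  out <- Re(stats::fft(stats::fft(P) * K, inverse = TRUE)) / (H2 * W2)
  out[seq_len(H), seq_len(W), drop = FALSE]
}

# internal: 1-D windowed sum of a vector of ones (in-bounds weight mass)
conv_ones <- function(n, k, r) {
  out <- numeric(n)
  for (d in (-r):r) {
    if (d >= n) next
    a <- max(1L, 1L - d); b <- min(n, n - d)
    if (a <= b) out[a:b] <- out[a:b] + k[d + r + 1L]
  }
  out
}

#' Per-pixel local contrast energy map
#'
#' For every pixel, computes the Gaussian-weighted RMS contrast of the
#' luminance within the spatial window: the weighted standard deviation of
#' luminance relative to the weighted mean (`variant = "rms"`, the default), or
#' the weighted variance relative to the squared mean (`variant = "squared"`).
#' Weights are renormalized over the in-bounds support at image borders.
#'
#' Pixels whose window covers only zero luminance have undefined contrast;
#' their values are `NA` and the count is recorded in the `n_undefined` field
#' (flagged, not silently zeroed).
#'
#' @param img a [luminance_image()] (or bare matrix).
#' @param spec a [window_spec()].
#' @param variant `"rms"` (square root applied) or `"squared"`.
#' @return An object of class `contrast_energy_map` with fields `values`
#'   (matrix, same dimensions as the image), `window`, `variant`,
#'   `n_undefined`.
#' @export
contrast_energy_map <- function(img, spec = window_spec(), variant = c("rms", "squared")) {
  variant <- match.arg(variant)
  img <- as_luminance_image(img)
  stopifnot(inherits(spec, "window_spec"))
  X <- img$values
  # center the image before the moment computation: the weighted variance is
  # shift-invariant and this avoids catastrophic cancellation in m2 - mu^2
  c0 <- mean(X)
  Xc <- X - c0

  r <- spec$truncation_radius_px
  k <- exp(-((-r):r)^2 / (2 * spec$sigma_px^2))
  W <- conv_ones(nrow(X), k, r) %o% conv_ones(ncol(X), k, r)
  S1 <- conv_sep(Xc, k, r)
  S2 <- conv_sep(Xc^2, k, r)
  mu_c <- S1 / W
  v <- pmax(S2 / W - mu_c^2, 0)           # weighted variance (shift-invariant)
  mu <- mu_c + c0                         # weighted mean of the raw luminance

  undef <- mu <= 0
  # mu == 0 can only arise when every in-window luminance is zero (values >= 0)
  vals <- matrix(NA_real_, nrow(X), ncol(X))
  ok <- !undef
  vals[ok] <- if (variant == "rms") sqrt(v[ok]) / mu[ok] else v[ok] / mu[ok]^2
  structure(list(values = vals, window = spec, variant = variant,
                 n_undefined = sum(undef), geometry = img$geometry),
            class = "contrast_energy_map")
}

#' @export
print.contrast_energy_map <- function(x, ...) {
  cat(sprintf("<contrast_energy_map> %d x %d, variant=%s, sigma=%.3g px, %d undefined px\n",
              ncol(x$values), nrow(x$values), x$variant, x$window$sigma_px,
              x$n_undefined))
  invisible(x)
}

#' Change region (binary mask of manipulated pixels)
#'
#' @param mask logical matrix, `TRUE` where the image pair differs.
#' @return An object of class `change_region` with fields `mask`, `n_px`, and
#'   `centroid_px` (x, y; 0-based center of mass).
#' @export
change_region <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  n_px <- sum(mask)
  if (n_px < 1L)
    stop(no_change_error("change region is empty"))
  ij <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask, n_px = n_px,
                 centroid_px = c(x = mean(ij[, 2] - 1), y = mean(ij[, 1] - 1))),
            class = "change_region")
}

#' @export
print.change_region <- function(x, ...) {
  cat(sprintf("<change_region> %d px, centroid (%.1f, %.1f)\n",
              x$n_px, x$centroid_px[["x"]], x$centroid_px[["y"]]))
  invisible(x)
}

no_change_error <- function(msg) {
  structure(class = c("changescope_no_change", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Detect the changed region of an image pair
#'
#' Pixels where the absolute luminance difference exceeds `tol` form the
#' change region. With `tol = NULL` the tolerance is 0 when both images are
#' integer-valued and `1e-6` otherwise.
#'
#' @param orig,manip [luminance_image()] objects with a shared geometry.
#' @param tol luminance-difference tolerance, or `NULL` for the default rule.
#' @return A [change_region()].
#' @export
diff_region <- function(orig, manip, tol = NULL) {
  orig <- as_luminance_image(orig); manip <- as_luminance_image(manip)
  check_same_geometry(orig, manip)
  if (is.null(tol)) {
    int_valued <- all(orig$values == round(orig$values)) &&
      all(manip$values == round(manip$values))
    tol <- if (int_valued) 0 else 1e-6
  }
  mask <- abs(orig$values - manip$values) > tol
  if (!any(mask))
    stop(no_change_error("images are identical within tolerance: no change region"))
  change_region(mask)
}

#' Importance map (averaged human labels)
#'
#' A grid of subjective-importance values in `[0, 1]`: the average of
#' `n_observers` binary label maps, so every value is a multiple of
#' `1/n_observers`.
#'
#' @param values numeric matrix in `[0, 1]`.
#' @param n_observers number of observers the map averages over (5 in the
#'   standard setup).
#' @return An object of class `importance_map`.
#' @export
importance_map <- function(values, n_observers = 5L) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1) || anyNA(values))
    stop("importance values must lie in [0, 1]", call. = FALSE)
  structure(list(values = values, n_observers = as.integer(n_observers)),
            class = "importance_map")
}

#' Contrast-energy change of a manipulation
#'
#' The absolute difference between the mean local contrast energy of the
#' original and the manipulated image, restricted to the changed region. By
#' default only a cropped neighborhood of the region (expanded by the window
#' truncation radius) is evaluated, which is exact — every window that touches
#' a region pixel lies inside the crop — and much faster on large images.
#'
#' @param orig,manip [luminance_image()] objects with a shared geometry.
#' @param region a [change_region()].
#' @param spec a [window_spec()].
#' @param variant contrast variant, see [contrast_energy_map()].
#' @param crop use the exact cropped computation (default `TRUE`).
#' @return Non-negative scalar.
#' @export
contrast_energy_change <- function(orig, manip, region, spec = window_spec(),
                                   variant = c("rms", "squared"), crop = TRUE) {
  variant <- match.arg(variant)
  orig <- as_luminance_image(orig); manip <- as_luminance_image(manip)
  check_same_geometry(orig, manip)
  stopifnot(inherits(region, "change_region"))
  if (!all(dim(region$mask) == dim(orig$values)))
    stop("region mask dimensions do not match the images", call. = FALSE)
  m <- region_map_means(orig, manip, region, spec, variant, crop)
  abs(m$orig_mean - m$manip_mean)
}

# internal: mean/extreme contrast-energy values over the region for both
# images, using the exact crop optimization
region_map_means <- function(orig, manip, region, spec, variant, crop) {
  mask <- region$mask
  if (crop) {
    r <- spec$truncation_radius_px
    ij <- which(mask, arr.ind = TRUE)
    rr <- range(ij[, 1]); cc <- range(ij[, 2])
    rows <- max(1L, rr[1] - r):min(nrow(mask), rr[2] + r)
    cols <- max(1L, cc[1] - r):min(ncol(mask), cc[2] + r)
    sub <- function(img) luminance_image(
      img$values[rows, cols, drop = FALSE],
      image_geometry(length(cols), length(rows),
                     deg_per_px = img$geometry$deg_per_px))
    o <- contrast_energy_map(sub(orig), spec, variant)
    m <- contrast_energy_map(sub(manip), spec, variant)
    msub <- mask[rows, cols, drop = FALSE]
    vo <- o$values[msub]; vm <- m$values[msub]
  } else {
    o <- contrast_energy_map(orig, spec, variant)
    m <- contrast_energy_map(manip, spec, variant)
    vo <- o$values[mask]; vm <- m$values[mask]
  }
  if (anyNA(vo) || anyNA(vm))
    stop("undefined contrast (all-zero window) inside the change region",
         call. = FALSE)
  list(orig_mean = mean(vo), manip_mean = mean(vm),
       orig_vals = vo, manip_vals = vm)
}

#' Subjective-importance change of a manipulation
#'
#' The sum of the averaged-label importance values over the pixels of the
#' changed region. Additive over disjoint regions.
#'
#' @param imap an [importance_map()] (or bare matrix in `[0, 1]`).
#' @param region a [change_region()].
#' @return Non-negative scalar.
#' @export
subjective_importance_change <- function(imap, region) {
  if (!inherits(imap, "importance_map")) imap <- importance_map(imap)
  stopifnot(inherits(region, "change_region"))
  if (!all(dim(imap$values) == dim(region$mask)))
    stop("importance map and region dimensions differ", call. = FALSE)
  sum(imap$values[region$mask])
}

#' Balancing covariates of a manipulated region
#'
#' Computes the region statistics used to balance the experimental conditions:
#' size in pixels, eccentricity of the region's center of mass, mean/max/min
#' local contrast over the region (averaged resp. extremized over both
#' images), absolute mean-luminance change, and the spatial-frequency change
#' (median of the bin-wise difference of radially binned Fourier amplitude
#' spectra of the Hann-tapered bounding-box patches). When an importance map
#' is supplied, `ce_change` and `si_change` are included.
#'
#' @param orig,manip [luminance_image()] objects sharing a geometry.
#' @param region a [change_region()].
#' @param spec a [window_spec()].
#' @param imap optional [importance_map()].
#' @param variant contrast variant, see [contrast_energy_map()].
#' @return A one-row `data.frame` with columns `size_px`, `eccentricity_deg`,
#'   `mean_contrast`, `max_contrast`, `min_contrast`, `luminance_change`,
#'   `sf_change`, and (when computable) `ce_change`, `si_change`.
#' @export
region_covariates <- function(orig, manip, region, spec = window_spec(),
                              imap = NULL, variant = c("rms", "squared")) {
  variant <- match.arg(variant)
  orig <- as_luminance_image(orig); manip <- as_luminance_image(manip)
  check_same_geometry(orig, manip)
  stopifnot(inherits(region, "change_region"))
  geom <- orig$geometry
  ctr <- geom$center_px
  ecc_px <- sqrt((region$centroid_px[["x"]] - ctr[["x"]])^2 +
                 (region$centroid_px[["y"]] - ctr[["y"]])^2)

  m <- region_map_means(orig, manip, region, spec, variant, crop = TRUE)
  lum_o <- mean(orig$values[region$mask])
  lum_m <- mean(manip$values[region$mask])

  out <- data.frame(
    size_px = region$n_px,
    eccentricity_deg = pixels_to_degrees(ecc_px, geom),
    mean_contrast = (m$orig_mean + m$manip_mean) / 2,
    max_contrast = max(m$orig_vals, m$manip_vals),
    min_contrast = min(m$orig_vals, m$manip_vals),
    luminance_change = abs(lum_o - lum_m),
    sf_change = sf_change(orig, manip, region))
  out$ce_change <- abs(m$orig_mean - m$manip_mean)
  if (!is.null(imap))
    out$si_change <- subjective_importance_change(imap, region)
  out
}

# internal: spatial-frequency change — median of the bin-wise difference of
# the radially binned 2-D Fourier amplitude spectra of the bounding-box
# patches (Hann taper; DC bin excluded, it is the luminance covariate)
sf_change <- function(orig, manip, region) {
  ij <- which(region$mask, arr.ind = TRUE)
  rr <- range(ij[, 1]); cc <- range(ij[, 2])
  if (rr[1] < 1 || cc[1] < 1 || rr[2] > nrow(region$mask) ||
      cc[2] > ncol(region$mask))
    warning("region bounding box clipped to image bounds")
  rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
  po <- orig$values[rows, cols, drop = FALSE]
  pm <- manip$values[rows, cols, drop = FALSE]
  if (length(po) < 4 || min(dim(po)) < 2) return(0)
  bo <- radial_amplitude(po)
  bm <- radial_amplitude(pm)
  stats::median(bo - bm)
}

# internal: 1-D radial amplitude distribution of a patch
radial_amplitude <- function(patch) {
  h <- nrow(patch); w <- ncol(patch)
  hann <- function(n) if (n == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  taper <- hann(h) %o% hann(w)
  A <- Mod(stats::fft(patch * taper))
  fy <- ifelse(0:(h - 1) > h / 2, 0:(h - 1) - h, 0:(h - 1)) / h
  fx <- ifelse(0:(w - 1) > w / 2, 0:(w - 1) - w, 0:(w - 1)) / w
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  n_bins <- max(2L, floor(min(h, w) / 2))
  bins <- pmin(1L + floor(fr / 0.5 * n_bins), n_bins)
  out <- rep(0, n_bins)
  agg <- tapply(A[fr > 0], bins[fr > 0], sum)
  out[as.integer(names(agg))] <- agg
  out
}
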