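#' Read a grayscale image from PNG or CSV
#'
#' PNG files are read with the `png` package (RGB(A) inputs are averaged to
#' gray; values arrive in `[0, 1]` and are rescaled by `scale`). CSV files
#' are headerless numeric grids, read verbatim.
#'
#' @param path file path ending in `.png` or `.csv`.
#' @param scale multiplier applied to PNG values (default 255, giving 8-bit
#'   luminance units).
#' @return A numeric matrix (rows = y, columns = x).
#' @export
read_gray_image <- function(path, scale = 255) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                         c(1, 2), mean)
    a * scale
  } else if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else stop("unsupported image format: .", ext, call. = FALSE)
}

#' Write a grayscale image to PNG or CSV
#'
#' PNG output is 8-bit: values are divided by `scale` and clipped to
#' `[0, 1]` (lossy). CSV output is the verbatim numeric grid.
#'
#' @param mat numeric matrix.
#' @param path destination ending in `.png` or `.csv`.
#' @param scale divisor mapping luminance to `[0, 1]` for PNG.
#' @export
write_gray_image <- function(mat, path, scale = 255) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(mat / scale, 0), 1), path)
  } else if (ext == "csv") {
    utils::write.table(mat, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}

#' Score a manifest of image pairs
#'
#' Computes `ce_change`, `si_change` and the balance covariates for every
#' pair listed in a manifest with columns `pair_id`, `original_path`,
#' `manipulated_path`, `importance_path`, and optionally `mask_path` (when
#' absent the change region is recovered with [diff_region()]) and
#' `source_image_id`.
#'
#' @param manifest `data.frame` or path to a manifest CSV.
#' @param sigma_px contrast-energy window SD in pixels.
#' @param variant contrast variant, see [contrast_energy_map()].
#' @param geometry [image_geometry()] applied to all images; `NULL` derives
#'   one per image at the standard angular resolution.
#' @return A scores `data.frame`, one row per pair.
#' @export
score_image_pairs <- function(manifest, sigma_px = 19.4,
                              variant = c("rms", "squared"), geometry = NULL) {
  variant <- match.arg(variant)
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "original_path", "manipulated_path",
                  "importance_path") %in% names(manifest)))
  spec <- window_spec(sigma_px)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    orig <- luminance_image(read_gray_image(manifest$original_path[i]), geometry)
    manip <- luminance_image(read_gray_image(manifest$manipulated_path[i]), geometry)
    ipath <- manifest$importance_path[i]
    iv <- read_gray_image(ipath, scale = 1)
    if (tolower(tools::file_ext(ipath)) != "csv")
      iv <- iv / max(1, max(iv))
    imap <- importance_map(iv)
    region <- if ("mask_path" %in% names(manifest) &&
                  !is.na(manifest$mask_path[i]) && nzchar(manifest$mask_path[i])) {
      change_region(read_gray_image(manifest$mask_path[i], scale = 1) > 0.5)
    } else diff_region(orig, manip)
    cv <- region_covariates(orig, manip, region, spec, imap = imap,
                            variant = variant)
    cbind(data.frame(pair_id = manifest$pair_id[i]),
          if ("source_image_id" %in% names(manifest))
            data.frame(source_image_id = manifest$source_image_id[i]),
          cv)
  })
  do.call(rbind, rows)
}

#' Export a stimulus pool to image files plus a manifest
#'
#' Writes the original, manipulated, importance and mask images of every
#' pair in a pool (regenerated from the stored seeds) and a manifest CSV, so
#' the file-based scoring path can be exercised end to end.
#'
#' @param pool a [generate_stimulus_pool()] result.
#' @param dir output directory.
#' @param pairs subset of pair ids (default: all).
#' @param format `"png"` (8-bit, lossy) or `"csv"` (lossless).
#' @return The manifest `data.frame` (also written to `manifest.csv`).
#' @export
export_pool <- function(pool, dir, pairs = pool$scores$pair_id,
                        format = c("png", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(pairs, function(pid) {
    pr <- regenerate_pair(pool, pid)
    paths <- file.path(dir, paste0(pid, "_", c("orig", "manip", "imp", "mask"),
                                   ".", format))
    write_gray_image(pr$orig$values, paths[1])
    write_gray_image(pr$manip$values, paths[2])
    write_gray_image(pr$imap$values, paths[3], scale = 1)
    write_gray_image(pr$region$mask * 1, paths[4], scale = 1)
    data.frame(pair_id = pid,
               source_image_id = pool$scores$source_image_id[
                 pool$scores$pair_id == pid],
               original_path = paths[1], manipulated_path = paths[2],
               importance_path = paths[3], mask_path = paths[4])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
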