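#' Render a synthetic single-pulmosphere image with known ground truth
#'
#' Draws the two-region structure of a collagen-embedded spheroid micrograph:
#' a bright filled disk (the dense spheroid core) surrounded by small bright
#' blobs (single invading cells) scattered at radii beyond the core edge, over
#' an optionally noisy background. The exact pixel masks of the core and of
#' the total invaded region (core plus cells) are recorded alongside the
#' rendered intensities, so segmentation and area measurement can be scored
#' against known truth.
#'
#' Cells are rendered as Gaussian intensity bumps whose support is cut at a
#' fixed intensity level; the ground-truth invasion mask is exactly the set of
#' pixels whose noise-free intensity is nonzero, which makes noiseless images
#' segmentable without error. Areas follow the pixel-center convention: a
#' pixel belongs to the core when its center lies within `core_radius` of the
#' spheroid center.
#'
#' @param core_radius Radius of the core disk, in pixels (>= 3).
#' @param n_cells Number of invading cells to scatter (>= 0).
#' @param reach Maximal distance beyond the core edge at which cell centers
#'   are placed, in pixels (>= 0). With `reach = 0` or `n_cells = 0` the
#'   image contains a core only and its ZOI% is 0.
#' @param noise_sd Standard deviation of additive Gaussian background noise
#'   on the \[0, 1\] intensity scale; intensities are clipped to \[0, 1\].
#' @param seed Integer seed; the same seed reproduces the image bit for bit.
#' @param size Image side length in pixels. The default leaves a margin
#'   around the invasion zone; a `size` too small to contain
#'   `core_radius + reach` plus the widest cell blob is an error, never a
#'   silent clip.
#' @param cell_sigma_range Range of the Gaussian blob sigma, in pixels.
#'
#' @return An object of class `pulmosphere_image`: a list with `pixels`
#'   (numeric matrix in \[0, 1\]), `core_mask` and `invasion_mask` (0/1
#'   integer matrices, invasion containing core), ground-truth pixel areas
#'   `truth_R` and `truth_H`, and the `seed`.
#'
#' @examples
#' img <- generate_pulmosphere_image(core_radius = 20, n_cells = 40,
#'                                   reach = 30, noise_sd = 0.05, seed = 1)
#' img$truth_H / img$truth_R
#' @export
generate_pulmosphere_image <- function(core_radius, n_cells, reach,
                                       noise_sd = 0.05, seed = 1L,
                                       size = NULL,
                                       cell_sigma_range = c(2, 4)) {
  assert_scalar_number(core_radius, "core_radius", lower = 3)
  assert_scalar_number(n_cells, "n_cells", lower = 0)
  assert_scalar_number(reach, "reach", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  # widest possible blob support: sigma_max * sqrt(2*log(amp/cut))
  blob_margin <- ceiling(max(cell_sigma_range) *
                           sqrt(2 * log(.blob_amp / .blob_cut))) + 1
  need <- 2 * ceiling(core_radius + reach + blob_margin) + 1
  if (is.null(size)) size <- need
  size <- as.integer(size)
  if (size < need)
    abort(sprintf(paste0("image size %d would clip the invasion zone: ",
                         "core_radius + reach + blob margin needs %d px"),
                  size, need))

  cx <- (size + 1) / 2
  dist <- sqrt(outer((seq_len(size) - cx)^2, (seq_len(size) - cx)^2, "+"))
  core_mask <- (dist <= core_radius) * 1L

  clean <- matrix(0, size, size)
  clean[core_mask == 1L] <- .core_intensity

  with_seed(seed, {
    if (n_cells >= 1 && reach > 0) {
      # area-uniform radial placement within the annulus
      r0 <- core_radius
      r1 <- core_radius + reach
      rr <- sqrt(runif(n_cells, r0^2, r1^2))
      th <- runif(n_cells, 0, 2 * pi)
      sg <- runif(n_cells, cell_sigma_range[1], cell_sigma_range[2])
      xs <- cx + rr * cos(th)
      ys <- cx + rr * sin(th)
      for (i in seq_len(n_cells)) {
        ext <- ceiling(sg[i] * sqrt(2 * log(.blob_amp / .blob_cut)))
        ix <- max(1L, floor(xs[i] - ext)):min(size, ceiling(xs[i] + ext))
        iy <- max(1L, floor(ys[i] - ext)):min(size, ceiling(ys[i] + ext))
        d2 <- outer((ix - xs[i])^2, (iy - ys[i])^2, "+")
        bump <- .blob_amp * exp(-d2 / (2 * sg[i]^2))
        bump[bump < .blob_cut] <- 0  # hard support: mask == nonzero pixels
        clean[ix, iy] <- pmax(clean[ix, iy], bump)
      }
    }
    invasion_mask <- (clean > 0) * 1L
    pixels <- clean
    if (noise_sd > 0)
      pixels <- pixels + rnorm(length(pixels), 0, noise_sd)
  })
  pixels <- pmin(pmax(pixels, 0), 1)

  structure(
    list(pixels = pixels,
         core_mask = core_mask,
         invasion_mask = invasion_mask,
         truth_R = sum(core_mask),
         truth_H = sum(invasion_mask),
         seed = as.integer(seed)),
    class = "pulmosphere_image"
  )
}

.core_intensity <- 0.9
.blob_amp <- 0.8
.blob_cut <- 0.25

#' @export
print.pulmosphere_image <- function(x, ...) {
  cat(sprintf(
    "<pulmosphere_image> %d x %d px | truth_R = %d, truth_H = %d (ZOI%% = %.1f)\n",
    nrow(x$pixels), ncol(x$pixels), x$truth_R, x$truth_H,
    zoi_percent(x$truth_H, x$truth_R)))
  invisible(x)
}

#' Display a synthetic pulmosphere image with its ground-truth outlines
#'
#' @param object A `pulmosphere_image`.
#' @param ... Unused.
#' @return A ggplot object: intensity raster with core and invasion masks
#'   overlaid as contours.
#' @method autoplot pulmosphere_image
#' @export
autoplot.pulmosphere_image <- function(object, ...) {
  df <- tidyr::expand_grid(x = seq_len(nrow(object$pixels)),
                           y = seq_len(ncol(object$pixels)))
  df$intensity <- as.vector(object$pixels)
  df$core <- as.vector(object$core_mask)
  df$invasion <- as.vector(object$invasion_mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$invasion),
                          breaks = 0.5, colour = "purple", linewidth = 0.3) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$core),
                          breaks = 0.5, colour = "yellow", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("truth R = %d px, H = %d px",
                                  object$truth_R, object$truth_H))
}

#' Write a synthetic image to a 16-bit grayscale TIFF
#'
#' @param image A `pulmosphere_image`.
#' @param path Output file path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_pulmosphere_tiff <- function(image, path) {
  stopifnot(inherits(image, "pulmosphere_image"))
  tiff::writeTIFF(t(image$pixels), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF or PNG micrograph as an intensity matrix
#'
#' Multi-channel images are averaged to one channel; intensities are
#' rescaled to \[0, 1\] if the file stores integers.
#'
#' @param path Image file path; format chosen by extension.
#' @return A numeric matrix of intensities in \[0, 1\].
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    abort(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  t(arr)  # row = x, column = y, matching the generator's convention
}
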