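#' Segment the foreground of a single-spheroid micrograph
#'
#' Thresholds a grayscale image, fills holes, and removes small connected
#' components, producing the binary mask from which the core area R and total
#' invaded area H are measured. The automatic threshold is Otsu's method; a
#' fixed intensity cut can be supplied instead, e.g. for noiseless synthetic
#' images.
#'
#' @param image Numeric matrix of intensities, finite values.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Intensity cut in \[0, 1\], required when
#'   `threshold_method = "fixed"`.
#' @param min_size Connected components smaller than this pixel count are
#'   discarded (default 5).
#' @param fill_holes Fill enclosed background holes inside components
#'   (default `TRUE`).
#' @return A 0/1 integer matrix of the same dimensions. An image with no
#'   pixel above threshold is an error ("empty foreground"), never a silent
#'   all-zero mask.
#' @export
segment_foreground <- function(image, threshold_method = c("otsu", "fixed"),
                               fixed_threshold = NULL, min_size = 5L,
                               fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (!is.matrix(image) || !is.numeric(image) || !all(is.finite(image)))
    abort("`image` must be a numeric matrix of finite intensities")
  thr <- switch(threshold_method,
    otsu = EBImage::otsu(EBImage::Image(image), range = range(image),
                         levels = 256),
    fixed = {
      if (is.null(fixed_threshold))
        abort("`fixed_threshold` is required when threshold_method = \"fixed\"")
      fixed_threshold
    })
  mask <- (image > thr) * 1
  if (sum(mask) == 0) abort("empty foreground: no pixel above threshold")
  if (fill_holes) mask <- EBImage::fillHull(mask)
  if (min_size > 1) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    mask <- matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
    if (sum(mask) == 0)
      abort("empty foreground: all components below `min_size`")
  }
  matrix(as.integer(mask > 0), nrow(image), ncol(image))
}

#' Measure the core area R of a segmented spheroid
#'
#' Isolates the dense spheroid center from thin radiating invading cells by a
#' morphological opening: the mask is eroded by `erosion_radius`, the largest
#' surviving connected component is taken as the core seed, and the seed is
#' dilated by the same radius within the original mask. Erosion and dilation
#' use the Euclidean distance transform, so a solid disk survives the
#' round-trip unchanged. R is the pixel count of the recovered core.
#'
#' @param mask 0/1 matrix from [segment_foreground()].
#' @param erosion_radius Opening radius in pixels. The default, `NULL`,
#'   estimates it as 1/4 of the equivalent-circle radius of the largest
#'   component — large enough to delete single-cell strands, small enough to
#'   keep the core.
#' @return The core area R in pixels, with the radius used attached as
#'   attribute `erosion_radius`. Erosion that deletes the whole mask is an
#'   error suggesting a smaller radius.
#' @export
measure_core_area <- function(mask, erosion_radius = NULL) {
  check_mask(mask)
  if (is.null(erosion_radius)) {
    lab <- EBImage::bwlabel(mask)
    big_area <- max(tabulate(lab[lab > 0]))
    erosion_radius <- max(1, round(sqrt(big_area / pi) / 4))
  }
  assert_scalar_number(erosion_radius, "erosion_radius", lower = 0,
                       strict_lower = TRUE)
  eroded <- (EBImage::distmap(mask) > erosion_radius) * 1
  if (sum(eroded) == 0)
    abort(sprintf(paste0("erosion radius %.3g annihilates the mask; ",
                         "use a smaller `erosion_radius`"), erosion_radius))
  lab <- EBImage::bwlabel(eroded)
  seed <- (lab == which.max(tabulate(lab[lab > 0]))) * 1
  # cells merged with the core rim survive erosion as local bumps on the
  # seed and would be re-captured by the dilation; a second, slightly
  # stronger opening of the seed shaves them (including small clusters)
  # while leaving a disk-shaped seed intact
  seed <- open_within(seed, 1.5 * erosion_radius) %||% seed
  # half-pixel slop on the dilation radius; the intersection with the
  # original mask caps any overshoot, and without it digital disks lose
  # their axis-extreme boundary pixels
  reach <- EBImage::distmap(1 - seed)
  core <- (seed > 0 | reach <= erosion_radius + 0.75) & mask > 0
  structure(sum(core), erosion_radius = erosion_radius)
}

#' Measure the total invaded area H of a segmented spheroid
#'
#' @param mask 0/1 matrix from [segment_foreground()].
#' @param hull_method `"convex_hull"` (default): H is the number of pixel
#'   centers inside the convex hull of all foreground pixel centers,
#'   mimicking a hand-outlined invasion front; `"component_union"`: H is the
#'   raw foreground pixel count.
#' @return The area H in pixels. Under `"convex_hull"`, H is always at least
#'   the foreground pixel count, hence at least the core area.
#' @export
measure_total_invaded_area <- function(mask,
                                       hull_method = c("convex_hull",
                                                       "component_union")) {
  hull_method <- match.arg(hull_method)
  check_mask(mask)
  if (hull_method == "component_union") return(sum(mask > 0))
  idx <- which(mask > 0, arr.ind = TRUE)
  hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  if (nrow(hull) <= 2) return(sum(mask > 0))  # collinear foreground
  count_pixels_in_convex_polygon(hull)
}

# Count integer grid points inside (or on) a convex polygon given by its
# vertices in counter-clockwise or clockwise order. Scanline over rows:
# for each integer y, intersect the polygon edges to get the x interval.
count_pixels_in_convex_polygon <- function(hull) {
  vx <- hull[, 1]; vy <- hull[, 2]
  nv <- length(vx)
  ys <- seq(ceiling(min(vy)), floor(max(vy)))
  eps <- 1e-9
  total <- 0L
  x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
  for (y in ys) {
    xs_hit <- numeric(0)
    for (e in seq_len(nv)) {
      ylo <- min(vy[e], y2[e]); yhi <- max(vy[e], y2[e])
      if (y < ylo - eps || y > yhi + eps) next
      if (abs(vy[e] - y2[e]) < eps) {
        xs_hit <- c(xs_hit, vx[e], x2[e])  # horizontal edge
      } else {
        t <- (y - vy[e]) / (y2[e] - vy[e])
        xs_hit <- c(xs_hit, vx[e] + t * (x2[e] - vx[e]))
      }
    }
    if (!length(xs_hit)) next
    total <- total + max(0L, floor(max(xs_hit) + eps) -
                           ceiling(min(xs_hit) - eps) + 1L)
  }
  total
}

# Euclidean opening of a binary seed by `radius`, capped within the seed.
# Returns NULL when the erosion annihilates the seed (caller keeps the
# unsmoothed seed in that case).
open_within <- function(seed, radius) {
  er <- (EBImage::distmap(seed) > radius) * 1
  if (sum(er) == 0) return(NULL)
  reach <- EBImage::distmap(1 - er)
  (er > 0 | reach <= radius + 0.75) & seed > 0
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || sum(mask > 0) == 0)
    abort("`mask` must be a nonempty binary matrix")
  invisible(mask)
}

#' Quantify one spheroid image into a measurement record
#'
#' Runs segmentation, core isolation, and total-area measurement, and returns
#' a one-row tibble ready for ZOI% scoring. Stage failures are propagated
#' with the failing stage named.
#'
#' @param image Numeric intensity matrix, or a `pulmosphere_image`, or a
#'   file path readable by [read_micrograph()].
#' @param config Segmentation parameters, see [run_config()]. Relevant
#'   entries: `threshold_method`, `fixed_threshold`, `min_component_size`,
#'   `erosion_radius`, `hull_method`, `um_per_px`.
#' @param patient_id,arm,replicate Identifiers attached to the measurement.
#'   When `image` is a path and these are `NA`, they are parsed from a
#'   filename of the form `<patient>_<arm>_<replicate>.<ext>`.
#' @return A one-row tibble: `patient_id`, `arm`, `replicate`, `H`, `R`,
#'   `unit` (`"px^2"`, or `"um^2"` when `um_per_px` is set), `zoi_percent`,
#'   `source_image`.
#' @examples
#' img <- generate_pulmosphere_image(30, 80, 40, noise_sd = 0.05, seed = 2)
#' quantify_image(img, patient_id = "P01", arm = "untreated", replicate = 1)
#' @export
quantify_image <- function(image, config = run_config(), patient_id = NA,
                           arm = NA, replicate = NA) {
  source_image <- NA_character_
  if (is.character(image)) {
    source_image <- image
    ids <- parse_image_filename(image)
    if (is.na(patient_id)) patient_id <- ids$patient_id
    if (is.na(arm)) arm <- ids$arm
    if (is.na(replicate)) replicate <- ids$replicate
    image <- read_micrograph(image)
  } else if (inherits(image, "pulmosphere_image")) {
    image <- image$pixels
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("[%s] %s", name, conditionMessage(e))))
  }
  mask <- stage("segment_foreground",
                segment_foreground(image,
                                   threshold_method = config$threshold_method,
                                   fixed_threshold = config$fixed_threshold,
                                   min_size = config$min_component_size))
  R <- stage("measure_core_area",
             as.numeric(measure_core_area(mask, config$erosion_radius)))
  H <- stage("measure_total_invaded_area",
             measure_total_invaded_area(mask, config$hull_method))
  H <- max(H, R)  # hull of everything can never undercut the core region
  unit <- "px^2"
  if (!is.null(config$um_per_px) && !is.na(config$um_per_px)) {
    H <- H * config$um_per_px^2
    R <- R * config$um_per_px^2
    unit <- "um^2"
  }
  tibble::tibble(patient_id = as.character(patient_id),
                 arm = as.character(arm),
                 replicate = as.integer(replicate),
                 H = H, R = R, unit = unit,
                 zoi_percent = zoi_percent(H, R),
                 source_image = source_image)
}

parse_image_filename <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) >= 3) {
    list(patient_id = parts[1],
         arm = parts[2],
         replicate = suppressWarnings(as.integer(parts[length(parts)])))
  } else {
    list(patient_id = stem, arm = NA_character_, replicate = NA_integer_)
  }
}
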