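# Segmentation of the epithelial band and its nuclei. The route is
# deliberately deterministic: Gaussian smoothing, a global Otsu threshold,
# then morphology — no trainable classifier, so two runs on the same image
# always agree.

#' Segment the epithelial band
#'
#' Smooths the band-marker channel with a Gaussian kernel, applies a global
#' Otsu threshold, closes small gaps with a disc-shaped structuring element,
#' fills holes, and keeps the largest 8-connected foreground component, so
#' the result is a single connected band mask.
#'
#' @param x A [micrograph()].
#' @param smoothing_sigma_um Gaussian smoothing sigma in micrometres.
#' @param closing_radius_um Morphological closing radius in micrometres.
#' @return A logical matrix of class `band_mask` (attribute
#'   `pixel_size_um`), `TRUE` on the band.
#' @export
segment_band <- function(x, smoothing_sigma_um = 1, closing_radius_um = 2) {
  stopifnot(inherits(x, "micrograph"))
  check_number(smoothing_sigma_um, "smoothing_sigma_um", 0)
  check_number(closing_radius_um, "closing_radius_um", 0)
  ch <- norm_grey(x$band, x$bit_depth)
  if (diff(range(ch)) == 0) {
    abort("no foreground: band channel is constant.")
  }
  psz <- x$pixel_size_um
  sm <- smooth_px(ch, smoothing_sigma_um / psz)
  # an already-binary raster stays itself: Otsu on {0, 1} splits at the gap
  bw <- sm > EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  if (!any(bw)) abort("no foreground after thresholding.")
  rad <- max(1L, round(closing_radius_um / psz))
  brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  bw <- as.matrix(EBImage::closing(bw * 1, brush)) > 0
  bw <- as.matrix(EBImage::fillHull(bw * 1)) > 0
  lab <- EBImage::bwlabel(bw * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- matrix(as.vector(lab) == keep, nrow(bw), ncol(bw))
  structure(mask, class = c("band_mask", "matrix", "array"),
            pixel_size_um = psz)
}

# Gaussian smoothing in pixel units; sigma 0 is the identity. gblur needs an
# odd kernel no larger than the image, so the radius is clamped.
smooth_px <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- min(max(2, ceiling(3 * sigma_px)), floor((min(dim(m)) - 1) / 2))
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma_px, radius = 2L * r + 1L))
}

#' Detect nuclei and split touching ones
#'
#' Smooths and Otsu-thresholds the nuclear channel, separates touching
#' objects by a watershed on the Euclidean distance transform (seeded at
#' local maxima at least `min_seed_distance_um` apart), labels the result
#' with 8-connectivity, and reports one record per object. An object is
#' in-band iff its centroid pixel lies inside the band mask.
#'
#' @param x A [micrograph()].
#' @param band A `band_mask` from [segment_band()] (or any logical matrix of
#'   matching shape).
#' @param smoothing_sigma_um Gaussian smoothing sigma in micrometres.
#' @param min_seed_distance_um Minimum separation of watershed seeds in
#'   micrometres; objects closer than this are not split.
#' @return A tibble with one row per detected object: `label`, `area_um2`,
#'   `centroid_row`, `centroid_col` (fractional pixel coordinates) and
#'   `in_band`. Empty (zero-row) when nothing is detected.
#' @export
segment_nuclei <- function(x, band, smoothing_sigma_um = 0.25,
                           min_seed_distance_um = 2) {
  stopifnot(inherits(x, "micrograph"))
  if (!identical(dim(band), dim(x$nuclei))) {
    abort("`band` shape does not match the nuclei channel.")
  }
  check_number(smoothing_sigma_um, "smoothing_sigma_um", 0)
  check_number(min_seed_distance_um, "min_seed_distance_um", 0, strict_min = TRUE)
  psz <- x$pixel_size_um
  ch <- norm_grey(x$nuclei, x$bit_depth)
  if (diff(range(ch)) == 0) {
    return(empty_nucleus_records())
  }
  sm <- smooth_px(ch, smoothing_sigma_um / psz)
  bw <- sm > EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  if (!any(bw)) {
    return(empty_nucleus_records())
  }
  dm <- EBImage::distmap(bw * 1)
  ext <- max(1L, round(min_seed_distance_um / psz / 2))
  lab <- EBImage::watershed(dm, tolerance = 0.5, ext = ext)
  lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  st <- label_stats(lab)
  ib <- band[cbind(
    pmin(pmax(round(st$centroid_row), 1L), nrow(bw)),
    pmin(pmax(round(st$centroid_col), 1L), ncol(bw))
  )]
  tibble(
    label = st$label,
    area_um2 = st$n_px * psz^2,
    centroid_row = st$centroid_row,
    centroid_col = st$centroid_col,
    in_band = as.logical(ib)
  )
}

empty_nucleus_records <- function() {
  tibble(
    label = integer(), area_um2 = double(),
    centroid_row = double(), centroid_col = double(),
    in_band = logical()
  )
}
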