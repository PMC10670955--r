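# ROI-based fluorescence quantification: arithmetic mean intensity per
# polygonal region, fold change against a negative control, and the
# densitometric total grey value normalized per 10,000 um^2.

#' Polygonal region of interest
#'
#' A simple (non-self-intersecting) polygon in fractional pixel coordinates.
#' The centre of pixel `(i, j)` is the point `(i, j)`; a pixel belongs to
#' the ROI iff its centre falls inside the polygon, which makes region
#' statistics additive under splitting an ROI along a line between pixel
#' centres.
#'
#' @param vertices Two-column matrix or data frame of `(row, col)` polygon
#'   vertices, at least 3.
#' @param pixel_size_um Pixel side length in micrometres.
#' @param label Optional identifier (e.g. "section 3, ROI 2").
#' @return An object of class `roi`.
#' @export
roi <- function(vertices, pixel_size_um, label = "roi") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) {
    abort("`vertices` must be an n x 2 matrix with n >= 3.")
  }
  if (anyNA(v)) abort("`vertices` must not contain missing values.")
  check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE)
  if (polygon_self_intersects(v)) {
    abort("`vertices` describe a self-intersecting polygon.")
  }
  structure(
    list(
      vertices = v, pixel_size_um = as.numeric(pixel_size_um),
      label = as.character(label)
    ),
    class = "roi"
  )
}

# O(k^2) segment-intersection check; ROIs have few vertices.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  crosses <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through the closing edge
      if (crosses(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf(
    "<roi '%s'> %d vertices, %.4g um/px\n",
    x$label, nrow(x$vertices), x$pixel_size_um
  ))
  invisible(x)
}

# Logical mask of pixels whose centres lie inside the ROI polygon.
roi_pixel_mask <- function(image, r) {
  stopifnot(inherits(r, "roi"))
  if (!is.matrix(image)) abort("`image` must be a single-channel matrix.")
  v <- r$vertices
  if (any(v[, 1] < 0.5 - 1e-9) || any(v[, 1] > nrow(image) + 0.5 + 1e-9) ||
    any(v[, 2] < 0.5 - 1e-9) || any(v[, 2] > ncol(image) + 0.5 + 1e-9)) {
    abort("ROI lies outside the image bounds.")
  }
  r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(nrow(image), ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(ncol(image), ceiling(max(v[, 2])))
  rows <- r0:r1
  cols <- c0:c1
  pts <- cbind(
    rep(rows, times = length(cols)),
    rep(cols, each = length(rows))
  )
  inside <- mgcv::in.out(rbind(v, v[1, , drop = FALSE]), pts)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[pts[inside, , drop = FALSE]] <- TRUE
  mask
}

#' Arithmetic mean intensity inside an ROI
#'
#' @param image Single-channel numeric matrix of grey values.
#' @param r An [roi()].
#' @return Mean grey value over the pixels whose centres fall inside the
#'   polygon; errors if the ROI covers no pixel or leaves the image.
#' @export
roi_mean_intensity <- function(image, r) {
  mask <- roi_pixel_mask(image, r)
  if (!any(mask)) abort("ROI covers zero pixels.")
  mean(image[mask])
}

#' Fold change of a mean intensity against a negative control
#'
#' @param mean_fi Mean fluorescence intensity of the region of interest.
#' @param negative_mean_fi Mean intensity of the negative-control staining
#'   (primary antibody omitted); must be > 0.
#' @return `mean_fi / negative_mean_fi`.
#' @export
fold_change_vs_negative <- function(mean_fi, negative_mean_fi) {
  check_number(mean_fi, "mean_fi", min = 0)
  check_number(negative_mean_fi, "negative_mean_fi", min = 0, strict_min = TRUE)
  mean_fi / negative_mean_fi
}

#' Densitometric grey value per 10,000 square micrometres
#'
#' Sums the grey values of the pixels inside the ROI and normalizes the
#' total to a reference area of 10,000 um^2:
#' `sum(grey) / area_um2 * 10000`.
#'
#' @inheritParams roi_mean_intensity
#' @param mode `"sum"` (default, densitometric total) or `"mean"` (the mean
#'   grey value scaled the same way, for instruments that report means).
#' @return Normalized grey value (a single number).
#' @export
gray_per_area <- function(image, r, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  mask <- roi_pixel_mask(image, r)
  if (!any(mask)) abort("ROI covers zero pixels (zero area).")
  area_um2 <- sum(mask) * r$pixel_size_um^2
  val <- if (mode == "sum") sum(image[mask]) else mean(image[mask])
  val / area_um2 * 1e4
}

#' Quantify a set of ROIs on one image
#'
#' Tidy wrapper producing one row per ROI with the mean intensity, the
#' grey-per-area densitometry, and (when a negative-control mean is given)
#' the fold change.
#'
#' @param image Single-channel numeric matrix.
#' @param rois List of [roi()] objects.
#' @param negative_mean_fi Optional negative-control mean intensity.
#' @return Tibble: `label`, `n_px`, `area_um2`, `mean_fi`,
#'   `gray_per_10k_um2`, and `fold_change` when the control is supplied.
#' @export
quantify_rois <- function(image, rois, negative_mean_fi = NULL) {
  if (inherits(rois, "roi")) rois <- list(rois)
  purrr::map_dfr(rois, function(r) {
    mask <- roi_pixel_mask(image, r)
    if (!any(mask)) abort(sprintf("ROI '%s' covers zero pixels.", r$label))
    mfi <- mean(image[mask])
    out <- tibble(
      label = r$label,
      n_px = sum(mask),
      area_um2 = sum(mask) * r$pixel_size_um^2,
      mean_fi = mfi,
      gray_per_10k_um2 = sum(image[mask]) / (sum(mask) * r$pixel_size_um^2) * 1e4
    )
    if (!is.null(negative_mean_fi)) {
      out$fold_change <- fold_change_vs_negative(mfi, negative_mean_fi)
    }
    out
  })
}

#' Read / write ROI polygons as JSON
#'
#' The schema is a JSON array of objects with fields `label`,
#' `pixel_size_um`, and `vertices` (array of `[row, col]` pairs).
#'
#' @param rois List of [roi()] objects.
#' @param path JSON file path.
#' @return `write_rois_json`: `path`, invisibly. `read_rois_json`: list of
#'   [roi()] objects.
#' @export
write_rois_json <- function(rois, path) {
  if (inherits(rois, "roi")) rois <- list(rois)
  jsonlite::write_json(
    lapply(rois, function(r) {
      list(
        label = r$label, pixel_size_um = r$pixel_size_um,
        vertices = unname(apply(r$vertices, 1, function(v) c(v[1], v[2]), simplify = FALSE))
      )
    }),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    roi(
      do.call(rbind, lapply(x$vertices, unlist)),
      pixel_size_um = x$pixel_size_um, label = x$label
    )
  })
}
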