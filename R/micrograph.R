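#' Calibrated two-channel micrograph
#'
#' Container for the unit of image analysis: two equally shaped intensity
#' rasters — an epithelial band marker channel (e.g. Cytokeratin 7) and a
#' nuclear channel (e.g. DAPI) — together with the pixel size in micrometres
#' and the acquisition bit depth. Matrices are indexed `[row, col]` with row 1
#' at the top; the centre of pixel `(i, j)` sits at `((i - 0.5) * pixel_size,
#' (j - 0.5) * pixel_size)` in micrometre coordinates.
#'
#' @param band Numeric matrix of grey levels for the band-marker channel.
#' @param nuclei Numeric matrix of grey levels for the nuclear channel; must
#'   have the same dimensions as `band`.
#' @param pixel_size_um Side length of one pixel in micrometres (> 0).
#' @param bit_depth Acquisition bit depth, 8 or 16.
#' @param id Optional identifier (e.g. section id / ROI index) carried into
#'   downstream result tables.
#'
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(band, nuclei, pixel_size_um, bit_depth = 8L,
                       id = "micrograph") {
  if (!is.matrix(band) || !is.matrix(nuclei)) {
    abort("`band` and `nuclei` must be numeric matrices.")
  }
  if (!identical(dim(band), dim(nuclei))) {
    abort("`band` and `nuclei` must have identical dimensions.")
  }
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE)
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16.")
  structure(
    list(
      band = band, nuclei = nuclei,
      pixel_size_um = as.numeric(pixel_size_um),
      bit_depth = as.integer(bit_depth),
      id = as.character(id)
    ),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph '%s'> %d x %d px, %.4g um/px, %d-bit\n",
    x$id, nrow(x$band), ncol(x$band), x$pixel_size_um, x$bit_depth
  ))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$band)

#' Write a micrograph to a two-page TIFF with a JSON sidecar
#'
#' The two channels are written as consecutive pages of one 16-bit TIFF.
#' Pixel size, bit depth and id go to `<path>.json`, since TIFF resolution
#' tags are not reliably round-tripped across readers.
#'
#' @param x A [micrograph()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(x, path) {
  stopifnot(inherits(x, "micrograph"))
  maxval <- 2^x$bit_depth - 1
  tiff::writeTIFF(
    list(x$band / maxval, x$nuclei / maxval),
    path, bits.per.sample = 16L, compression = "none"
  )
  jsonlite::write_json(
    list(
      pixel_size_um = x$pixel_size_um,
      bit_depth = x$bit_depth, id = x$id,
      channels = c("band", "nuclei")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a micrograph written by [write_micrograph()]
#'
#' @param path TIFF path; `<path>.json` supplies calibration unless
#'   `pixel_size_um` is given explicitly.
#' @param pixel_size_um Optional override for the pixel size in micrometres.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) abort("expected a two-page TIFF (band, nuclei).")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  psz <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(psz)) {
    abort("pixel size not found: pass `pixel_size_um` or provide the JSON sidecar.")
  }
  bit_depth <- as.integer(meta$bit_depth %||% 8L)
  maxval <- 2^bit_depth - 1
  micrograph(
    band = round(pages[[1]] * maxval),
    nuclei = round(pages[[2]] * maxval),
    pixel_size_um = psz,
    bit_depth = bit_depth,
    id = as.character(meta$id %||% basename(path))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
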