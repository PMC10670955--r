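# Synthetic tissue phantoms: a curved epithelial band of known centerline
# length containing nuclei at an exact linear density, plus sub-threshold
# debris inside the band and nucleus-like clutter outside it. The ground
# truth is exact by construction, which is what makes parameter-recovery
# tests on the density pipeline sharp.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards: generators are pure in (params, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parameters for the tissue phantom generator
#'
#' Defaults emulate a 20x field of mouse urothelium: a 128 x 128 um canvas at
#' 0.5 um/px, a gently curved band about 12 um thick, nuclei of 2 x 1.5 um
#' semi-axes at 0.3 nuclei per um of centerline, with faint Gaussian camera
#' noise, a few sub-resolution debris specks inside the band and a few
#' nucleus-like objects outside it.
#'
#' @param image_height_px,image_width_px Canvas size in pixels.
#' @param pixel_size_um Pixel side length in micrometres.
#' @param centerline_kind One of `"straight"`, `"sinusoid"`, `"arc"`.
#' @param amplitude_um,wavelength_um Sinusoid geometry (ignored otherwise).
#' @param arc_radius_um,arc_span_rad Arc geometry: centerline radius and
#'   subtended angle (default a half circle), ignored otherwise.
#' @param band_thickness_um Band thickness; must exceed twice the nucleus
#'   minor semi-axis so nuclei fit inside the band.
#' @param target_density_per_um Nuclei per micrometre of centerline.
#' @param nucleus_major_um,nucleus_minor_um Nucleus ellipse semi-axes (um).
#' @param band_intensity,nucleus_intensity,background_intensity Grey levels.
#' @param gaussian_noise_sd Additive Gaussian noise SD in grey levels,
#'   clipped to the bit depth.
#' @param debris_count Sub-threshold specks (< 1 um^2) placed inside the band.
#' @param clutter_count Nucleus-like objects placed outside the band.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#'
#' @return A validated parameter list of class `tissue_phantom_params`.
#' @export
tissue_phantom_params <- function(image_height_px = 256L,
                                  image_width_px = 256L,
                                  pixel_size_um = 0.5,
                                  centerline_kind = c("sinusoid", "straight", "arc"),
                                  amplitude_um = 10,
                                  wavelength_um = 60,
                                  arc_radius_um = 45,
                                  arc_span_rad = pi,
                                  band_thickness_um = 12,
                                  target_density_per_um = 0.3,
                                  nucleus_major_um = 2,
                                  nucleus_minor_um = 1.5,
                                  band_intensity = 180,
                                  nucleus_intensity = 200,
                                  background_intensity = 10,
                                  gaussian_noise_sd = 0,
                                  debris_count = 0L,
                                  clutter_count = 0L,
                                  bit_depth = 8L,
                                  seed = 1L) {
  centerline_kind <- match.arg(centerline_kind)
  p <- list(
    image_height_px = check_count(image_height_px, "image_height_px", 16L),
    image_width_px = check_count(image_width_px, "image_width_px", 16L),
    pixel_size_um = check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE),
    centerline_kind = centerline_kind,
    amplitude_um = check_number(amplitude_um, "amplitude_um", 0),
    wavelength_um = check_number(wavelength_um, "wavelength_um", 0, strict_min = TRUE),
    arc_radius_um = check_number(arc_radius_um, "arc_radius_um", 0, strict_min = TRUE),
    arc_span_rad = check_number(arc_span_rad, "arc_span_rad", 0, max = 2 * pi, strict_min = TRUE),
    band_thickness_um = check_number(band_thickness_um, "band_thickness_um", 0, strict_min = TRUE),
    target_density_per_um = check_number(target_density_per_um, "target_density_per_um", 0),
    nucleus_major_um = check_number(nucleus_major_um, "nucleus_major_um", 0, strict_min = TRUE),
    nucleus_minor_um = check_number(nucleus_minor_um, "nucleus_minor_um", 0, strict_min = TRUE),
    band_intensity = band_intensity,
    nucleus_intensity = nucleus_intensity,
    background_intensity = background_intensity,
    gaussian_noise_sd = check_number(gaussian_noise_sd, "gaussian_noise_sd", 0),
    debris_count = check_count(debris_count, "debris_count"),
    clutter_count = check_count(clutter_count, "clutter_count"),
    bit_depth = if (bit_depth %in% c(8L, 16L)) as.integer(bit_depth) else abort("`bit_depth` must be 8 or 16."),
    seed = check_count(seed, "seed", min = -2147483647L)
  )
  if (p$band_thickness_um <= 2 * p$nucleus_minor_um) {
    abort("`band_thickness_um` must exceed 2 * nucleus_minor_um.")
  }
  maxval <- 2^p$bit_depth - 1
  for (f in c("band_intensity", "nucleus_intensity", "background_intensity")) {
    check_number(p[[f]], f, min = 0, max = maxval)
  }
  structure(p, class = "tissue_phantom_params")
}

# Analytic centerline in micrometre coordinates (x across, y down), densely
# sampled by arc length, with the closed-form (or quadrature) total length.
phantom_centerline <- function(p) {
  H_um <- p$image_height_px * p$pixel_size_um
  W_um <- p$image_width_px * p$pixel_size_um
  margin <- p$band_thickness_um / 2 + p$nucleus_major_um + 1
  n_dense <- 4096L
  if (p$centerline_kind == "straight") {
    x0 <- margin
    x1 <- W_um - margin
    if (x1 <= x0) abort("straight centerline does not fit the canvas.")
    x <- seq(x0, x1, length.out = n_dense)
    y <- rep(H_um / 2, n_dense)
    length_um <- x1 - x0
  } else if (p$centerline_kind == "sinusoid") {
    x0 <- margin
    x1 <- W_um - margin
    if (x1 <= x0) abort("sinusoid centerline does not fit the canvas.")
    x <- seq(x0, x1, length.out = n_dense)
    y <- H_um / 2 + p$amplitude_um * sin(2 * pi * (x - x0) / p$wavelength_um)
    dyd <- function(t) {
      2 * pi * p$amplitude_um / p$wavelength_um * cos(2 * pi * (t - x0) / p$wavelength_um)
    }
    length_um <- integrate(function(t) sqrt(1 + dyd(t)^2), x0, x1,
      rel.tol = 1e-9, subdivisions = 1000L
    )$value
  } else { # arc centred on the canvas, opening downwards
    cy <- H_um / 2 - p$arc_radius_um / 2
    cx <- W_um / 2
    th <- seq((pi - p$arc_span_rad) / 2, (pi + p$arc_span_rad) / 2,
      length.out = n_dense
    )
    x <- cx + p$arc_radius_um * cos(pi - th)
    y <- cy + p$arc_radius_um * sin(th)
    length_um <- p$arc_radius_um * p$arc_span_rad
  }
  if (any(x < margin - 1e-9) || any(x > W_um - margin + 1e-9) ||
    any(y < margin - 1e-9) || any(y > H_um - margin + 1e-9)) {
    abort(paste0(
      "centerline geometry does not fit the canvas with a clearance of ",
      sprintf("%.1f um; enlarge the image or shrink the band.", margin)
    ))
  }
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  # unit tangents by central differences
  tx <- c(x[2] - x[1], x[-1] - x[-n_dense])
  ty <- c(y[2] - y[1], y[-1] - y[-n_dense])
  nrm <- sqrt(tx^2 + ty^2)
  list(
    x = x, y = y, s = s, tx = tx / nrm, ty = ty / nrm,
    length_um = length_um
  )
}

# Render a filled ellipse (centre in um, semi-axes a >= b, orientation theta)
# into logical canvas `m`; returns the linear pixel indices covered.
ellipse_pixels <- function(dims, psz, cx, cy, a, b, theta) {
  r0 <- max(1L, floor((cy - a) / psz))
  r1 <- min(dims[1], ceiling((cy + a) / psz + 1))
  c0 <- max(1L, floor((cx - a) / psz))
  c1 <- min(dims[2], ceiling((cx + a) / psz + 1))
  if (r1 < r0 || c1 < c0) return(integer())
  rows <- r0:r1
  cols <- c0:c1
  yc <- (rows - 0.5) * psz
  xc <- (cols - 0.5) * psz
  dx <- outer(rep(1, length(rows)), xc - cx)
  dy <- outer(yc - cy, rep(1, length(cols)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  hit <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  if (!nrow(hit)) return(integer())
  (cols[hit[, 2]] - 1L) * dims[1] + rows[hit[, 1]]
}

#' Generate a calibrated tissue phantom with exact ground truth
#'
#' Renders a two-channel micrograph — channel 1 the epithelial band, channel 2
#' the nuclei plus optional debris and clutter — together with its exact
#' ground truth. Nuclei are placed at deterministic arc-length spacing
#' `1 / target_density_per_um` along the centerline with seeded jitter bounded
#' so that every centroid stays inside the band; the reported in-band count is
#' therefore exactly `round(target_density_per_um * centerline_length_um)` and
#' the true density is exact by construction, not merely in expectation.
#'
#' @param params A [tissue_phantom_params()] object.
#'
#' @return A list with elements `micrograph` (a [micrograph()]) and `truth`,
#'   a `phantom_truth` list carrying `centerline_length_um`,
#'   `in_band_nucleus_count`, `true_density_per_um`, `nucleus_areas_um2`
#'   (rendered pixel areas), `centroids` (a tibble of fractional pixel
#'   coordinates), and the ground-truth `band_mask`.
#' @export
generate_tissue_phantom <- function(params) {
  stopifnot(inherits(params, "tissue_phantom_params"))
  p <- params
  with_seed(p$seed, {
    H <- p$image_height_px
    W <- p$image_width_px
    psz <- p$pixel_size_um
    curve <- phantom_centerline(p)
    L <- curve$length_um

    # distance-to-centerline raster -> ground-truth band mask
    rows <- pmin(pmax(round(curve$y / psz + 0.5), 1L), H)
    cols <- pmin(pmax(round(curve$x / psz + 0.5), 1L), W)
    z <- matrix(1, H, W)
    z[cbind(rows, cols)] <- 0
    dist_um <- as.matrix(EBImage::distmap(z)) * psz
    band_mask <- dist_um <= p$band_thickness_um / 2
    # cut the band flat at the centerline ends (as a field of view would),
    # so the band's extent matches the generating centerline exactly
    nd <- length(curve$x)
    for (endi in c(1L, nd)) {
      px0 <- c(curve$x[endi], curve$y[endi])
      tg <- c(curve$tx[endi], curve$ty[endi]) * if (endi == 1L) 1 else -1
      cap_r <- p$band_thickness_um / 2 + 2 * psz
      rr <- which(band_mask, arr.ind = TRUE)
      xy <- cbind((rr[, 2] - 0.5) * psz, (rr[, 1] - 0.5) * psz)
      near <- sqrt((xy[, 1] - px0[1])^2 + (xy[, 2] - px0[2])^2) <= cap_r
      beyond <- (xy[, 1] - px0[1]) * tg[1] + (xy[, 2] - px0[2]) * tg[2] < 0
      band_mask[rr[near & beyond, , drop = FALSE]] <- FALSE
    }

    n <- round(p$target_density_per_um * L)
    jt <- if (n > 0) min(0.25 * L / n, 1.0) else 0
    jn <- max(0, p$band_thickness_um / 2 - p$nucleus_minor_um - 0.3)

    nuc_lgl <- matrix(FALSE, H, W)
    areas <- numeric(n)
    cent <- matrix(NA_real_, n, 2)
    if (n > 0) {
      sk <- (seq_len(n) - 0.5) * L / n
      bx <- approx(curve$s, curve$x, xout = sk, rule = 2)$y
      by <- approx(curve$s, curve$y, xout = sk, rule = 2)$y
      tx <- approx(curve$s, curve$tx, xout = sk, rule = 2)$y
      ty <- approx(curve$s, curve$ty, xout = sk, rule = 2)$y
      nrm <- sqrt(tx^2 + ty^2)
      tx <- tx / nrm
      ty <- ty / nrm
      # successive nuclei alternate across the band (urothelial nuclei sit
      # in layers, not in single file); the stagger also keeps neighbours
      # from touching when the along-band spacing is below a nucleus length
      stagger <- min(jn, p$nucleus_minor_um + 0.7)
      u <- runif(n, -jt, jt)
      v <- rep_len(c(-stagger, stagger), n) +
        runif(n, -min(0.5, jn - stagger), min(0.5, jn - stagger))
      cx <- bx + u * tx - v * ty
      cy <- by + u * ty + v * tx
      th <- atan2(ty, tx)
      for (k in seq_len(n)) {
        px <- ellipse_pixels(
          c(H, W), psz, cx[k], cy[k],
          p$nucleus_major_um, p$nucleus_minor_um, th[k]
        )
        nuc_lgl[px] <- TRUE
        areas[k] <- length(px) * psz^2
        cent[k, ] <- c(cy[k] / psz + 0.5, cx[k] / psz + 0.5)
      }
    }

    # sub-threshold debris inside the band: 1-2 px specks (< 1 um^2 for
    # pixel sizes below ~0.7 um), kept clear of nuclei so they never merge
    extra_lgl <- matrix(FALSE, H, W)
    grown <- if (any(nuc_lgl)) {
      as.matrix(EBImage::dilate(nuc_lgl * 1, EBImage::makeBrush(3, "box"))) > 0
    } else {
      nuc_lgl
    }
    placed_debris <- 0L
    tries <- 0L
    while (placed_debris < p$debris_count && tries < 100L * (p$debris_count + 1L)) {
      tries <- tries + 1L
      sd_ <- runif(1, 0, L)
      vd <- runif(1, -jn, jn)
      bx <- approx(curve$s, curve$x, xout = sd_, rule = 2)$y
      by <- approx(curve$s, curve$y, xout = sd_, rule = 2)$y
      tx <- approx(curve$s, curve$tx, xout = sd_, rule = 2)$y
      ty <- approx(curve$s, curve$ty, xout = sd_, rule = 2)$y
      r <- round(by / psz + 0.5 + vd * tx / psz)
      cc <- round(bx / psz + 0.5 - vd * ty / psz)
      npx <- sample(1:2, 1)
      rr2 <- c(r, if (npx == 2) r + 1L else NULL)
      cc2 <- rep(cc, npx)
      ok <- all(rr2 >= 2, rr2 <= H - 1, cc2 >= 2, cc2 <= W - 1) &&
        all(band_mask[cbind(rr2, cc2)]) &&
        !any(grown[cbind(rr2, cc2)])
      if (ok) {
        extra_lgl[cbind(rr2, cc2)] <- TRUE
        grown[cbind(rr2, cc2)] <- TRUE
        placed_debris <- placed_debris + 1L
      }
    }

    # nucleus-like clutter well outside the band
    placed_clutter <- 0L
    tries <- 0L
    clear_um <- p$band_thickness_um / 2 + p$nucleus_major_um + 1
    while (placed_clutter < p$clutter_count && tries < 200L * (p$clutter_count + 1L)) {
      tries <- tries + 1L
      r <- sample(seq(4L, H - 4L), 1)
      cc <- sample(seq(4L, W - 4L), 1)
      if (dist_um[r, cc] > clear_um) {
        px <- ellipse_pixels(
          c(H, W), psz, (cc - 0.5) * psz, (r - 0.5) * psz,
          p$nucleus_major_um, p$nucleus_minor_um, runif(1, 0, pi)
        )
        extra_lgl[px] <- TRUE
        placed_clutter <- placed_clutter + 1L
      }
    }

    maxval <- 2^p$bit_depth - 1
    band_ch <- matrix(p$background_intensity, H, W)
    band_ch[band_mask] <- p$band_intensity
    nuc_ch <- matrix(p$background_intensity, H, W)
    nuc_ch[nuc_lgl | extra_lgl] <- p$nucleus_intensity
    if (p$gaussian_noise_sd > 0) {
      band_ch <- band_ch + rnorm(H * W, 0, p$gaussian_noise_sd)
      nuc_ch <- nuc_ch + rnorm(H * W, 0, p$gaussian_noise_sd)
    }
    band_ch <- round(pmin(pmax(band_ch, 0), maxval))
    nuc_ch <- round(pmin(pmax(nuc_ch, 0), maxval))

    truth <- structure(
      list(
        centerline_length_um = L,
        in_band_nucleus_count = as.integer(n),
        true_density_per_um = n / L,
        nucleus_areas_um2 = areas,
        centroids = tibble(
          row = cent[, 1], col = cent[, 2]
        ),
        band_mask = band_mask,
        n_debris = placed_debris,
        n_clutter = placed_clutter,
        params = p
      ),
      class = "phantom_truth"
    )
    list(
      micrograph = micrograph(
        band = band_ch, nuclei = nuc_ch,
        pixel_size_um = psz, bit_depth = p$bit_depth,
        id = sprintf("phantom-%s-seed%d", p$centerline_kind, p$seed)
      ),
      truth = truth
    )
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> length %.2f um, %d nuclei, true density %.4f /um\n",
    x$centerline_length_um, x$in_band_nucleus_count, x$true_density_per_um
  ))
  invisible(x)
}
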