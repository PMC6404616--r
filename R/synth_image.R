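#' Rendering parameters for synthetic plate scans
#'
#' Controls the geometry and noise model used by [render_plate_image()].
#' Spots are hard disks with Gaussian edge smoothing (sigma = radius / 4);
#' the background is a smooth linear gradient plus i.i.d. Gaussian pixel
#' noise; intensities saturate at `saturation_ceiling` (the scanner's
#' dynamic-range ceiling on a 16-bit scale).
#'
#' @param spot_radius_px Spot radius in pixels.
#' @param grid_pitch_px Distance between adjacent grid centers in pixels;
#'   must exceed twice the spot radius.
#' @param margin_px Margin between the outermost centers and the image edge.
#' @param bg_level Mean background level (intensity units).
#' @param bg_gradient_amplitude Peak-to-peak amplitude of the smooth
#'   background gradient.
#' @param pixel_noise_sd Standard deviation of per-pixel Gaussian noise.
#' @param saturation_ceiling Intensity at which pixels clip; must exceed the
#'   background maximum.
#' @param amp_per_density Peak spot amplitude contributed per unit of
#'   requested density; the background-subtracted integrated intensity of a
#'   rendered spot is proportional to density with this single global scale.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `render_params`.
#' @export
render_params <- function(spot_radius_px = 8, grid_pitch_px = 40,
                          margin_px = 30, bg_level = 500,
                          bg_gradient_amplitude = 200, pixel_noise_sd = 20,
                          saturation_ceiling = 60000, amp_per_density = 5,
                          seed = 1L) {
  check_scalar_number(spot_radius_px, "spot_radius_px", min = 1)
  check_scalar_number(grid_pitch_px, "grid_pitch_px", min = 1)
  if (grid_pitch_px <= 2 * spot_radius_px) {
    ps_abort("grid_pitch_px must exceed 2 * spot_radius_px", "config_error")
  }
  check_scalar_number(pixel_noise_sd, "pixel_noise_sd", min = 0)
  check_scalar_number(bg_gradient_amplitude, "bg_gradient_amplitude", min = 0)
  if (saturation_ceiling <= bg_level + bg_gradient_amplitude) {
    ps_abort("saturation_ceiling must exceed the background maximum",
             "config_error")
  }
  structure(
    list(spot_radius_px = spot_radius_px, grid_pitch_px = grid_pitch_px,
         margin_px = margin_px, bg_level = bg_level,
         bg_gradient_amplitude = bg_gradient_amplitude,
         pixel_noise_sd = pixel_noise_sd,
         saturation_ceiling = saturation_ceiling,
         amp_per_density = amp_per_density, seed = as.integer(seed)),
    class = "render_params"
  )
}

#' Render a synthetic plate scan from a density grid
#'
#' Inverse of the digitization stage: draws each layout position as a
#' smoothed disk whose background-subtracted integrated intensity is
#' proportional to the requested colony density, on top of a smooth
#' background gradient with Gaussian pixel noise. Deterministic for a fixed
#' seed. The proportionality constant is `amp_per_density` times the disk
#' profile integral, identical for all spots, so densities are recoverable
#' up to one global scale factor.
#'
#' @param densities Numeric matrix (`n_rows x n_cols` of the layout) of
#'   requested densities; must be non-negative.
#' @param layout A [plate_layout()]; its grid dimensions must match
#'   `densities`.
#' @param params A [render_params()].
#' @return Numeric matrix of pixel intensities (rows = image rows), class
#'   `plate_image`, with attributes `row_centers` / `col_centers` giving the
#'   true spot centers in pixels.
#' @export
render_plate_image <- function(densities, layout, params = render_params()) {
  if (!is.matrix(densities) ||
      nrow(densities) != layout$n_rows || ncol(densities) != layout$n_cols) {
    ps_abort("density grid shape does not match the layout grid",
             "config_error")
  }
  if (any(densities < 0)) {
    ps_abort("densities must be non-negative", "value_error")
  }
  r <- params$spot_radius_px
  pitch <- params$grid_pitch_px
  margin <- params$margin_px
  H <- 2 * margin + (layout$n_rows - 1) * pitch + 1
  W <- 2 * margin + (layout$n_cols - 1) * pitch + 1
  row_centers <- margin + (seq_len(layout$n_rows) - 1) * pitch + 1
  col_centers <- margin + (seq_len(layout$n_cols) - 1) * pitch + 1

  y <- matrix(seq_len(H), nrow = H, ncol = W)
  x <- matrix(seq_len(W), nrow = H, ncol = W, byrow = TRUE)
  img <- params$bg_level +
    params$bg_gradient_amplitude * ((x / W) * 0.6 + (y / H) * 0.4)

  sigma <- r / 4
  ext <- ceiling(r + 4 * sigma)
  # local template coordinates reused for every spot
  dy <- matrix(-ext:ext, nrow = 2 * ext + 1, ncol = 2 * ext + 1)
  dx <- t(dy)
  dist <- sqrt(dy^2 + dx^2)
  profile <- stats::pnorm((r - dist) / sigma)
  for (i in seq_len(layout$n_rows)) {
    for (j in seq_len(layout$n_cols)) {
      d <- densities[i, j]
      if (d <= 0) next
      ys <- (row_centers[i] - ext):(row_centers[i] + ext)
      xs <- (col_centers[j] - ext):(col_centers[j] + ext)
      ky <- ys >= 1 & ys <= H   # clip the template at the image border
      kx <- xs >= 1 & xs <= W
      img[ys[ky], xs[kx]] <- img[ys[ky], xs[kx]] +
        d * params$amp_per_density * profile[ky, kx, drop = FALSE]
    }
  }
  if (params$pixel_noise_sd > 0) {
    img <- img + with_seed(params$seed,
                           matrix(stats::rnorm(H * W, 0, params$pixel_noise_sd),
                                  nrow = H))
  }
  img <- pmin(pmax(img, 0), params$saturation_ceiling)
  structure(img, class = c("plate_image", "matrix"),
            row_centers = row_centers, col_centers = col_centers,
            params = params)
}

#' Write / read a plate image as 16-bit grayscale TIFF
#'
#' Intensities are stored on the 16-bit scale (0-65535); reading returns
#' them on the same scale.
#'
#' @param image Numeric matrix of intensities in `[0, 65535]`.
#' @param path File path (`.tif`/`.tiff`).
#' @export
write_plate_image <- function(image, path) {
  m <- unclass(image) / 65535
  attributes(m) <- list(dim = dim(image))
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_plate_image
#' @return `read_plate_image()` returns a numeric intensity matrix.
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) {
    ps_abort(sprintf("image file not found: %s", path), "io_error")
  }
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]  # take first channel if multi
  m * 65535
}
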