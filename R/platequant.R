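#' Detect the spot grid of a scanned plate image
#'
#' Locates row and column centers by peak-calling the marginal intensity
#' projections (row means and column means) of the image, with an optional
#' exhaustive search over small rotations (the scanner never mounts plates
#' perfectly straight). A detection is accepted only when the expected
#' number of regularly spaced peaks is found on both axes.
#'
#' @param image 2-D numeric intensity matrix.
#' @param expected_rows,expected_cols Expected grid dimensions (>= 2 each).
#' @param rotation_tol Maximum rotation searched/accepted, degrees.
#' @param rotation_step Step of the rotation search, degrees.
#' @param search_rotation Whether to search rotations when the unrotated
#'   detection fails.
#' @return An object of class `grid_fit`: `row_centers`, `col_centers`
#'   (pixel coordinates, strictly increasing), `pitch_row`, `pitch_col`,
#'   `rotation` (degrees) and `quality` (fraction of expected peaks found).
#' @export
detect_grid <- function(image, expected_rows, expected_cols,
                        rotation_tol = 2, rotation_step = 0.5,
                        search_rotation = TRUE) {
  if (length(dim(image)) != 2L) {
    ps_abort("image must be a 2-D single-channel matrix", "value_error")
  }
  if (expected_rows < 2 || expected_cols < 2) {
    ps_abort("expected grid must be at least 2 x 2", "value_error")
  }
  img <- unclass(image)

  try_angle <- function(angle) {
    m <- rotate_image(img, angle)
    rows <- find_axis_peaks(rowMeans(m), expected_rows)
    cols <- find_axis_peaks(colMeans(m), expected_cols)
    quality <- (min(rows$n_found, expected_rows) +
                  min(cols$n_found, expected_cols)) /
      (expected_rows + expected_cols)
    ok <- rows$ok && cols$ok
    list(ok = ok, rows = rows, cols = cols, quality = quality,
         angle = angle)
  }

  fit <- try_angle(0)
  if (!fit$ok && search_rotation) {
    angles <- setdiff(seq(-rotation_tol, rotation_tol, by = rotation_step), 0)
    best <- fit
    for (a in angles) {
      cand <- try_angle(a)
      if (cand$quality > best$quality ||
          (cand$ok && !best$ok)) best <- cand
      if (cand$ok) break
    }
    fit <- best
  }
  if (!fit$ok) {
    ps_abort(sprintf(
      "grid detection failed: found %.0f%% of expected peaks within +/-%.1f degrees",
      100 * fit$quality, rotation_tol), "grid_detection_error")
  }
  structure(
    list(row_centers = fit$rows$centers, col_centers = fit$cols$centers,
         pitch_row = mean(diff(fit$rows$centers)),
         pitch_col = mean(diff(fit$cols$centers)),
         rotation = fit$angle, quality = fit$quality),
    class = "grid_fit"
  )
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf(
    "grid_fit: %d x %d centers, pitch %.1f/%.1f px, rotation %.1f deg, quality %.2f\n",
    length(x$row_centers), length(x$col_centers), x$pitch_row, x$pitch_col,
    x$rotation, x$quality))
  invisible(x)
}

# Peak-call one marginal projection. Returns centers (refined by local
# centroid), the number of peaks found, and whether the detection satisfies
# the count and spacing-regularity requirements.
find_axis_peaks <- function(p, expected_n) {
  len <- length(p)
  fail <- list(centers = numeric(0), n_found = 0L, ok = FALSE)
  if (max(p) - min(p) < 1e-9) return(fail)
  w <- max(3L, 2L * (len %/% (expected_n * 12L)) + 1L)  # odd smoothing window
  ps <- stats::filter(p, rep(1 / w, w), sides = 2)
  ps[is.na(ps)] <- p[is.na(ps)]
  ps <- as.numeric(ps)
  baseline <- stats::median(ps)
  thresh <- baseline + 0.2 * (max(ps) - baseline)
  n <- length(ps)
  cand <- which(ps >= thresh &
                  ps >= c(-Inf, ps[-n]) & ps >= c(ps[-1], -Inf))
  if (!length(cand)) return(fail)
  # collapse plateaus, then greedy non-maximum suppression at min separation
  min_sep <- max(2, floor(0.5 * len / (expected_n + 1)))
  ord <- cand[order(ps[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  n_found <- length(kept)
  if (n_found > expected_n) {
    kept <- kept[seq_len(expected_n)]  # strongest expected_n peaks
  }
  kept <- sort(kept)
  # centroid refinement on the background-subtracted profile
  half <- max(2L, floor(min_sep * 0.8))
  centers <- vapply(kept, function(i) {
    win <- max(1L, i - half):min(n, i + half)
    wts <- pmax(ps[win] - baseline, 0)
    if (sum(wts) == 0) return(as.numeric(i))
    sum(win * wts) / sum(wts)
  }, numeric(1))
  ok <- n_found >= expected_n
  if (ok && expected_n >= 3) {
    d <- diff(centers)
    ok <- stats::sd(d) / mean(d) <= 0.15  # spacing must be regular
  }
  list(centers = centers, n_found = n_found, ok = ok)
}

# Rotate an image about its center (nearest-neighbour resampling,
# median fill outside the source frame).
rotate_image <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  th <- angle_deg * pi / 180
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  sy <- cy + cos(th) * (yy - cy) - sin(th) * (xx - cx)
  sx <- cx + sin(th) * (yy - cy) + cos(th) * (xx - cx)
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  out <- matrix(stats::median(img), H, W)
  out[ok] <- img[cbind(si[ok], sj[ok])]
  out
}

#' Quantify colony spots on a plate image
#'
#' For every layout position, integrates pixel intensity over a disk of
#' radius `radius_px` centered at the fitted grid point, subtracts a local
#' background estimated as the median of an annulus from `radius_px` to
#' `1.6 * radius_px`, and clips the integral at zero. Quality flags:
#' \describe{
#'   \item{EMPTY}{integrated density at or below the spot's detection
#'     limit: `empty_threshold` when supplied, otherwise three times the
#'     annulus noise (MAD) scaled by the square root of the disk area —
#'     the integration noise floor, so a faint-but-real colony on a
#'     treated plate is quantified, not discarded.}
#'   \item{SATURATED}{any disk pixel at or above `saturation_level`.}
#'   \item{CONTAMINATED}{annulus spread (MAD) above `contamination_mad`.}
#'   \item{EDGE}{disk truncated by the image border (quantified on the
#'     available pixels, flagged rather than erroring).}
#' }
#' Densities are relative (arbitrary units); only ratios are meaningful
#' downstream, which is all the growth-score stage needs.
#'
#' @param image 2-D numeric intensity matrix (as passed to [detect_grid()]).
#' @param grid A [detect_grid()] result.
#' @param layout A [plate_layout()] whose grid matches the fit.
#' @param radius_px Integration disk radius; default 0.35 x grid pitch.
#' @param empty_threshold Absolute density below which a spot is EMPTY;
#'   `NULL` for the per-spot noise-floor default.
#' @param saturation_level Intensity treated as sensor saturation.
#' @param contamination_mad Annulus MAD above which a spot is flagged
#'   CONTAMINATED (default `Inf`: disabled).
#' @return data.frame of class `spot_quant` with columns `row`, `col`,
#'   `strain_id`, `is_wt`, `dilution_step`, `integrated_density`,
#'   `local_background`, `flags` (comma-separated, `""` when clean).
#' @export
quantify_spots <- function(image, grid, layout, radius_px = NULL,
                           empty_threshold = NULL, saturation_level = 60000,
                           contamination_mad = Inf) {
  if (length(grid$row_centers) != layout$n_rows ||
      length(grid$col_centers) != layout$n_cols) {
    ps_abort("grid fit dimensions do not match the layout", "value_error")
  }
  img <- unclass(image)
  if (grid$rotation != 0) img <- rotate_image(img, grid$rotation)
  H <- nrow(img); W <- ncol(img)
  pitch <- mean(c(grid$pitch_row, grid$pitch_col))
  r <- radius_px %||% (0.35 * pitch)
  outer_r <- 1.6 * r
  ext <- ceiling(outer_r)

  pos <- layout$positions
  nq <- nrow(pos)
  dens <- bg <- noise_floor <- numeric(nq)
  flags <- vector("list", nq)
  for (q in seq_len(nq)) {
    cy <- grid$row_centers[pos$row[q]]
    cx <- grid$col_centers[pos$col[q]]
    ys <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
    xs <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
    f <- character(0)
    if (cy - ext < 1 || cy + ext > H || cx - ext < 1 || cx + ext > W) {
      f <- c(f, "EDGE")
    }
    win <- img[ys, xs, drop = FALSE]
    dist <- sqrt(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2))
    disk <- dist <= r
    annulus <- dist > r & dist <= outer_r
    local_bg <- stats::median(win[annulus])
    total <- sum(win[disk]) - local_bg * sum(disk)
    dens[q] <- max(0, total)
    bg[q] <- local_bg
    noise_floor[q] <- 3 * stats::mad(win[annulus]) * sqrt(sum(disk))
    if (any(win[disk] >= saturation_level)) f <- c(f, "SATURATED")
    if (is.finite(contamination_mad) &&
        stats::mad(win[annulus]) > contamination_mad) {
      f <- c(f, "CONTAMINATED")
    }
    flags[[q]] <- f
  }
  thr <- if (is.null(empty_threshold)) noise_floor
         else rep(empty_threshold, nq)
  for (q in seq_len(nq)) {
    if (dens[q] <= thr[q]) flags[[q]] <- c(flags[[q]], "EMPTY")
  }
  out <- data.frame(
    row = pos$row, col = pos$col, strain_id = pos$strain_id,
    is_wt = pos$is_wt, dilution_step = pos$dilution_step,
    integrated_density = dens, local_background = bg,
    flags = vapply(flags, paste, character(1), collapse = ",")
  )
  class(out) <- c("spot_quant", "data.frame")
  attr(out, "radius_px") <- r
  attr(out, "empty_threshold") <- unname(thr)
  out
}

#' Collapse a dilution series to one density per strain
#'
#' Serial-dilution spot assays print one strain as several spots of
#' decreasing inoculum. The strain's density is the sum of integrated
#' densities over its usable spots: spots flagged SATURATED, EMPTY,
#' CONTAMINATED or EDGE are excluded. Summation uses all usable spots and
#' is monotone in fitness; for a single-spot pin assay it reduces to the
#' identity.
#'
#' @param density Numeric vector of integrated densities along the series.
#' @param flags Character vector of comma-separated flags per spot (or a
#'   list of character vectors); `""`/`character(0)` means clean.
#' @return The collapsed density (a single number).
#' @export
collapse_dilution_series <- function(density, flags = NULL) {
  n <- length(density)
  if (is.null(flags)) flags <- rep("", n)
  if (is.list(flags)) {
    flags <- vapply(flags, paste, character(1), collapse = ",")
  }
  excl <- c("SATURATED", "EMPTY", "CONTAMINATED", "EDGE")
  usable <- !vapply(strsplit(flags, ","), function(f) any(f %in% excl),
                    logical(1))
  if (!any(usable)) {
    ps_abort("all spots in the dilution series are flagged",
             "missing_data_error")
  }
  sum(density[usable])
}

#' Reduce a spot quantification table to per-strain densities
#'
#' Groups [quantify_spots()] output by strain (positions labelled `EMPTY`
#' in the layout are skipped) and collapses each strain's spots with
#' [collapse_dilution_series()]. Strains whose every spot is flagged come
#' back as `NA` with a warning, never silently dropped.
#'
#' @param quant A `spot_quant` data.frame.
#' @return data.frame with columns `strain` and `density`.
#' @export
quant_to_strain_densities <- function(quant) {
  keep <- quant$strain_id != "EMPTY"
  q <- quant[keep, ]
  strains <- unique(q$strain_id)
  density <- vapply(strains, function(s) {
    rows <- q[q$strain_id == s, ]
    tryCatch(collapse_dilution_series(rows$integrated_density, rows$flags),
             phenolscreen_missing_data_error = function(e) {
               ps_warn(sprintf("strain %s: all spots flagged; density NA", s),
                       "dropped_record")
               NA_real_
             })
  }, numeric(1))
  data.frame(strain = strains, density = unname(density))
}
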