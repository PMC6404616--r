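test_that("grid detection finds every center within 1 px on synthetic plates", {
  pl <- make_rendered_plate(seed = 13)
  fit <- detect_grid(pl$image, pl$layout$n_rows, pl$layout$n_cols)
  expect_lt(max(abs(fit$row_centers - attr(pl$image, "row_centers"))), 1)
  expect_lt(max(abs(fit$col_centers - attr(pl$image, "col_centers"))), 1)
  expect_equal(fit$quality, 1)
  expect_true(!is.unsorted(fit$row_centers, strictly = TRUE))
  expect_true(!is.unsorted(fit$col_centers, strictly = TRUE))
})

test_that("grid detection fails on blank images and excessive rotation", {
  expect_error(detect_grid(matrix(0, 200, 300), 8, 12),
               class = "phenolscreen_grid_detection_error")
  pl <- make_rendered_plate(seed = 13)
  rotated <- phenolscreen:::rotate_image(unclass(pl$image), 10)
  expect_error(detect_grid(rotated, 8, 12, rotation_tol = 2),
               class = "phenolscreen_grid_detection_error")
  expect_error(detect_grid(matrix(0, 10, 10), 1, 5),
               class = "phenolscreen_value_error")
})

test_that("a small within-tolerance rotation is recovered", {
  pl <- make_rendered_plate(seed = 13)
  rotated <- phenolscreen:::rotate_image(unclass(pl$image), 1)
  fit <- detect_grid(rotated, 8, 12, rotation_tol = 2)
  expect_lte(abs(fit$rotation), 2)
  expect_equal(fit$quality, 1)
})

test_that("quantification recovers rendered densities within 5% after rescaling", {
  pl <- make_rendered_plate(seed = 42)
  fit <- detect_grid(pl$image, 8, 12)
  q <- quantify_spots(pl$image, fit, pl$layout)
  truth <- pl$densities[cbind(q$row, q$col)]
  sel <- truth > 0
  scale <- sum(q$integrated_density[sel] * truth[sel]) / sum(truth[sel]^2)
  rel <- abs(q$integrated_density[sel] / scale - truth[sel]) / truth[sel]
  expect_lt(max(rel), 0.05)
})

test_that("quality flags mark empty, saturated and edge-truncated spots", {
  layout <- make_test_layout()
  pl <- make_rendered_plate(layout, seed = 42)
  fit <- detect_grid(pl$image, 8, 12)
  q <- quantify_spots(pl$image, fit, layout)
  at_empty <- q$strain_id == "EMPTY"
  expect_true(all(grepl("EMPTY", q$flags[at_empty])))
  thr <- attr(q, "empty_threshold")
  expect_true(all(q$integrated_density[at_empty] <= thr[at_empty]))
  expect_false(any(grepl("EMPTY", q$flags[!at_empty])))

  # saturating one spot flags it
  dsat <- pl$densities; dsat[1, 2] <- 1e6
  img <- render_plate_image(dsat, layout, pl$params)
  qs <- quantify_spots(img, detect_grid(img, 8, 12), layout,
                       saturation_level = pl$params$saturation_ceiling)
  expect_match(qs$flags[qs$row == 1 & qs$col == 2], "SATURATED")

  # a margin thinner than the annulus truncates border disks: EDGE, no error
  tight <- render_params(margin_px = 12, seed = 1)
  img2 <- render_plate_image(pl$densities, layout, tight)
  q2 <- quantify_spots(img2, detect_grid(img2, 8, 12), layout)
  expect_match(q2$flags[q2$row == 1 & q2$col == 1], "EDGE")
})

test_that("quantification is invariant to a constant intensity offset", {
  pl <- make_rendered_plate(seed = 8)
  fit <- detect_grid(pl$image, 8, 12)
  q1 <- quantify_spots(pl$image, fit, pl$layout)
  q2 <- quantify_spots(unclass(pl$image) + 300, fit, pl$layout)
  sel <- q1$integrated_density > 0 & pl$densities[cbind(q1$row, q1$col)] > 0
  expect_lt(max(abs(q2$integrated_density[sel] / q1$integrated_density[sel]
                    - 1)), 0.01)
})

test_that("denser spots always quantify higher", {
  layout <- make_test_layout()
  dmat <- matrix(500, 8, 12)
  dmat[4, 5] <- 800
  dmat[4, 7] <- 1200
  img <- render_plate_image(dmat, layout, render_params(seed = 2))
  q <- quantify_spots(img, detect_grid(img, 8, 12), layout)
  expect_lt(q$integrated_density[q$row == 4 & q$col == 5],
            q$integrated_density[q$row == 4 & q$col == 7])
})

test_that("dilution series collapse sums usable spots and flags exclusions", {
  expect_equal(collapse_dilution_series(c(100, 10, 1, 0, 0)), 111)
  expect_equal(collapse_dilution_series(c(5000, 10, 1),
                                        c("SATURATED", "", "")), 11)
  expect_equal(collapse_dilution_series(42), 42)  # single-spot pin assay
  expect_error(collapse_dilution_series(c(1, 2), c("SATURATED", "EMPTY")),
               class = "phenolscreen_missing_data_error")
})

test_that("per-strain reduction reports flagged-out strains as NA, not dropped", {
  q <- data.frame(row = c(1, 1), col = c(1, 2),
                  strain_id = c("sA", "sB"), is_wt = FALSE,
                  dilution_step = NA_integer_,
                  integrated_density = c(100, 50),
                  local_background = 0,
                  flags = c("", "SATURATED"))
  class(q) <- c("spot_quant", "data.frame")
  expect_warning(res <- quant_to_strain_densities(q),
                 class = "phenolscreen_dropped_record")
  expect_equal(res$density[res$strain == "sA"], 100)
  expect_true(is.na(res$density[res$strain == "sB"]))
})
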