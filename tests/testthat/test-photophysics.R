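test_that("detect_qds finds isolated emitters and nothing in blank images", {
  expect_equal(nrow(detect_qds(matrix(0L, 32, 32))), 0)
  # 50 well-separated QDs: full recall, no false positives, <1 px error
  cfg <- scan_config(30, c(200, 200), 20, n_line_repeats = 10)
  f <- generate_qd_field(50, cfg, photon_rate_per_us = 5,
                         min_separation_nm = 600, edge_margin_nm = 400,
                         seed = 12)
  stk <- simulate_acquisition(f, cfg, background_fraction = 0,
                              blinking = NULL, channels = "STED",
                              seed = 13)
  det <- detect_qds(stk$channels$STED, pixel_size_nm = 30)
  expect_equal(nrow(det), 50)
  # greedy nearest matching (sites are >> 1 px apart, so unambiguous)
  dmat <- outer(det$x_nm, f$sites$x_nm, `-`)^2 +
    outer(det$y_nm, f$sites$y_nm, `-`)^2
  nearest <- sqrt(apply(dmat, 2, min))
  expect_true(all(nearest < 30))
  expect_equal(sort(apply(dmat, 2, which.min)), 1:50)
})

test_that("sub-diffraction pairs merge into one confocal detection", {
  cfg <- roi_scan(halfwidth_px = 10)
  ctr <- roi_center_nm(cfg)
  stk <- simulate_single_qd(cfg, "confocal", seed = 5,
                            photon_rate_per_us = 10, blinking = NULL,
                            offsets_nm = rbind(c(-50, 0), c(50, 0)))
  det <- detect_qds(stk$channels$confocal, min_distance_px = 3)
  expect_equal(nrow(det), 1)
})

test_that("blink map contracts hold on exact and degenerate inputs", {
  cfg <- roi_scan()
  pred_img <- 100 * render_psf(psf_model("lorentzian", fwhm_nm = 65), cfg,
                               roi_center_nm(cfg))
  # roi equal to prediction -> all considered ON, ratio 0
  bm <- compute_blink_map(pred_img, pred_img)
  expect_equal(blinking_pixel_ratio(bm), 0)
  expect_true(all(bm$on_mask[bm$considered_mask]))
  expect_true(all(bm$considered_mask[bm$on_mask]))
  # all-zero roi -> ratio 1
  bm0 <- compute_blink_map(pred_img * 0, pred_img)
  expect_equal(blinking_pixel_ratio(bm0), 1)
  expect_error(compute_blink_map(pred_img, pred_img * 0), "all-zero")
})

test_that("blinking pixel ratio counts OFF pixels among considered", {
  considered <- matrix(FALSE, 4, 4); considered[1:10] <- TRUE
  on <- considered; on[1:3] <- FALSE  # 3 OFF of 10 considered
  map <- structure(list(roi_counts = matrix(0, 4, 4), on_mask = on,
                        considered_mask = considered, prediction = NULL,
                        background = 0), class = "blink_map")
  expect_equal(blinking_pixel_ratio(map), 0.3)
  map$on_mask <- considered
  expect_equal(blinking_pixel_ratio(map), 0)
  map$on_mask <- considered & FALSE
  expect_equal(blinking_pixel_ratio(map), 1)
  map$considered_mask <- considered & FALSE
  expect_error(blinking_pixel_ratio(map), "empty considered")
})

test_that("blinking ratio is invariant to common rescaling", {
  cfg <- roi_scan()
  stk <- simulate_single_qd(cfg, "STED", seed = 30,
                            background_fraction = 0)
  roi <- stk$channels$STED
  pred <- qd_radial_prediction(roi, 30, fwhm_nm = 65)
  r1 <- blinking_pixel_ratio(compute_blink_map(roi, pred))
  pred5 <- pred
  pred5$signal <- 5 * pred$signal
  pred5$background <- 5 * pred$background
  pred5$prediction <- 5 * pred$prediction
  r5 <- blinking_pixel_ratio(compute_blink_map(5 * roi, pred5))
  expect_equal(r1, r5)
})

test_that("blinking ratio tracks OFF occupancy when lines are fast", {
  # tau_on = tau_off and line time << tau: ratio ~ OFF occupancy 0.5
  bm <- blinking_model(0.5, 0.5, suppression_factor = 1)
  cfg <- roi_scan(halfwidth_px = 5, dwell_time_us = 200,
                  n_line_repeats = 1)
  rats <- sapply(1:120, function(s) {
    stk <- simulate_single_qd(cfg, "STED", seed = 400 + s, blinking = bm,
                              photon_rate_per_us = 4,
                              background_fraction = 0)
    tryCatch({
      pred <- qd_radial_prediction(stk$channels$STED, 30, fwhm_nm = 65)
      blinking_pixel_ratio(compute_blink_map(stk$channels$STED, pred))
    }, error = function(e) NA)
  })
  m <- mean(rats, na.rm = TRUE)
  se <- sd(rats, na.rm = TRUE) / sqrt(sum(!is.na(rats)))
  # 200 us pixels sample the 0.5 ms dwells coarsely; the mean ratio sits
  # near the OFF occupancy
  expect_gt(m, 0.5 - 5 * se - 0.12)
  expect_lt(m, 0.5 + 5 * se + 0.12)
})

test_that("non-blinking QDs are almost never classified OFF", {
  cfg <- roi_scan()
  rats <- sapply(1:30, function(s) {
    stk <- simulate_single_qd(cfg, "STED", seed = 500 + s,
                              blinking = NULL, photon_rate_per_us = 4,
                              background_fraction = 0)
    pred <- qd_radial_prediction(stk$channels$STED, 30, fwhm_nm = 65)
    blinking_pixel_ratio(compute_blink_map(stk$channels$STED, pred))
  })
  expect_lt(mean(rats), 0.05)
})

test_that("mean blinking ratio increases with OFF occupancy", {
  cfg <- roi_scan(dwell_time_us = 20, n_line_repeats = 10)
  mean_ratio <- function(tau_off) {
    bm <- blinking_model(0.45, tau_off, suppression_factor = 1)
    mean(sapply(1:40, function(s) {
      stk <- simulate_single_qd(cfg, "STED", seed = 700 + s,
                                blinking = bm, photon_rate_per_us = 4,
                                background_fraction = 0)
      tryCatch({
        pred <- qd_radial_prediction(stk$channels$STED, 30, fwhm_nm = 65)
        blinking_pixel_ratio(compute_blink_map(stk$channels$STED, pred))
      }, error = function(e) NA)
    }), na.rm = TRUE)
  }
  r <- sapply(c(0.15, 0.45, 1.0), mean_ratio)
  expect_true(all(diff(r) > 0))
})

test_that("integrated brightness sums background-subtracted counts", {
  roi <- matrix(0, 5, 5)
  considered <- matrix(FALSE, 5, 5); considered[2:4, 2:4] <- TRUE
  map <- structure(list(roi_counts = roi, on_mask = considered,
                        considered_mask = considered, prediction = NULL,
                        background = 0), class = "blink_map")
  expect_equal(integrated_brightness(roi, map, 0), 0)
  roi[considered] <- 10
  expect_equal(integrated_brightness(roi, map, 1), 81)
  expect_equal(integrated_brightness(roi, map, 1, pixels = "considered"),
               81)
  # clipping at zero: background larger than counts contributes nothing
  expect_equal(integrated_brightness(roi, map, 20), 0)
})

test_that("brightness responds linearly to the photon rate", {
  cfg <- roi_scan()
  bright <- function(rate) {
    mean(sapply(1:25, function(s) {
      stk <- simulate_single_qd(cfg, "STED", seed = 900 + s,
                                blinking = NULL, photon_rate_per_us = rate,
                                background_fraction = 0,
                                dark_counts_per_us = 0)
      pred <- qd_radial_prediction(stk$channels$STED, 30, fwhm_nm = 65)
      integrated_brightness(stk$channels$STED,
                            compute_blink_map(stk$channels$STED, pred))
    }))
  }
  b <- sapply(c(1, 2, 4), bright)
  expect_equal(b[2] / b[1], 2, tolerance = 0.1)
  expect_equal(b[3] / b[2], 2, tolerance = 0.1)
})

test_that("fit_line_profile is exact on model-generated data", {
  x <- seq(-300, 300, by = 25)
  yl <- 120 / (1 + 4 * x^2 / 65^2)
  fl <- fit_line_profile(x, yl, "lorentzian")
  expect_equal(fl$fwhm_nm, 65, tolerance = 1e-6)
  expect_equal(fl$amplitude, 120, tolerance = 1e-6)
  expect_lt(fl$fit_residual, 1e-6)
  yg <- 80 * exp(-4 * log(2) * (x - 40)^2 / 150^2) + 5
  fg <- fit_line_profile(x, yg, "gaussian")
  expect_equal(fg$fwhm_nm, 150, tolerance = 1e-6)
  expect_equal(fg$offset, 5, tolerance = 1e-6)
  expect_equal(fg$center_nm, 40, tolerance = 1e-5)
  expect_error(fit_line_profile(x[1:4], yl[1:4]), "at least 5")
})

test_that("a double Lorentzian resolves two adjacent peaks", {
  x <- seq(0, 900, by = 30)
  y <- 100 / (1 + 4 * (x - 300)^2 / 70^2) +
    60 / (1 + 4 * (x - 600)^2 / 90^2) + 3
  f2 <- fit_line_profile(x, y, "lorentzian2")
  expect_equal(sort(f2$center_nm), c(300, 600), tolerance = 1e-3)
  expect_equal(sort(f2$fwhm_nm), c(70, 90), tolerance = 1e-3)
})

test_that("simulated STEDsub profiles recover the configured width", {
  cfg <- roi_scan(halfwidth_px = 10)
  fw <- sapply(1:50, function(s) {
    stk <- simulate_single_qd(cfg, c("STED", "STEDonly"), seed = 1200 + s,
                              photon_rate_per_us = 5, blinking = NULL)
    sub <- compute_stedsub(stk$channels$STED, stk$channels$STEDonly)
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    prof <- line_profile(sub, pk[1], 30)
    tryCatch(fit_line_profile(prof$position_nm, prof$counts,
                              "lorentzian")$fwhm_nm,
             error = function(e) NA)
  })
  expect_lt(abs(mean(fw, na.rm = TRUE) / 65 - 1), 0.10)
})

test_that("resolution_vs_power dispatches models and flags sparse points", {
  cfg <- scan_config(30, c(120, 120), 20, n_line_repeats = 10)
  powers <- c(0, 40, 160)
  imgs <- lapply(powers, function(p) {
    fw <- effective_sted_fwhm(250, p, 12)
    f <- generate_qd_field(12, cfg, photon_rate_per_us = 8,
                           min_separation_nm = 700, edge_margin_nm = 400,
                           seed = 40 + p)
    ch <- if (p == 0) "confocal" else "STED"
    stk <- simulate_acquisition(f, cfg, sted_fwhm_nm = max(fw, 30),
                                background_fraction = 0, blinking = NULL,
                                channels = ch, seed = 50 + p)
    stk$channels[[ch]]
  })
  names(imgs) <- powers
  curve <- resolution_vs_power(imgs, 30, n_qds_per_point = 10)
  expect_s3_class(curve, "resolution_curve")
  expect_equal(curve$power_mW, powers)
  expect_true(all(curve$n >= 5))
  # measured widths track the law within a pixel-limited tolerance
  expect_equal(curve$fwhm_nm[1], 250, tolerance = 0.2)
  expect_equal(curve$fwhm_nm[3],
               effective_sted_fwhm(250, 160, 12), tolerance = 0.25)
  # an empty image yields a flagged NA point, not a dropped one
  imgs_bad <- c(imgs, list(`320` = matrix(0L, 120, 120)))
  expect_warning(curve2 <- resolution_vs_power(imgs_bad, 30),
                 "only 0 of")
  expect_equal(nrow(curve2), 4)
  expect_true(is.na(curve2$fwhm_nm[4]))
  expect_equal(attr(curve2, "flagged"), "320")
})

test_that("compare_groups reports rank-sum p, stars, and both effect forms", {
  set.seed(2)
  a <- rnorm(30, 10); b <- a
  cg <- compare_groups(a, b)
  expect_gte(cg$p_value, 0.99)
  expect_equal(cg$stars, "ns")
  expect_equal(cg$effect_pct, 0)
  expect_equal(cg$ratio_pct, 100)
  # clearly separated groups
  cg2 <- compare_groups(rnorm(50, 20, 1), rnorm(50, 10, 1))
  expect_lt(cg2$p_value, 1e-4)
  expect_equal(cg2$stars, "****")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("published group means map to the printed percentage changes", {
  # blinking pixel ratio 0.44 (Mowiol) vs 0.74 (PBS): ~40% mean decrease
  expect_equal(relative_difference_pct(0.44, 0.74), -40.54, tolerance = 1e-3)
  expect_equal(round(-relative_difference_pct(0.44, 0.74)), 41)
  # brightness 826 vs 205 counts: increase to 403% of the PBS mean
  expect_equal(round(ratio_of_means_pct(826, 205)), 403)
  expect_equal(significance_stars(3e-5), "****")
})
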