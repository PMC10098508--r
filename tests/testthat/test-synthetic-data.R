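test_that("generate_qd_field respects counts, separation and clustering", {
  cfg <- scan_config(30, c(334, 334), 20)  # ~10 x 10 um
  expect_equal(nrow(generate_qd_field(0, cfg)$sites), 0)
  f <- generate_qd_field(30, cfg, cluster_probability = 0, seed = 5)
  expect_true(all(f$sites$multiplicity == 1L))
  expect_equal(nrow(f$emitters), 30)
  # pairwise separation, brute force
  f <- generate_qd_field(50, cfg, min_separation_nm = 500, seed = 9)
  d <- as.matrix(dist(f$sites[, c("x_nm", "y_nm")]))
  expect_true(all(d[upper.tri(d)] >= 500))
  # reproducibility
  f2 <- generate_qd_field(50, cfg, min_separation_nm = 500, seed = 9)
  expect_identical(f$sites, f2$sites)
  # infeasible packing errors out
  small <- scan_config(30, c(40, 40), 20)
  expect_error(generate_qd_field(200, small, min_separation_nm = 500,
                                 edge_margin_nm = 100, max_tries = 50),
               "could not place")
  # cluster members stay within the cluster radius
  fc <- generate_qd_field(40, cfg, cluster_probability = 1,
                          max_multiplicity = 4, cluster_radius_nm = 75,
                          seed = 2)
  off <- sqrt((fc$emitters$x_nm - fc$sites$x_nm[fc$emitters$site])^2 +
                (fc$emitters$y_nm - fc$sites$y_nm[fc$emitters$site])^2)
  expect_true(all(off <= 75 + 1e-9))
  expect_true(all(fc$sites$multiplicity >= 2))
})

test_that("blink traces tile the duration with alternating segments", {
  bm <- blinking_model(0.4, 0.6)
  tr <- simulate_blink_trace(bm, 50, seed = 1)
  expect_equal(tr$start_ms[1], 0)
  expect_equal(tr$end_ms[nrow(tr)], 50)
  expect_equal(tr$start_ms[-1], tr$end_ms[-nrow(tr)])
  expect_true(all(tr$state[-1] != tr$state[-nrow(tr)]))
  expect_true(all(tr$end_ms > tr$start_ms))
})

test_that("a never-dark model yields a single full ON segment", {
  bm <- blinking_model(1e9, 1e9, p_on_initial = 1)
  tr <- simulate_blink_trace(bm, 10, seed = 2)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$state, "on")
  expect_equal(trace_on_time_fraction(tr), 1)
})

test_that("long-run ON fraction matches renewal-theory occupancy", {
  bm <- blinking_model(0.3, 0.7, suppression_factor = 1)
  rho <- on_occupancy(bm)
  expect_equal(rho, 0.3)
  se <- occupancy_se(bm, 1e4)
  z <- sapply(1:12, function(s) {
    (trace_on_time_fraction(simulate_blink_trace(bm, 1e4, seed = s)) -
       rho) / se
  })
  expect_lt(abs(mean(z)) * sqrt(12), 3)
  expect_lt(sd(z), 2)  # SE formula calibrated
})

test_that("trace_on_fraction integrates segments exactly", {
  tr <- structure(
    data.frame(state = c("on", "off", "on"),
               start_ms = c(0, 1, 3), end_ms = c(1, 3, 4)),
    class = c("blink_trace", "data.frame"))
  # window fully inside ON, fully OFF, and straddling
  expect_equal(trace_on_fraction(tr, 0, 500), 1)        # [0, 0.5] ms
  expect_equal(trace_on_fraction(tr, 1500, 1000), 0)    # [1.5, 2.5] ms
  expect_equal(trace_on_fraction(tr, 500, 1000), 0.5)   # [0.5, 1.5] ms
  expect_equal(trace_on_fraction(tr, 0, 4000), 0.5)     # whole trace
})

test_that("blinking suppression extends ON dwell in depleted channels", {
  bm <- blinking_model(0.4, 0.4, suppression_factor = 2)
  expect_equal(on_occupancy(bm), 0.5)
  expect_equal(on_occupancy(bm, suppressed = TRUE), 2 / 3)
})

test_that("STEDonly is dark apart from dark counts when background is off", {
  cfg <- roi_scan()
  stk <- simulate_single_qd(cfg, "STEDonly", seed = 4,
                            background_fraction = 0,
                            dark_counts_per_us = 0)
  expect_true(all(stk$channels$STEDonly == 0))
})

test_that("simulated images are non-negative integers", {
  cfg <- roi_scan(n_line_repeats = 3)
  stk <- simulate_single_qd(cfg, c("confocal", "STED", "STEDonly"),
                            seed = 10)
  for (ch in stk$channels) {
    expect_true(all(ch >= 0))
    expect_true(all(ch == round(ch)))
  }
})

test_that("total counts are conserved against the closed-form expectation", {
  # MC mean over seeds vs rate x dwell x sum(PSF) x occupancy
  cfg <- roi_scan(halfwidth_px = 7, dwell_time_us = 20, n_line_repeats = 10)
  tot <- sapply(1:60, function(s) {
    stk <- simulate_single_qd(cfg, "STED", seed = s,
                              background_fraction = 0.3,
                              dark_counts_per_us = 0)
    c(mc = sum(stk$channels$STED), exp = sum(stk$expected$STED))
  })
  expect_equal(tot["exp", 1], tot["exp", 2])  # deterministic expectation
  se <- sd(tot["mc", ]) / sqrt(ncol(tot))
  expect_lt(abs(mean(tot["mc", ]) - tot["exp", 1]), 4 * se + 1e-9)
  # and the expectation itself equals the rendered-PSF closed form
  ctr <- roi_center_nm(cfg)
  psf <- render_psf(psf_model("lorentzian", fwhm_nm = 65), cfg, ctr) +
    0.3 * render_psf(psf_model("donut", donut_scale_nm = 100), cfg, ctr)
  occ <- on_occupancy(blinking_model(), suppressed = TRUE)
  expect_equal(unname(tot["exp", 1]), 3 * 200 * occ * sum(psf),
               tolerance = 1e-6)
})

test_that("splitting the dwell over repeats conserves expected counts", {
  # with blinking disabled, 1/10/100 repeats of 200 us total are equivalent
  totals <- sapply(list(c(200, 1), c(20, 10), c(2, 100)), function(sc) {
    cfg <- roi_scan(dwell_time_us = sc[1], n_line_repeats = sc[2])
    stk <- simulate_single_qd(cfg, "STED", seed = 1, blinking = NULL,
                              background_fraction = 0,
                              dark_counts_per_us = 0)
    sum(stk$expected$STED)
  })
  expect_equal(totals[1], totals[2])
  expect_equal(totals[1], totals[3])
})

test_that("acquisition is reproducible for a fixed seed", {
  cfg <- roi_scan(n_line_repeats = 2)
  a <- simulate_single_qd(cfg, c("STED", "STEDonly"), seed = 77)
  b <- simulate_single_qd(cfg, c("STED", "STEDonly"), seed = 77)
  expect_identical(a$channels, b$channels)
})

test_that("STEDsub of a bright steady emitter recovers the STED PSF width", {
  cfg <- roi_scan(halfwidth_px = 10)
  stk <- simulate_single_qd(cfg, c("STED", "STEDonly"), seed = 21,
                            photon_rate_per_us = 40, blinking = NULL)
  sub <- compute_stedsub(stk$channels$STED, stk$channels$STEDonly)
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  prof <- line_profile(sub, pk[1], cfg$pixel_size_nm)
  ft <- fit_line_profile(prof$position_nm, prof$counts, "lorentzian")
  expect_lt(abs(ft$fwhm_nm - 65), cfg$pixel_size_nm)
})

test_that("cell scenes honour the constructed ground truth exactly", {
  sc <- generate_cell_scene(40, fraction_inside = 0.5,
                            fraction_near_tubulin = 0.75, seed = 31)
  s <- sc$sites
  expect_equal(sum(s$inside), 20)
  expect_equal(sum(s$near_tubulin), 30)
  # flags consistent with the masks by construction
  inside_chk <- qd_inside_mask(cbind(s$x_nm, s$y_nm), sc$vesicle_mask,
                               sc$config$pixel_size_nm)
  expect_equal(inside_chk, s$inside)
  # stored distances equal the exhaustive per-pixel search
  px <- which(sc$tubulin_mask, arr.ind = TRUE)
  for (i in seq_len(10)) {
    d_brute <- min(sqrt(((px[, 2] - 0.5) * sc$config$pixel_size_nm -
                           s$x_nm[i])^2 +
                          ((px[, 1] - 0.5) * sc$config$pixel_size_nm -
                             s$y_nm[i])^2))
    expect_equal(s$distance_nm[i], d_brute)
  }
  expect_equal(s$near_tubulin, s$distance_nm < 200)
})

test_that("extreme inside fractions are honoured", {
  sc1 <- generate_cell_scene(20, fraction_inside = 1, seed = 8)
  expect_true(all(qd_inside_mask(cbind(sc1$sites$x_nm, sc1$sites$y_nm),
                                 sc1$vesicle_mask,
                                 sc1$config$pixel_size_nm)))
  sc0 <- generate_cell_scene(20, fraction_inside = 0, seed = 8)
  expect_false(any(sc0$sites$inside))
})
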