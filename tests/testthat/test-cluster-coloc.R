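test_that("donut central ratio is 0 for an ideal donut and ~1 for a disk", {
  cfg <- roi_scan()
  don <- 200 * render_psf(psf_model("donut", donut_scale_nm = 100), cfg,
                          roi_center_nm(cfg))
  expect_equal(donut_central_ratio(don, c(8, 8)), 0)
  disk <- matrix(0, 15, 15)
  r <- sqrt(outer((1:15 - 8)^2, (1:15 - 8)^2, `+`))
  disk[r <= 5] <- 100
  expect_equal(donut_central_ratio(disk, c(8, 8)), 1, tolerance = 0.01)
  expect_error(donut_central_ratio(don, c(8, 8), ring_radii_px = c(1, 1.4)),
               "fewer than 8")
  expect_error(donut_central_ratio(matrix(1, 15, 15), c(8, 8)),
               "zero donut-crest")
})

test_that("a filled centre raises the ratio monotonically", {
  cfg <- roi_scan()
  ctr <- roi_center_nm(cfg)
  don <- 200 * render_psf(psf_model("donut", donut_scale_nm = 100), cfg, ctr)
  gau <- 200 * render_psf(psf_model("gaussian", fwhm_nm = 80), cfg, ctr)
  ratios <- sapply(c(0, 0.2, 0.5, 1), function(a)
    donut_central_ratio(don + a * gau, c(8, 8)))
  expect_true(all(diff(ratios) > 0))
})

test_that("clusters fill the STEDonly donut centre more than singles", {
  cfg <- roi_scan()
  ratio_for <- function(mult, seed) {
    set.seed(seed)
    off <- if (mult > 1) disk_offsets(mult, 75) else NULL
    stk <- simulate_single_qd(cfg, "STEDonly", seed = seed + 1,
                              offsets_nm = off, photon_rate_per_us = 3)
    ro <- extract_roi(stk$channels$STEDonly, c(8, 8), 7)
    donut_central_ratio(ro$roi, ro$center)
  }
  rs <- sapply(1:40, function(s) ratio_for(1, 2000 + s))
  rc <- sapply(1:40, function(s) ratio_for(sample(2:4, 1), 3000 + s))
  expect_gt(mean(rc), mean(rs))
  expect_lt(mean(rs), 0.1)
})

test_that("classification cutoff separates singles from clusters", {
  expect_equal(classify_multiplicity(0), "single")
  expect_equal(classify_multiplicity(0.3), "single")  # tie -> single
  expect_equal(classify_multiplicity(100), "cluster")
  expect_equal(classify_multiplicity(c(0.1, 0.6)), c("single", "cluster"))
  expect_error(classify_multiplicity(-0.1), ">= 0")
})

test_that("default-cutoff classifier reaches 90% balanced accuracy", {
  cfg <- roi_scan()
  classify_site <- function(mult, seed) {
    set.seed(seed)
    off <- if (mult > 1) disk_offsets(mult, 75) else NULL
    stk <- simulate_single_qd(cfg, "STEDonly", seed = seed + 1,
                              offsets_nm = off, photon_rate_per_us = 3)
    ro <- extract_roi(stk$channels$STEDonly, c(8, 8), 7)
    classify_multiplicity(donut_central_ratio(ro$roi, ro$center))
  }
  set.seed(99)
  mults <- ifelse(runif(100) < 0.3, sample(2:4, 100, replace = TRUE), 1L)
  got <- vapply(seq_along(mults),
                function(i) classify_site(mults[i], 5000 + 7 * i), "")
  truth <- ifelse(mults > 1, "cluster", "single")
  sens <- mean(got[truth == "cluster"] == "cluster")
  spec <- mean(got[truth == "single"] == "single")
  expect_gte((sens + spec) / 2, 0.9)
})

test_that("QDFI counts centres inside the mask under the grid convention", {
  mask <- matrix(FALSE, 4, 4); mask[2, 3] <- TRUE
  px <- 30
  inside_pt <- c((3 - 0.5) * px, (2 - 0.5) * px)
  outside_pt <- c(5, 5)
  expect_equal(qd_fraction_inside(rbind(inside_pt), mask, px), 1)
  expect_equal(qd_fraction_inside(rbind(outside_pt), mask, px), 0)
  expect_equal(qd_fraction_inside(rbind(inside_pt, outside_pt), mask, px),
               0.5)
  # empty mask -> 0; zero QDs -> error
  expect_error(qd_fraction_inside(matrix(0, 0, 2), mask, px), "zero QDs")
  expect_equal(qd_fraction_inside(rbind(inside_pt),
                                  mask & FALSE, px), 0)
  # inside + outside fractions sum to 1
  set.seed(1)
  pts <- cbind(runif(50, 0, 120), runif(50, 0, 120))
  fin <- qd_fraction_inside(pts, mask, px)
  fout <- mean(!qd_inside_mask(pts, mask, px))
  expect_equal(fin + fout, 1)
})

test_that("phantom QDFI equals the constructed fraction exactly", {
  sc <- generate_cell_scene(40, fraction_inside = 0.5, seed = 17)
  got <- qd_fraction_inside(cbind(sc$sites$x_nm, sc$sites$y_nm),
                            sc$vesicle_mask, sc$config$pixel_size_nm)
  expect_identical(got, 0.5)
})

test_that("SFP is the inside/outside single-fraction ratio", {
  expect_equal(compute_sfp(c("single", "cluster"),
                           c("single", "cluster")), 1)
  expect_equal(compute_sfp(rep("cluster", 4), rep("single", 4)), 0)
  # constructed 0.4 inside vs 0.5 outside -> 0.8
  expect_equal(compute_sfp(rep(c("single", "cluster"), c(4, 6)),
                           rep(c("single", "cluster"), c(5, 5))), 0.8)
  expect_error(compute_sfp(rep("single", 3), rep("cluster", 3)),
               "undefined SFP")
  expect_error(compute_sfp(character(0), "single"), "non-empty")
})

test_that("SFP is unbiased on phantoms with equal clustering", {
  # across seeded scenes with equal cluster fractions inside and outside,
  # counting the constructed classes recovers SFP ~ 1
  sfps <- sapply(1:60, function(s) {
    sc <- generate_cell_scene(60, fraction_inside = 0.5,
                              cluster_fraction_inside = 0.3,
                              cluster_fraction_outside = 0.3,
                              config = scan_config(40, c(150, 150), 10),
                              seed = 100 + s)
    cls <- ifelse(sc$sites$multiplicity > 1, "cluster", "single")
    compute_sfp(cls[sc$sites$inside], cls[!sc$sites$inside])
  })
  expect_gt(mean(sfps), 0.9)
  expect_lt(mean(sfps), 1.1)
})

test_that("tubulin distances match the exhaustive oracle exactly", {
  px <- 30
  mask <- matrix(FALSE, 20, 20)
  set.seed(6)
  mask[sample(400, 25)] <- TRUE
  pts <- cbind((sample(20, 8) - 0.5) * px, (sample(20, 8) - 0.5) * px)
  got <- distances_to_tubulin(pts, mask, px)
  # brute-force double loop over every mask pixel
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(pts))) {
    best <- Inf
    for (k in seq_len(nrow(idx))) {
      d <- sqrt(((idx[k, 2] - 0.5) * px - pts[i, 1])^2 +
                  ((idx[k, 1] - 0.5) * px - pts[i, 2])^2)
      best <- min(best, d)
    }
    expect_equal(got[i], best)
  }
})

test_that("distance rules: zero on the mask, 3-4-5 off it", {
  mask <- matrix(FALSE, 10, 10); mask[2, 2] <- TRUE
  px <- 30
  on_pt <- c((2 - 0.5) * px, (2 - 0.5) * px)
  expect_equal(distances_to_tubulin(rbind(on_pt), mask, px), 0)
  # a point 3 px right and 4 px down from the mask pixel: 5 px = 150 nm
  off_pt <- c((5 - 0.5) * px, (6 - 0.5) * px)
  expect_equal(distances_to_tubulin(rbind(off_pt), mask, px), 150)
  expect_error(distances_to_tubulin(rbind(on_pt), mask & FALSE, px),
               "no true pixels")
})

test_that("fraction_within applies a strict threshold", {
  expect_equal(fraction_within(c(0, 0, 0), 200), 1)
  expect_equal(fraction_within(c(200, 250), 200), 0)  # strict <
  expect_equal(fraction_within(c(0, 100, 250, 300), 200), 0.5)
  expect_error(fraction_within(numeric(0), 200), "at least one")
})

test_that("bleed-through recovers known crosstalk and degenerate cases", {
  set.seed(8)
  sig <- matrix(0, 40, 40); sig[10:30, 10:30] <- 50
  mask <- sig > 0
  noisy <- function(s) matrix(rpois(1600, s + 2), 40, 40)
  imgs <- list(
    A = list(A = noisy(sig), B = noisy(0.1 * sig)),
    B = list(A = noisy(0 * sig), B = noisy(sig)))
  masks <- list(A = mask, B = mask)
  bt <- bleedthrough_matrix(imgs, masks)
  expect_equal(diag(bt), c(A = 1, B = 1))
  expect_equal(bt["A", "B"], 0.10, tolerance = 0.03)
  expect_lt(bt["B", "A"], 0.02)
  # identical images in both channels -> off-diagonal 1
  same <- noisy(sig)
  bt2 <- bleedthrough_matrix(list(A = list(A = same, B = same)),
                             list(A = mask))
  expect_equal(bt2["A", "B"], 1)
  # zero own-channel signal is degenerate
  flat <- matrix(2, 40, 40)
  expect_error(bleedthrough_matrix(list(A = list(A = flat, B = flat)),
                                   list(A = mask)),
               "zero own-channel")
})
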