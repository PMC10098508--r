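# Shared fixture builders. Everything is generated in code at test time.

# A field with one emission site at a known position; `offsets_nm` places
# cluster members around it (rows of (dx, dy)).
single_site_field <- function(x_nm, y_nm, photon_rate_per_us = 3,
                              offsets_nm = NULL, fov = c(1e4, 1e4),
                              cluster_radius_nm = 75) {
  if (is.null(offsets_nm)) offsets_nm <- matrix(0, 1, 2)
  offsets_nm <- as.matrix(offsets_nm)
  structure(list(
    sites = data.frame(x_nm = x_nm, y_nm = y_nm,
                       multiplicity = nrow(offsets_nm)),
    emitters = data.frame(site = 1L,
                          x_nm = x_nm + offsets_nm[, 1],
                          y_nm = y_nm + offsets_nm[, 2],
                          photon_rate_per_us = photon_rate_per_us),
    cluster_radius_nm = cluster_radius_nm, fov_nm = fov),
    class = "qd_field")
}

# Small ROI-sized scan centred on one QD: (2h+1) x (2h+1) pixels.
roi_scan <- function(pixel_size_nm = 30, halfwidth_px = 7,
                     dwell_time_us = 20, n_line_repeats = 10) {
  n <- 2 * halfwidth_px + 1
  scan_config(pixel_size_nm, c(n, n), dwell_time_us, n_line_repeats)
}

# Centre of the roi_scan FOV in nm.
roi_center_nm <- function(config) fov_nm(config) / 2

# Simulate one QD (or cluster) and return the requested channel images.
simulate_single_qd <- function(config, channels, seed,
                               photon_rate_per_us = 3,
                               offsets_nm = NULL,
                               background_fraction = 0.4,
                               blinking = blinking_model(),
                               sted_fwhm_nm = 65, donut_scale_nm = 100,
                               dark_counts_per_us = 0.005) {
  ctr <- roi_center_nm(config)
  f <- single_site_field(ctr[1], ctr[2], photon_rate_per_us, offsets_nm,
                         fov = fov_nm(config))
  simulate_acquisition(f, config, sted_fwhm_nm = sted_fwhm_nm,
                       donut_scale_nm = donut_scale_nm,
                       background_fraction = background_fraction,
                       blinking = blinking,
                       dark_counts_per_us = dark_counts_per_us,
                       channels = channels, seed = seed)
}

# Uniform in-disk cluster offsets (the geometry used by the generators).
disk_offsets <- function(k, radius_nm) {
  r <- radius_nm * sqrt(stats::runif(k))
  a <- stats::runif(k, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}
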