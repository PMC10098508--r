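#' Simulate a multi-channel point-scanned acquisition
#'
#' Emulates the acquisition of confocal, STED and STED-only images of a field
#' of blinking quantum dots. For every pixel dwell window (ordered by the
#' line-by-line [pixel_clock()], repeats of a line completing before the next
#' line) and every emitter, the expected photon count is
#' `photon_rate x dwell x PSF x ON-fraction`, where the ON-fraction is the
#' overlap of the emitter's blink trace with the dwell window. Counts are
#' drawn Poisson per pixel per repeat and repeats are summed into the channel
#' image.
#'
#' Channel PSFs:
#' * `confocal`: Gaussian with `confocal_fwhm_nm`;
#' * `STED`: Lorentzian with `sted_fwhm_nm` (super-resolved centre) plus
#'   `background_fraction` times a donut of scale `donut_scale_nm` (the halo
#'   from direct excitation by the depletion beam);
#' * `STEDonly`: `background_fraction` times the donut alone.
#'
#' Each emitter carries one independent continuous blink trace per channel
#' acquisition, spanning the whole scan. In the STED and STEDonly channels
#' the depletion beam suppresses blinking: `tau_on` is multiplied by the
#' model's `suppression_factor`.
#'
#' @param field A [generate_qd_field()] result.
#' @param config A [scan_config()].
#' @param confocal_fwhm_nm Confocal PSF FWHM in nm. Default 250.
#' @param sted_fwhm_nm Effective STED PSF FWHM in nm. Default 65.
#' @param donut_scale_nm Radial scale of the direct-excitation donut in nm.
#'   Default 100.
#' @param background_fraction Peak direct-excitation intensity relative to
#'   the emitter's peak ON photon rate, in \[0, 1\].
#' @param blinking A [blinking_model()], or `NULL` for non-blinking emitters
#'   (always ON).
#' @param dark_counts_per_us Detector dark/background count rate per pixel
#'   per microsecond.
#' @param channels Channel subset to simulate, from
#'   `c("confocal", "STED", "STEDonly")`.
#' @param keep_repeats If `TRUE`, retain the per-repeat line stack
#'   (`repeat x row x col` array) for each channel.
#' @param seed Optional integer seed; one seed deterministically fans out to
#'   per-channel, per-emitter trace substreams and per-channel noise streams.
#' @return An [image_stack] whose `channels` hold the summed count images,
#'   with `line_repeat_stack` (if requested) and `expected` (the noise-free
#'   mean images, using the stationary ON occupancy) alongside.
#' @examples
#' cfg <- scan_config(30, c(32, 32), 20, n_line_repeats = 2)
#' f <- generate_qd_field(2, cfg, photon_rate_per_us = 2, seed = 1)
#' stk <- simulate_acquisition(f, cfg, background_fraction = 0.4, seed = 1)
#' names(stk$channels)
#' @export
simulate_acquisition <- function(field, config,
                                 confocal_fwhm_nm = 250,
                                 sted_fwhm_nm = 65,
                                 donut_scale_nm = 100,
                                 background_fraction = 0.4,
                                 blinking = blinking_model(),
                                 dark_counts_per_us = 0.005,
                                 channels = c("confocal", "STED", "STEDonly"),
                                 keep_repeats = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(field, "qd_field"), inherits(config, "scan_config"))
  channels <- match.arg(channels, c("confocal", "STED", "STEDonly"),
                        several.ok = TRUE)
  if (background_fraction < 0 || background_fraction > 1)
    stop("`background_fraction` must be in [0, 1]", call. = FALSE)
  if (!is.null(blinking)) stopifnot(inherits(blinking, "blinking_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  nr <- config$image_shape_px[1]; nc <- config$image_shape_px[2]
  nrep <- config$n_line_repeats
  dwell <- config$dwell_time_us
  line_period <- nc * dwell + config$flyback_time_us
  dur_ms <- scan_duration_us(config) / 1e3
  em <- field$emitters
  n_em <- nrow(em)

  # PSF components per channel: list of (model, weight)
  comp <- list(
    confocal = list(list(psf_model("gaussian", fwhm_nm = confocal_fwhm_nm), 1)),
    STED = list(
      list(psf_model("lorentzian", fwhm_nm = sted_fwhm_nm), 1),
      list(psf_model("donut", donut_scale_nm = donut_scale_nm),
           background_fraction)),
    STEDonly = list(
      list(psf_model("donut", donut_scale_nm = donut_scale_nm),
           background_fraction)))
  support_nm <- c(confocal = 2 * confocal_fwhm_nm,
                  STED = max(6 * sted_fwhm_nm, 3 * donut_scale_nm),
                  STEDonly = 3 * donut_scale_nm)

  # deterministic substreams: trace seeds per (channel, emitter), one noise
  # seed per channel
  n_ch <- length(channels)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             n_ch * max(n_em, 1L) + n_ch),
                  nrow = max(n_em, 1L) + 1L)

  ctr <- pixel_centers_nm(config)
  out_ch <- list(); out_rep <- list(); out_exp <- list()

  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    sted_like <- ch %in% c("STED", "STEDonly")
    bl <- if (is.null(blinking)) NULL
          else if (sted_like) suppressed_model(blinking) else blinking
    occ <- if (is.null(bl)) 1 else on_occupancy(bl)
    E <- array(0, dim = c(nrep, nr, nc))       # expected signal photons
    E_img <- matrix(0, nr, nc)                 # occupancy-mean image
    for (e in seq_len(n_em)) {
      rate <- em$photon_rate_per_us[e]
      cx <- em$x_nm[e]; cy <- em$y_nm[e]
      rad <- support_nm[[ch]]
      cols <- which(abs(ctr$x_nm - cx) <= rad)
      rows <- which(abs(ctr$y_nm - cy) <= rad)
      if (!length(cols) || !length(rows)) next
      r_nm <- sqrt(outer((ctr$y_nm[rows] - cy)^2, (ctr$x_nm[cols] - cx)^2,
                         `+`))
      psf <- 0
      for (cm in comp[[ch]]) psf <- psf + cm[[2]] * psf_value(cm[[1]], r_nm)
      E_img[rows, cols] <- E_img[rows, cols] +
        rate * dwell * nrep * occ * psf
      if (is.null(bl)) {
        add <- rate * dwell *
          array(rep(as.vector(psf), each = nrep),
                dim = c(nrep, length(rows), length(cols)))
      } else {
        tr <- simulate_blink_trace(bl, dur_ms, seed = seeds[e, ci])
        # dwell-window start times, dims (rep, row, col), all 0-based
        line_start <- t(outer((rows - 1L) * nrep, 0:(nrep - 1L), `+`)) *
          line_period                           # nrep x n_rows
        t_arr <- array(rep(as.vector(line_start), length(cols)),
                       dim = c(nrep, length(rows), length(cols))) +
          array(rep((cols - 1L) * dwell, each = nrep * length(rows)),
                dim = c(nrep, length(rows), length(cols)))
        onf <- trace_on_fraction(tr, as.vector(t_arr), dwell)
        add <- rate * dwell *
          array(rep(as.vector(psf), each = nrep),
                dim = c(nrep, length(rows), length(cols))) *
          array(onf, dim = c(nrep, length(rows), length(cols)))
      }
      E[, rows, cols] <- E[, rows, cols, drop = FALSE] + add
    }
    dark <- dark_counts_per_us * dwell
    set.seed(seeds[max(n_em, 1L) + 1L, ci])
    cnt <- array(stats::rpois(length(E), E + dark), dim = dim(E))
    img <- apply(cnt, c(2, 3), sum)
    storage.mode(img) <- "integer"
    out_ch[[ch]] <- img
    out_exp[[ch]] <- E_img + dark * nrep
    if (keep_repeats) out_rep[[ch]] <- cnt
  }

  image_stack(out_ch, config = config,
              line_repeat_stack = if (keep_repeats) out_rep else NULL,
              expected = out_exp,
              metadata = list(
                confocal_fwhm_nm = confocal_fwhm_nm,
                sted_fwhm_nm = sted_fwhm_nm,
                donut_scale_nm = donut_scale_nm,
                background_fraction = background_fraction,
                dark_counts_per_us = dark_counts_per_us,
                seed = seed))
}
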