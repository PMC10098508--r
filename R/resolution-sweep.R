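#' Measure a resolution-versus-power curve from images
#'
#' For each depletion power: detect quantum dots, fit a 1-pixel-wide line
#' profile along the fast axis through each detection (Gaussian at zero
#' power, i.e. confocal; Lorentzian otherwise), keep the `n_qds_per_point`
#' brightest successfully fitted dots, and report the mean and standard
#' deviation of their FWHMs.
#'
#' @param images Named list mapping depletion power in mW (names coercible
#'   to numeric) to 2D count matrices; typically STEDsub images, or confocal
#'   at power 0.
#' @param pixel_size_nm Pixel size in nm.
#' @param n_qds_per_point Number of dots to average per power. Default 10.
#' @param roi_halfwidth_px ROI half width used around each detection.
#' @param min_distance_px,threshold_sigma Passed to [detect_qds()].
#' @return A [resolution_curve()] with an extra `n` column (dots actually
#'   used) and a `flagged` attribute naming powers where fewer than
#'   `n_qds_per_point` fits succeeded (also raised as a warning; points with
#'   zero fits carry `NA` FWHM rather than being dropped).
#' @export
resolution_vs_power <- function(images, pixel_size_nm, n_qds_per_point = 10L,
                                roi_halfwidth_px = 10L, min_distance_px = 4L,
                                threshold_sigma = 5) {
  if (!is.list(images) || is.null(names(images)) || length(images) < 1L)
    stop("`images` must be a non-empty named list (names = power in mW)",
         call. = FALSE)
  powers <- as.numeric(names(images))
  if (any(is.na(powers)))
    stop("image names must be depletion powers in mW", call. = FALSE)
  o <- order(powers)
  powers <- powers[o]; images <- images[o]
  mean_fwhm <- sd_fwhm <- rep(NA_real_, length(powers))
  n_used <- integer(length(powers))
  flagged <- character(0)
  for (k in seq_along(powers)) {
    img <- images[[k]]
    model <- if (powers[k] == 0) "gaussian" else "lorentzian"
    det <- detect_qds(img, min_distance_px = min_distance_px,
                      threshold_sigma = threshold_sigma)
    fwhms <- numeric(0)
    for (i in seq_len(nrow(det))) {     # ordered brightest first
      if (length(fwhms) >= n_qds_per_point) break
      ro <- extract_roi(img, c(det$row[i], det$col[i]), roi_halfwidth_px)
      prof <- line_profile(img, det$row[i], pixel_size_nm, cols = ro$cols)
      f <- tryCatch(fit_line_profile(prof$position_nm, prof$counts, model),
                    error = function(e) NULL)
      if (!is.null(f) && is.finite(f$fwhm_nm)) fwhms <- c(fwhms, f$fwhm_nm)
    }
    n_used[k] <- length(fwhms)
    if (length(fwhms) > 0) {
      mean_fwhm[k] <- mean(fwhms)
      sd_fwhm[k] <- stats::sd(fwhms)
    }
    if (length(fwhms) < n_qds_per_point) {
      flagged <- c(flagged, as.character(powers[k]))
      warning(sprintf("power %g mW: only %d of %d QDs fitted", powers[k],
                      length(fwhms), n_qds_per_point), call. = FALSE)
    }
  }
  out <- resolution_curve(powers, mean_fwhm, sd_fwhm, n_used)
  attr(out, "flagged") <- flagged
  out
}
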