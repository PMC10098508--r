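#' Analytic point-spread-function models
#'
#' Three radially symmetric profiles cover the channels of a
#' STED / STED-only / confocal acquisition:
#'
#' * `gaussian`: `exp(-4 log(2) r^2 / fwhm^2)` — the confocal detection PSF;
#'   peak 1 at the centre, half maximum at `r = fwhm / 2`.
#' * `lorentzian`: `1 / (1 + 4 r^2 / fwhm^2)` — the effective super-resolved
#'   STED PSF, whose heavier tails match depleted emitters better than a
#'   Gaussian.
#' * `donut`: `(r^2 / s^2) * exp(1 - r^2 / s^2)` with `s = donut_scale_nm` —
#'   an LG01-like ring with an exact zero at the centre and peak 1 on the
#'   ring `r = s`; models the direct-excitation emission produced by the
#'   depletion beam alone.
#'
#' @param kind One of `"gaussian"`, `"lorentzian"`, `"donut"`.
#' @param fwhm_nm Full width at half maximum in nm (gaussian/lorentzian).
#' @param donut_scale_nm Radial scale of the donut ring in nm (donut only).
#' @return An object of class `psf_model`.
#' @examples
#' psf_value(psf_model("lorentzian", fwhm_nm = 100), r_nm = 50)  # 0.5
#' @export
psf_model <- function(kind = c("gaussian", "lorentzian", "donut"),
                      fwhm_nm = NULL, donut_scale_nm = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("gaussian", "lorentzian")) {
    if (is.null(fwhm_nm) || !is.numeric(fwhm_nm) || fwhm_nm <= 0)
      stop("`fwhm_nm` must be a positive number for ", kind, call. = FALSE)
    fwhm_nm <- as.numeric(fwhm_nm)
  } else {
    if (is.null(donut_scale_nm) || !is.numeric(donut_scale_nm) ||
        donut_scale_nm <= 0)
      stop("`donut_scale_nm` must be a positive number for a donut",
           call. = FALSE)
    donut_scale_nm <- as.numeric(donut_scale_nm)
  }
  structure(list(kind = kind, fwhm_nm = fwhm_nm,
                 donut_scale_nm = donut_scale_nm, peak_amplitude = 1),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  if (x$kind == "donut")
    cat(sprintf("PSF model: donut (scale %g nm, central zero, peak 1 at ring)\n",
                x$donut_scale_nm))
  else
    cat(sprintf("PSF model: %s (FWHM %g nm, peak 1)\n", x$kind, x$fwhm_nm))
  invisible(x)
}

#' Evaluate a PSF profile at radial distances
#'
#' @param model A [psf_model()].
#' @param r_nm Radial distances from the emitter centre, in nm.
#' @return Dimensionless intensities in \[0, 1\].
#' @export
psf_value <- function(model, r_nm) {
  stopifnot(inherits(model, "psf_model"))
  r2 <- r_nm^2
  switch(model$kind,
         gaussian = exp(-4 * log(2) * r2 / model$fwhm_nm^2),
         lorentzian = 1 / (1 + 4 * r2 / model$fwhm_nm^2),
         donut = {
           u <- r2 / model$donut_scale_nm^2
           u * exp(1 - u)
         })
}

#' Render a PSF onto a scan pixel grid
#'
#' Pixel values are the profile evaluated at pixel centres (no area
#' integration); pixel centres sit at half-integer grid positions, see
#' [scan_config()].
#'
#' @param model A [psf_model()].
#' @param config A [scan_config()] defining the grid.
#' @param center_nm Emitter centre `c(x, y)` in nm.
#' @return A `rows x cols` matrix of dimensionless intensities.
#' @examples
#' cfg <- scan_config(30, c(21, 21), 10)
#' img <- render_psf(psf_model("donut", donut_scale_nm = 120), cfg,
#'                   center_nm = c(315, 315))
#' img[11, 11]  # exact central zero
#' @export
render_psf <- function(model, config, center_nm) {
  stopifnot(inherits(model, "psf_model"), inherits(config, "scan_config"),
            length(center_nm) == 2L)
  ctr <- pixel_centers_nm(config)
  dx2 <- (ctr$x_nm - center_nm[1])^2          # length cols
  dy2 <- (ctr$y_nm - center_nm[2])^2          # length rows
  r <- sqrt(outer(dy2, dx2, `+`))             # rows x cols
  psf_value(model, r)
}

#' Effective STED resolution at a given depletion power
#'
#' The standard square-root depletion law
#' `FWHM(I) = confocal_fwhm / sqrt(1 + I / I_sat)`: the confocal width at
#' zero depletion power, shrinking with the saturation-scaled power.
#'
#' @param confocal_fwhm_nm Confocal FWHM in nm (> 0).
#' @param power_mW Depletion power in mW (>= 0); vectorized.
#' @param saturation_power_mW Saturation power in mW (> 0).
#' @return Effective FWHM in nm.
#' @examples
#' effective_sted_fwhm(240, 0, 50)        # 240
#' effective_sted_fwhm(240, 150, 50)      # 120
#' @export
effective_sted_fwhm <- function(confocal_fwhm_nm, power_mW,
                                saturation_power_mW) {
  if (!is.numeric(confocal_fwhm_nm) || confocal_fwhm_nm <= 0)
    stop("`confocal_fwhm_nm` must be > 0", call. = FALSE)
  if (!is.numeric(saturation_power_mW) || saturation_power_mW <= 0)
    stop("`saturation_power_mW` must be > 0", call. = FALSE)
  if (!is.numeric(power_mW) || any(power_mW < 0))
    stop("`power_mW` must be >= 0", call. = FALSE)
  confocal_fwhm_nm / sqrt(1 + power_mW / saturation_power_mW)
}
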