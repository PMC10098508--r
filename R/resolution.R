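#' Resolution-versus-depletion-power curve
#'
#' A container for a measured resolution curve: for each depletion power the
#' mean fitted FWHM over a set of quantum dots, its standard deviation, and
#' the number of dots averaged.
#'
#' @param powers_mW Strictly increasing depletion powers in mW.
#' @param fwhm_nm Mean FWHM per power in nm.
#' @param fwhm_sd_nm Optional standard deviation per power in nm.
#' @param n_per_point Optional number of QDs averaged per point.
#' @return A data.frame of class `resolution_curve`.
#' @export
resolution_curve <- function(powers_mW, fwhm_nm, fwhm_sd_nm = NA_real_,
                             n_per_point = NA_integer_) {
  if (length(powers_mW) != length(fwhm_nm))
    stop("`powers_mW` and `fwhm_nm` must have equal length", call. = FALSE)
  if (any(diff(powers_mW) <= 0))
    stop("`powers_mW` must be strictly increasing", call. = FALSE)
  out <- data.frame(power_mW = as.numeric(powers_mW),
                    fwhm_nm = as.numeric(fwhm_nm),
                    fwhm_sd_nm = as.numeric(fwhm_sd_nm),
                    n = as.integer(n_per_point))
  class(out) <- c("resolution_curve", "data.frame")
  out
}

#' Fit the depletion-power resolution law to a measured curve
#'
#' Least-squares fit of [effective_sted_fwhm()],
#' `FWHM(I) = d_c / sqrt(1 + I / I_sat)`, to mean FWHM measurements at a set
#' of depletion powers, estimating the confocal width `d_c` and the
#' saturation power `I_sat`.
#'
#' @param curve A [resolution_curve()] or a data.frame with columns
#'   `power_mW` and `fwhm_nm`; at least 3 distinct powers.
#' @return An object of class `resolution_fit` with components
#'   `confocal_fwhm_nm`, `saturation_power_mW`, `residual_norm`, the fitted
#'   `curve`, and the underlying `nls` fit. Supports `print()`, `coef()`,
#'   `predict()` (at new powers via `newdata = data.frame(power_mW = ...)`),
#'   and `residuals()`.
#' @examples
#' p <- c(0, 10, 25, 50, 100, 200)
#' cv <- resolution_curve(p, effective_sted_fwhm(240, p, 50))
#' coef(fit_resolution_curve(cv))
#' @export
fit_resolution_curve <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("power_mW", "fwhm_nm") %in% names(curve)))
    stop("`curve` must have columns `power_mW` and `fwhm_nm`", call. = FALSE)
  curve <- curve[is.finite(curve$power_mW) & is.finite(curve$fwhm_nm), ]
  if (length(unique(curve$power_mW)) < 3L)
    stop("need at least 3 distinct depletion powers to fit the resolution law",
         call. = FALSE)
  d0_start <- max(curve$fwhm_nm)
  # I_sat start: power at which fwhm ~ d0/sqrt(2), i.e. ratio^2 - 1 = 1
  ratio2 <- pmax((d0_start / curve$fwhm_nm)^2 - 1, .Machine$double.eps)
  pos <- curve$power_mW > 0
  psat_start <- if (any(pos)) stats::median(curve$power_mW[pos] / ratio2[pos])
                else 1
  psat_start <- max(psat_start, 1e-3)
  fit <- minpack.lm::nls.lm(
    par = c(d0 = d0_start, psat = psat_start),
    lower = c(d0 = 1e-6, psat = 1e-9),
    fn = function(p)
      curve$fwhm_nm - p[["d0"]] / sqrt(1 + curve$power_mW / p[["psat"]]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9))
    stop("resolution-law fit failed to converge: ", fit$message,
         call. = FALSE)
  structure(
    list(confocal_fwhm_nm = fit$par[["d0"]],
         saturation_power_mW = fit$par[["psat"]],
         residual_norm = sqrt(sum(fit$fvec^2)),
         curve = curve, fit = fit),
    class = "resolution_fit")
}

#' @export
print.resolution_fit <- function(x, ...) {
  cat("Depletion-power resolution law: FWHM(I) = d_c / sqrt(1 + I / I_sat)\n")
  cat(sprintf("  confocal FWHM d_c:    %.1f nm\n", x$confocal_fwhm_nm))
  cat(sprintf("  saturation power:     %.2f mW\n", x$saturation_power_mW))
  cat(sprintf("  residual norm:        %.3g nm (%d points)\n",
              x$residual_norm, nrow(x$curve)))
  invisible(x)
}

#' @export
coef.resolution_fit <- function(object, ...) {
  c(confocal_fwhm_nm = object$confocal_fwhm_nm,
    saturation_power_mW = object$saturation_power_mW)
}

#' @export
predict.resolution_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$curve$power_mW else newdata$power_mW
  effective_sted_fwhm(object$confocal_fwhm_nm, p, object$saturation_power_mW)
}

#' @export
residuals.resolution_fit <- function(object, ...) {
  object$curve$fwhm_nm - predict(object)
}

#' @export
plot.resolution_fit <- function(x, ...) {
  plot(x$curve$power_mW, x$curve$fwhm_nm, xlab = "Depletion power (mW)",
       ylab = "FWHM (nm)", pch = 19, ...)
  pp <- seq(min(x$curve$power_mW), max(x$curve$power_mW), length.out = 200)
  graphics::lines(pp, effective_sted_fwhm(x$confocal_fwhm_nm, pp,
                                          x$saturation_power_mW))
  invisible(x)
}
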