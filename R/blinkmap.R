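#' Radial model prediction for a quantum-dot ROI
#'
#' Builds the expected (non-blinking) count image of a single quantum dot
#' from its fitted radial profile: a 1D profile fit along the fast axis
#' through the brightest row gives the width and centre, and the full-ON
#' amplitude is estimated from the brightest rows (per-row least-squares
#' scales against the radial model, taking their maximum, on the premise
#' that the brightest lines were recorded with the dot fully ON).
#'
#' @param roi 2D count matrix centred on a detected quantum dot.
#' @param pixel_size_nm Pixel size in nm.
#' @param fwhm_nm Optional known PSF FWHM in nm; when `NULL` it is fitted
#'   from the ROI.
#' @param model Radial profile shape, `"lorentzian"` (default, STED-like) or
#'   `"gaussian"`.
#' @param bright_row_fraction Rows whose maximum exceeds this fraction of
#'   the global row maximum are treated as fully ON for the amplitude
#'   estimate. Default 0.75.
#' @return A list of class `qd_prediction`: `prediction` (signal +
#'   background), `signal`, `background` (ROI border median), `amplitude`,
#'   `fwhm_nm`, `center_px` (row, col; sub-pixel, 1-based).
#' @export
qd_radial_prediction <- function(roi, pixel_size_nm, fwhm_nm = NULL,
                                 model = c("lorentzian", "gaussian"),
                                 bright_row_fraction = 0.75) {
  model <- match.arg(model)
  stopifnot(is.matrix(roi), pixel_size_nm > 0)
  if (all(roi == roi[1]))
    stop("degenerate ROI: no peak structure to model", call. = FALSE)
  border <- c(roi[1, ], roi[nrow(roi), ], roi[, 1], roi[, ncol(roi)])
  bg <- stats::median(border)
  sig <- pmax(roi - bg, 0)
  peak <- which(roi == max(roi), arr.ind = TRUE)[1, ]
  # centre from background-subtracted centre of mass near the peak
  ii <- max(1, peak[1] - 2):min(nrow(roi), peak[1] + 2)
  jj <- max(1, peak[2] - 2):min(ncol(roi), peak[2] + 2)
  w <- sig[ii, jj, drop = FALSE]
  ctr <- if (sum(w) > 0)
    c(sum(outer(ii, rep(1, length(jj))) * w),
      sum(outer(rep(1, length(ii)), jj) * w)) / sum(w)
  else as.numeric(peak)
  if (is.null(fwhm_nm)) {
    prof <- line_profile(roi, peak[1], pixel_size_nm)
    pf <- fit_line_profile(prof$position_nm, prof$counts, model = model)
    fwhm_nm <- pf$fwhm_nm
    ctr[2] <- pf$center_nm / pixel_size_nm + 0.5
  }
  x_nm <- (seq_len(ncol(roi)) - ctr[2]) * pixel_size_nm
  y_nm <- (seq_len(nrow(roi)) - ctr[1]) * pixel_size_nm
  r <- sqrt(outer(y_nm^2, x_nm^2, `+`))
  m <- psf_value(psf_model(model, fwhm_nm = fwhm_nm), r)
  # per-row least-squares scale on the brightest rows
  row_max <- apply(sig, 1, max)
  bright <- row_max >= bright_row_fraction * max(row_max)
  usable <- rowSums(m^2) > 0.05 * max(rowSums(m^2))
  rows_amp <- which(bright & usable)
  if (!length(rows_amp)) rows_amp <- which.max(row_max)
  scales <- vapply(rows_amp, function(i)
    sum(sig[i, ] * m[i, ]) / sum(m[i, ]^2), numeric(1))
  amp <- max(scales)
  if (!is.finite(amp) || amp <= 0)
    stop("could not estimate a positive ON amplitude", call. = FALSE)
  structure(list(prediction = amp * m + bg, signal = amp * m,
                 background = bg, amplitude = amp, fwhm_nm = fwhm_nm,
                 center_px = ctr),
            class = "qd_prediction")
}

#' Classify ON/OFF pixels of a quantum dot (blinking mask)
#'
#' Compares a quantum dot's recorded ROI with its expected non-blinking
#' image. Classification is only defined where the expected signal is
#' substantial (`considered_floor` of the predicted peak, default 20%); a
#' considered pixel is ON when its background-subtracted counts reach
#' `off_fraction_cutoff` (default 0.25) of the predicted signal, OFF
#' (blinking) otherwise.
#'
#' @param roi 2D count matrix.
#' @param model_prediction A [qd_radial_prediction()] result, or a plain
#'   matrix of expected counts (then background is taken as 0).
#' @param off_fraction_cutoff ON threshold as a fraction of the predicted
#'   signal, in \[0, 1\].
#' @param considered_floor Fraction of the predicted peak below which pixels
#'   are not classified.
#' @return An object of class `blink_map`: `roi_counts`, `on_mask`,
#'   `considered_mask`, `prediction`, `background`.
#' @export
compute_blink_map <- function(roi, model_prediction,
                              off_fraction_cutoff = 0.25,
                              considered_floor = 0.20) {
  if (inherits(model_prediction, "qd_prediction")) {
    signal <- model_prediction$signal
    bg <- model_prediction$background
    pred <- model_prediction$prediction
  } else {
    stopifnot(is.matrix(model_prediction))
    signal <- model_prediction
    bg <- 0
    pred <- model_prediction
  }
  if (!identical(dim(roi), dim(signal)))
    stop("`roi` and prediction must share one shape", call. = FALSE)
  if (max(signal) <= 0)
    stop("degenerate input: all-zero model prediction", call. = FALSE)
  considered <- signal >= considered_floor * max(signal)
  on <- considered & ((roi - bg) >= off_fraction_cutoff * signal)
  structure(list(roi_counts = roi, on_mask = on,
                 considered_mask = considered, prediction = pred,
                 background = bg),
            class = "blink_map")
}

#' @export
print.blink_map <- function(x, ...) {
  cat(sprintf("Blink map: %d considered px, %d ON, blinking pixel ratio %.2f\n",
              sum(x$considered_mask), sum(x$on_mask),
              blinking_pixel_ratio(x)))
  invisible(x)
}

#' Blinking pixel ratio of a blink map
#'
#' Fraction of considered pixels classified OFF: 0 means the dot never
#' appeared dark inside its footprint, 1 means always dark.
#'
#' @param map A [compute_blink_map()] result.
#' @return Ratio in \[0, 1\].
#' @export
blinking_pixel_ratio <- function(map) {
  stopifnot(inherits(map, "blink_map"))
  n_cons <- sum(map$considered_mask)
  if (n_cons == 0L)
    stop("degenerate input: empty considered mask", call. = FALSE)
  sum(map$considered_mask & !map$on_mask) / n_cons
}

#' Integrated brightness of a quantum dot
#'
#' Background-subtracted sum of counts over the dot's footprint,
#' `sum(max(counts - background_per_px, 0))`. By default the sum runs over
#' the ON pixels of the blinking mask (the pixels carrying the dot's
#' recorded signal); `pixels = "considered"` sums the full classified
#' footprint instead.
#'
#' @param roi 2D count matrix.
#' @param map A [compute_blink_map()] result for the same ROI.
#' @param background_per_px Expected background counts per pixel; defaults
#'   to the background stored in the map.
#' @param pixels `"on"` (default) or `"considered"`.
#' @return Total counts (>= 0).
#' @export
integrated_brightness <- function(roi, map, background_per_px = NULL,
                                  pixels = c("on", "considered")) {
  pixels <- match.arg(pixels)
  stopifnot(inherits(map, "blink_map"))
  if (!identical(dim(roi), dim(map$considered_mask)))
    stop("`roi` and `map` shapes differ", call. = FALSE)
  if (is.null(background_per_px)) background_per_px <- map$background
  sel <- if (pixels == "on") map$on_mask else map$considered_mask
  sum(pmax(roi[sel] - background_per_px, 0))
}
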