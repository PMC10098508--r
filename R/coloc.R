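#' Centre-to-crest intensity ratio of a STED-only donut
#'
#' A single quantum dot excited by the donut-shaped depletion beam alone
#' emits a donut image with (near-)zero central intensity; an unresolved
#' cluster fills the centre because each member sits off the zero of its
#' neighbours' donuts. The ratio of the mean background-subtracted counts
#' inside `inner_radius_px` of the centre to that in the crest annulus
#' `[r1, r2]` is therefore near 0 for singles and elevated for clusters.
#' Background is the ROI border median; both means are floored at 0 before
#' division.
#'
#' @param stedonly_roi 2D count matrix from the STED-only channel.
#' @param center_px `c(row, col)` centre (sub-pixel allowed, 1-based),
#'   typically the position detected in the STEDsub image.
#' @param inner_radius_px Radius of the central disk, in pixels. The default
#'   0.5 keeps only the centre pixel, where a single dot's donut is exactly
#'   zero.
#' @param ring_radii_px `c(r1, r2)` annulus radii in pixels bracketing the
#'   donut crest; must contain at least 8 pixels.
#' @return Ratio >= 0.
#' @export
donut_central_ratio <- function(stedonly_roi, center_px,
                                inner_radius_px = 0.5,
                                ring_radii_px = c(2.5, 4.5)) {
  stopifnot(is.matrix(stedonly_roi), length(center_px) == 2L,
            length(ring_radii_px) == 2L, ring_radii_px[1] < ring_radii_px[2])
  nr <- nrow(stedonly_roi); nc <- ncol(stedonly_roi)
  r <- sqrt(outer((seq_len(nr) - center_px[1])^2,
                  (seq_len(nc) - center_px[2])^2, `+`))
  inner <- r <= inner_radius_px
  ring <- r >= ring_radii_px[1] & r <= ring_radii_px[2]
  if (sum(ring) < 8L)
    stop("crest annulus contains fewer than 8 pixels", call. = FALSE)
  if (!any(inner))
    stop("inner region contains no pixels", call. = FALSE)
  border <- c(stedonly_roi[1, ], stedonly_roi[nr, ],
              stedonly_roi[, 1], stedonly_roi[, nc])
  bg <- stats::median(border)
  inner_mean <- max(mean(stedonly_roi[inner]) - bg, 0)
  ring_mean <- max(mean(stedonly_roi[ring]) - bg, 0)
  if (ring_mean == 0)
    stop("degenerate input: zero donut-crest signal", call. = FALSE)
  inner_mean / ring_mean
}

#' Classify a quantum dot as single or cluster
#'
#' Thresholds the [donut_central_ratio()]: at or below the cutoff the
#' STED-only emission has a dark centre (single dot), above it the centre is
#' filled (cluster). Ties classify as single.
#'
#' @param ratio Donut central ratio (>= 0); vectorized.
#' @param cutoff Classification cutoff. Default 0.3.
#' @return Character vector, `"single"` or `"cluster"`.
#' @examples
#' classify_multiplicity(c(0, 0.31))
#' @export
classify_multiplicity <- function(ratio, cutoff = 0.3) {
  if (any(ratio < 0)) stop("`ratio` must be >= 0", call. = FALSE)
  ifelse(ratio <= cutoff, "single", "cluster")
}

#' Fraction of quantum dots inside a vesicle mask (QDFI)
#'
#' A dot counts as inside when its centre falls in a true mask pixel
#' (centre mapped to the containing pixel under the pixel-centre convention
#' of [scan_config()]; no dilation).
#'
#' @param qd_centers_nm Two-column matrix or data.frame of dot centres
#'   (x_nm, y_nm); at least one dot.
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_size_nm Pixel size of the mask grid in nm.
#' @return Fraction in \[0, 1\].
#' @export
qd_fraction_inside <- function(qd_centers_nm, mask, pixel_size_nm) {
  inside <- qd_inside_mask(qd_centers_nm, mask, pixel_size_nm)
  mean(inside)
}

#' Which quantum dots lie inside a mask
#' @inheritParams qd_fraction_inside
#' @return Logical vector, one element per dot.
#' @export
qd_inside_mask <- function(qd_centers_nm, mask, pixel_size_nm) {
  qd_centers_nm <- as.matrix(qd_centers_nm)
  if (nrow(qd_centers_nm) < 1L)
    stop("degenerate input: zero QDs", call. = FALSE)
  stopifnot(ncol(qd_centers_nm) == 2L, pixel_size_nm > 0)
  mask <- mask != 0
  cols <- floor(qd_centers_nm[, 1] / pixel_size_nm) + 1L
  rows <- floor(qd_centers_nm[, 2] / pixel_size_nm) + 1L
  ok <- rows >= 1L & rows <= nrow(mask) & cols >= 1L & cols <= ncol(mask)
  inside <- logical(nrow(qd_centers_nm))
  inside[ok] <- mask[cbind(rows[ok], cols[ok])]
  inside
}

#' Single fraction parameter (SFP)
#'
#' Ratio of the fraction of single (non-clustered) dots among those inside a
#' vesicle class to the single fraction among those outside:
#' `SFP = single_fraction_inside / single_fraction_outside`. SFP below 1
#' indicates relatively more clustering inside that vesicle type; per-cell
#' values are aggregated as mean +/- dispersion across cells by the caller.
#'
#' @param class_inside Character vector of multiplicity classes
#'   (`"single"`/`"cluster"`) for the dots inside the vesicle masks.
#' @param class_outside Same, for the dots outside.
#' @return SFP >= 0.
#' @examples
#' compute_sfp(rep(c("single", "cluster"), c(2, 3)),
#'             rep(c("single", "cluster"), c(5, 5)))  # 0.8
#' @export
compute_sfp <- function(class_inside, class_outside) {
  if (length(class_inside) < 1L || length(class_outside) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  chk <- c(class_inside, class_outside) %in% c("single", "cluster")
  if (!all(chk))
    stop("classes must be 'single' or 'cluster'", call. = FALSE)
  sf_out <- mean(class_outside == "single")
  if (sf_out == 0)
    stop("undefined SFP: no single QDs outside the vesicle masks",
         call. = FALSE)
  mean(class_inside == "single") / sf_out
}

#' Distance from each quantum dot to the nearest microtubule
#'
#' Euclidean distance from each dot centre to the nearest true pixel centre
#' of the tubulin mask, in nm; 0 when the dot's centre lies inside the mask
#' itself. Distances are centre-to-pixel-centre, without sub-pixel
#' refinement.
#'
#' @param qd_centers_nm Two-column matrix/data.frame of dot centres (nm).
#' @param tubulin_mask Logical (or 0/1) matrix with at least one true pixel.
#' @param pixel_size_nm Pixel size of the mask grid in nm.
#' @return Numeric vector of distances in nm, one per dot.
#' @export
distances_to_tubulin <- function(qd_centers_nm, tubulin_mask, pixel_size_nm) {
  qd_centers_nm <- as.matrix(qd_centers_nm)
  stopifnot(ncol(qd_centers_nm) == 2L, pixel_size_nm > 0)
  tubulin_mask <- tubulin_mask != 0
  if (!any(tubulin_mask))
    stop("tubulin mask has no true pixels", call. = FALSE)
  inside <- qd_inside_mask(qd_centers_nm, tubulin_mask, pixel_size_nm)
  px <- which(tubulin_mask, arr.ind = TRUE)
  mx <- (px[, 2] - 0.5) * pixel_size_nm
  my <- (px[, 1] - 0.5) * pixel_size_nm
  d <- vapply(seq_len(nrow(qd_centers_nm)), function(i) {
    if (inside[i]) return(0)
    sqrt(min((mx - qd_centers_nm[i, 1])^2 + (my - qd_centers_nm[i, 2])^2))
  }, numeric(1))
  d
}

#' Fraction of distances below a threshold
#'
#' Strict comparison (`distance < threshold`), matching the "less than
#' 200 nm" convention for quantum-dot-to-microtubule distances.
#'
#' @param distances_nm Numeric distances (at least one).
#' @param threshold_nm Threshold in nm.
#' @return Fraction in \[0, 1\].
#' @export
fraction_within <- function(distances_nm, threshold_nm) {
  if (length(distances_nm) < 1L)
    stop("need at least one distance", call. = FALSE)
  mean(distances_nm < threshold_nm)
}
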