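#' Detect quantum dots as local intensity maxima
#'
#' Candidate pixels exceed `background median + threshold_sigma x robust
#' sigma` (median absolute deviation, Poisson-floored at `sqrt(median + 1)`),
#' are local maxima of their `(2 min_distance + 1)^2` neighbourhood
#' (non-maximum suppression), pass a local prominence test — the peak must
#' exceed the median of a surrounding annulus by `threshold_sigma` times the
#' noise estimated from that annulus (its MAD, Poisson-floored), which
#' rejects shot-noise maxima riding on halos and on subtraction residue —
#' and are refined to sub-pixel centres by a background-subtracted centre of
#' mass over the 3x3 neighbourhood.
#'
#' @param image 2D count matrix.
#' @param min_distance_px Minimum separation between detections, in pixels.
#' @param threshold_sigma Detection threshold in robust sigmas above the
#'   background median.
#' @param pixel_size_nm Optional pixel size; when given, centres are also
#'   reported in nm (pixel-centre convention of [scan_config()]).
#' @return A data.frame with one row per detection: `row`, `col` (1-based
#'   integer peak pixel), `row_sub`, `col_sub` (sub-pixel), `x_nm`, `y_nm`
#'   (if `pixel_size_nm` given), and `peak_counts`; ordered by decreasing
#'   peak counts. Zero rows when nothing is found.
#' @export
detect_qds <- function(image, min_distance_px = 3L, threshold_sigma = 5,
                       pixel_size_nm = NULL) {
  if (!is.matrix(image) || !length(image))
    stop("`image` must be a non-empty matrix", call. = FALSE)
  bg <- stats::median(image)
  sig <- max(stats::mad(image), sqrt(bg + 1))
  thr <- bg + threshold_sigma * sig
  nr <- nrow(image); nc <- ncol(image)
  cand <- which(image > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  d <- as.integer(min_distance_px)
  for (k in seq_len(nrow(cand))) {
    # local max with deterministic tie-break (first position of a plateau)
    keep[k] <- local_max_first(image, cand[k, 1], cand[k, 2], d) &&
      locally_prominent(image, cand[k, 1], cand[k, 2], d, threshold_sigma)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- data.frame(row = integer(0), col = integer(0),
                      row_sub = numeric(0), col_sub = numeric(0),
                      peak_counts = numeric(0))
  } else {
    rs <- cs <- numeric(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      ii <- max(1, i - 1):min(nr, i + 1); jj <- max(1, j - 1):min(nc, j + 1)
      w <- pmax(image[ii, jj, drop = FALSE] - bg, 0)
      if (sum(w) == 0) { rs[k] <- i; cs[k] <- j; next }
      rs[k] <- sum(outer(ii, rep(1, length(jj))) * w) / sum(w)
      cs[k] <- sum(outer(rep(1, length(ii)), jj) * w) / sum(w)
    }
    out <- data.frame(row = cand[, 1], col = cand[, 2],
                      row_sub = rs, col_sub = cs,
                      peak_counts = image[cand])
    out <- out[order(-out$peak_counts), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(pixel_size_nm)) {
    out$x_nm <- (out$col_sub - 0.5) * pixel_size_nm
    out$y_nm <- (out$row_sub - 0.5) * pixel_size_nm
  }
  out
}

# Prominence test: the peak must stand threshold_sigma local noise units
# above the median of an annulus at radii (d + 2)..(d + 5) pixels.
locally_prominent <- function(image, i, j, d, threshold_sigma) {
  nr <- nrow(image); nc <- ncol(image)
  r_out <- d + 5L
  ii <- max(1, i - r_out):min(nr, i + r_out)
  jj <- max(1, j - r_out):min(nc, j + r_out)
  rr <- sqrt(outer((ii - i)^2, (jj - j)^2, `+`))
  ring <- image[ii, jj, drop = FALSE][rr >= d + 2 & rr <= r_out]
  if (length(ring) < 8L) return(TRUE)
  m <- stats::median(ring)
  s <- max(stats::mad(ring), sqrt(max(m, 0) + 1))
  image[i, j] >= m + threshold_sigma * s
}

# Tie-break helper: TRUE if (i, j) is the first (column-major) position
# attaining the neighbourhood maximum, so plateaus yield one detection.
local_max_first <- function(image, i, j, d) {
  nr <- nrow(image); nc <- ncol(image)
  ii <- max(1, i - d):min(nr, i + d); jj <- max(1, j - d):min(nc, j + d)
  nb <- image[ii, jj, drop = FALSE]
  m <- max(nb)
  if (image[i, j] < m) return(FALSE)
  first <- which(nb == m)[1]
  fi <- ii[(first - 1) %% length(ii) + 1]
  fj <- jj[(first - 1) %/% length(ii) + 1]
  fi == i && fj == j
}

#' Extract a square region of interest around a centre pixel
#'
#' @param image 2D matrix.
#' @param center_px `c(row, col)` (1-based).
#' @param halfwidth_px ROI half width; the ROI is
#'   `(2 halfwidth + 1)^2`, cropped at the image border.
#' @return A list with `roi` (matrix), `rows`, `cols` (index vectors into
#'   `image`), and `center` (the centre's position within the ROI).
#' @export
extract_roi <- function(image, center_px, halfwidth_px = 5L) {
  stopifnot(is.matrix(image), length(center_px) == 2L)
  i <- round(center_px[1]); j <- round(center_px[2])
  rows <- max(1, i - halfwidth_px):min(nrow(image), i + halfwidth_px)
  cols <- max(1, j - halfwidth_px):min(ncol(image), j + halfwidth_px)
  list(roi = image[rows, cols, drop = FALSE], rows = rows, cols = cols,
       center = c(match(i, rows), match(j, cols)))
}
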