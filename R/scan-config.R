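#' Raster-scan configuration
#'
#' Describes the geometry and timing of a point-scanned acquisition: pixel
#' size, image shape, the per-line pixel dwell time, the number of times each
#' line is repeated before the scan moves to the next line, and the dead time
#' between lines. The total dwell per pixel is
#' `dwell_time_us * n_line_repeats`; characterization acquisitions in this
#' package follow schedules totalling 200 us per pixel (1 x 200, 10 x 20, or
#' 100 x 2 us).
#'
#' Conventions used throughout the package: row/column indices are 0-based in
#' all timing and geometry formulas, the fast scan axis runs along columns
#' (x), and the centre of pixel `(i, j)` lies at
#' `((j + 0.5) * pixel_size_nm, (i + 0.5) * pixel_size_nm)` in (x, y).
#'
#' @param pixel_size_nm Pixel size in nm (> 0). Typical values 25-30 nm.
#' @param image_shape_px Integer vector `c(rows, cols)`.
#' @param dwell_time_us Pixel dwell time per line repeat, in microseconds.
#' @param n_line_repeats Number of consecutive repeats of each line (>= 1).
#' @param flyback_time_us Dead time appended after each line, in
#'   microseconds. Defaults to 0.
#'
#' @return An object of class `scan_config`.
#' @examples
#' cfg <- scan_config(30, c(64, 64), dwell_time_us = 20, n_line_repeats = 10)
#' scan_duration_us(cfg)
#' @export
scan_config <- function(pixel_size_nm, image_shape_px, dwell_time_us,
                        n_line_repeats = 1L, flyback_time_us = 0) {
  stopifnot(length(pixel_size_nm) == 1L, length(dwell_time_us) == 1L,
            length(n_line_repeats) == 1L, length(image_shape_px) == 2L)
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive number", call. = FALSE)
  if (!is.numeric(dwell_time_us) || dwell_time_us <= 0)
    stop("`dwell_time_us` must be a positive number", call. = FALSE)
  n_line_repeats <- as.integer(n_line_repeats)
  if (is.na(n_line_repeats) || n_line_repeats < 1L)
    stop("`n_line_repeats` must be an integer >= 1", call. = FALSE)
  image_shape_px <- as.integer(image_shape_px)
  if (any(is.na(image_shape_px)) || any(image_shape_px < 1L))
    stop("`image_shape_px` must be positive integers c(rows, cols)",
         call. = FALSE)
  if (!is.numeric(flyback_time_us) || flyback_time_us < 0)
    stop("`flyback_time_us` must be >= 0", call. = FALSE)
  structure(
    list(pixel_size_nm = as.numeric(pixel_size_nm),
         image_shape_px = image_shape_px,
         dwell_time_us = as.numeric(dwell_time_us),
         n_line_repeats = n_line_repeats,
         fast_axis = "columns",
         flyback_time_us = as.numeric(flyback_time_us)),
    class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("Raster scan configuration\n")
  cat(sprintf("  image:  %d x %d px, %.1f nm pixels (%.2f x %.2f um)\n",
              x$image_shape_px[1], x$image_shape_px[2], x$pixel_size_nm,
              x$image_shape_px[2] * x$pixel_size_nm / 1e3,
              x$image_shape_px[1] * x$pixel_size_nm / 1e3))
  cat(sprintf("  dwell:  %g us x %d line repeats (total %g us/px)\n",
              x$dwell_time_us, x$n_line_repeats,
              x$dwell_time_us * x$n_line_repeats))
  if (x$flyback_time_us > 0)
    cat(sprintf("  flyback: %g us/line\n", x$flyback_time_us))
  cat(sprintf("  duration: %.3f ms\n", scan_duration_us(x) / 1e3))
  invisible(x)
}

#' Field of view extent in nm
#' @param config A [scan_config()].
#' @return Numeric `c(width_x_nm, height_y_nm)`.
#' @export
fov_nm <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  c(config$image_shape_px[2], config$image_shape_px[1]) * config$pixel_size_nm
}

#' Pixel-centre coordinates of a scan grid
#'
#' @param config A [scan_config()].
#' @return List with `x_nm` (length cols) and `y_nm` (length rows): the
#'   physical coordinates of pixel centres.
#' @export
pixel_centers_nm <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  px <- config$pixel_size_nm
  list(x_nm = (seq_len(config$image_shape_px[2]) - 0.5) * px,
       y_nm = (seq_len(config$image_shape_px[1]) - 0.5) * px)
}

#' Absolute start time of every pixel dwell window
#'
#' Scanning is line-by-line along the fast (column) axis; all repeats of a
#' row complete before the scan advances to the next row. The start time of
#' the dwell window of pixel `(row, col)` during line repeat `rep`
#' (all 0-based) is
#' `(row * n_line_repeats + rep) * line_period + col * dwell_time_us` with
#' `line_period = cols * dwell_time_us + flyback_time_us`.
#'
#' @param config A [scan_config()].
#' @param rows Optional integer vector of 0-based row indices to restrict the
#'   clock to (defaults to all rows).
#' @return A data.frame with 0-based `row`, `rep`, `col` and `t_start_us`,
#'   ordered by (row, rep, col).
#' @examples
#' pixel_clock(scan_config(30, c(1, 3), 2))$t_start_us  # 0 2 4
#' @export
pixel_clock <- function(config, rows = NULL) {
  stopifnot(inherits(config, "scan_config"))
  nr <- config$image_shape_px[1]; nc <- config$image_shape_px[2]
  if (is.null(rows)) rows <- 0:(nr - 1L)
  rows <- as.integer(rows)
  if (any(rows < 0L | rows >= nr)) stop("row index out of range", call. = FALSE)
  nrep <- config$n_line_repeats
  line_period <- nc * config$dwell_time_us + config$flyback_time_us
  g <- expand.grid(col = 0:(nc - 1L), rep = 0:(nrep - 1L), row = rows,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("row", "rep", "col")]
  g$t_start_us <- (g$row * nrep + g$rep) * line_period +
    g$col * config$dwell_time_us
  g
}

#' Total scan duration in microseconds
#'
#' Closed form: `rows * n_line_repeats * (cols * dwell + flyback)`.
#'
#' @param config A [scan_config()].
#' @return Duration in microseconds.
#' @export
scan_duration_us <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  config$image_shape_px[1] * config$n_line_repeats *
    (config$image_shape_px[2] * config$dwell_time_us + config$flyback_time_us)
}
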