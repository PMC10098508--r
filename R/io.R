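#' Write a count image as TIFF
#'
#' Non-negative integer images up to 65535 counts are written as 16-bit
#' TIFF. Signed or larger-valued images (e.g. unclipped STED-minus-STEDonly
#' differences) are written as 32-bit TIFF with an offset encoding
#' (`(value + 2^17) / 2^18` scaled over the 32-bit range), which
#' round-trips integer counts exactly through [read_count_tiff()].
#' Multi-page output (a list of matrices, or a `repeat x row x col` array)
#' stores one page per line repeat.
#'
#' @param image Matrix, list of matrices, or 3D array (`repeat` first).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_tiff <- function(image, path) {
  if (is.array(image) && length(dim(image)) == 3L)
    image <- lapply(seq_len(dim(image)[1]), function(k) image[k, , ])
  pages <- if (is.list(image)) image else list(image)
  lo <- min(vapply(pages, min, 0)); hi <- max(vapply(pages, max, 0))
  int_ok <- lo >= 0 && hi <= 65535 &&
    all(vapply(pages, function(p) all(p == round(p)), TRUE))
  if (int_ok) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    if (lo < -131072 || hi > 131071)
      stop("image values outside the encodable range [-131072, 131071]",
           call. = FALSE)
    tiff::writeTIFF(lapply(pages, function(p) (p + 131072) / 262144), path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a count TIFF written by [write_count_tiff()]
#'
#' @param path TIFF file path.
#' @param all If `TRUE`, return all pages as a `repeat x row x col` array
#'   (single-page files come back as a matrix unless `all = TRUE`).
#' @return Matrix, or 3D array for multi-page files.
#' @export
read_count_tiff <- function(path, all = FALSE) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  props <- tiff::readTIFF(path, payload = FALSE)
  bits <- props$bits.per.sample[1]
  decode <- function(p) {
    if (!is.null(bits) && bits == 32L) {
      # `as.is` yields wrapped signed int32; recover the unsigned fraction,
      # then undo the offset encoding
      u <- as.numeric(p)
      u[u < 0] <- u[u < 0] + 2^32
      round(matrix(u / (2^32 - 1), nrow(p), ncol(p)) * 262144 - 131072)
    } else p
  }
  pages <- lapply(pages, decode)
  if (length(pages) == 1L && !all) return(pages[[1]])
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                          ncol(pages[[1]])))
  for (k in seq_along(pages)) out[k, , ] <- pages[[k]]
  out
}

#' Write a binary mask as 8-bit TIFF
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask != 0) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask TIFF
#' @param path File path.
#' @return Logical matrix.
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  tiff::readTIFF(path, as.is = TRUE) != 0
}

#' Read a multi-channel image stack from TIFF files
#'
#' Channels are aligned by shape; pixel size and acquisition metadata come
#' from the configuration, never from TIFF tags. Multi-page files keep the
#' page (line-repeat) axis as the first axis of the repeat stack.
#'
#' @param paths Named character vector or list mapping channel role
#'   (`confocal`, `STED`, `STEDonly`, ...) to a TIFF path.
#' @param config Optional [scan_config()].
#' @param metadata Optional acquisition metadata list.
#' @return An [image_stack()]; multi-page inputs populate
#'   `line_repeat_stack` and their summed image.
#' @export
read_image_stack <- function(paths, config = NULL, metadata = list()) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by channel role", call. = FALSE)
  channels <- list(); repeats <- list()
  for (ch in names(paths)) {
    img <- read_count_tiff(paths[[ch]], all = TRUE)
    if (length(dim(img)) == 3L) {
      if (dim(img)[1] > 1L) repeats[[ch]] <- img
      channels[[ch]] <- accumulate_line_repeats(img)
    } else channels[[ch]] <- img
  }
  image_stack(channels, config = config,
              line_repeat_stack = if (length(repeats)) repeats else NULL,
              metadata = metadata)
}

#' Read an analysis configuration from YAML
#'
#' The configuration holds the `scan` geometry (lengths in nm, times in us,
#' powers in mW; no unit parsing), per-channel `psf` parameters, the
#' `blinking` model, detection/classification `thresholds`, `seed`, and an
#' `output` directory. Unspecified values fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list of class `analysis_config` with `scan` realized as a
#'   [scan_config()] and `blinking` as a [blinking_model()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_analysis_config(raw)
}

#' Build an analysis configuration from a list
#' @param raw Named list (as from YAML).
#' @return An `analysis_config` list.
#' @export
as_analysis_config <- function(raw) {
  sc <- raw$scan
  if (is.null(sc)) stop("config lacks a `scan` section", call. = FALSE)
  cfg <- list(
    scan = scan_config(sc$pixel_size_nm,
                       unlist(sc$image_shape_px),
                       sc$dwell_time_us,
                       n_line_repeats = sc$n_line_repeats %||% 1L,
                       flyback_time_us = sc$flyback_time_us %||% 0),
    psf = utils::modifyList(list(confocal_fwhm_nm = 250, sted_fwhm_nm = 65,
                                 donut_scale_nm = 100,
                                 background_fraction = 0.4),
                            raw$psf %||% list()),
    blinking = if (is.null(raw$blinking)) blinking_model()
    else blinking_model(raw$blinking$tau_on_ms %||% 0.45,
                        raw$blinking$tau_off_ms %||% 0.45,
                        raw$blinking$p_on_initial,
                        raw$blinking$suppression_factor %||% 1.5),
    thresholds = utils::modifyList(
      list(detect_min_distance_px = 3, detect_sigma = 5,
           off_fraction_cutoff = 0.25, considered_floor = 0.20,
           roi_halfwidth_px = 5, cluster_cutoff = 0.3,
           near_distance_nm = 200),
      raw$thresholds %||% list()),
    simulate = raw$simulate %||% list(),
    seed = raw$seed %||% 1L,
    output = raw$output %||% ".",
    raw = raw)
  class(cfg) <- "analysis_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable hash of a configuration
#'
#' Polynomial rolling hash (base 257 modulo the Mersenne prime 2^31 - 1) of
#' the canonical YAML serialization; changes whenever any threshold or
#' parameter changes. Used to stamp result files.
#'
#' @param config An `analysis_config` or plain list.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  if (inherits(config, "analysis_config")) config <- config$raw
  txt <- yaml::as.yaml(config)
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write measurement records as CSV with a provenance header
#'
#' Writes a data.frame with stable column order plus `#`-prefixed header
#' comments recording the package version, configuration hash and seed, so
#' that identical configuration and seed reproduce identical files.
#'
#' @param records A data.frame (possibly with zero rows).
#' @param path Output CSV path.
#' @param config Optional configuration (hashed into the header).
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, config = NULL, seed = NULL) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# qdsted %s",
                     as.character(utils::packageVersion("qdsted"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash %s", config_hash(config)), con)
  if (!is.null(seed)) writeLines(sprintf("# seed %s", seed), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path CSV path.
#' @return data.frame (header comments skipped).
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
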