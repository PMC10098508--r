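#' Measure per-quantum-dot photophysics on an image
#'
#' Runs the per-dot measurement chain on a (typically STEDsub) image:
#' detection, radial model prediction, blinking mask, blinking pixel ratio,
#' integrated brightness, and a line-profile FWHM fit.
#'
#' @param image 2D count matrix.
#' @param pixel_size_nm Pixel size in nm.
#' @param fit_model `"lorentzian"` (STED-like images) or `"gaussian"`
#'   (confocal).
#' @param roi_halfwidth_px ROI half width around each detection (default 5,
#'   about 150 nm at 30 nm pixels: the STED PSF and first halo ring).
#' @param min_distance_px,threshold_sigma Passed to [detect_qds()].
#' @param off_fraction_cutoff,considered_floor Passed to
#'   [compute_blink_map()].
#' @param known_fwhm_nm Optional PSF FWHM used for the blink-map prediction
#'   instead of fitting it per dot.
#' @param brightness_pixels Passed to [integrated_brightness()].
#' @param max_qds Optional cap on the number of dots measured (brightest
#'   first).
#' @return data.frame with one row per measured dot: centre (pixels and
#'   nm), `integrated_brightness_counts`, `blinking_pixel_ratio`, `fwhm_nm`
#'   (NA when the profile fit failed), `fit_model`, `n_considered_px`.
#' @export
measure_qd_photophysics <- function(image, pixel_size_nm,
                                    fit_model = c("lorentzian", "gaussian"),
                                    roi_halfwidth_px = 5L,
                                    min_distance_px = 3L,
                                    threshold_sigma = 5,
                                    off_fraction_cutoff = 0.25,
                                    considered_floor = 0.20,
                                    known_fwhm_nm = NULL,
                                    brightness_pixels = "on",
                                    max_qds = Inf) {
  fit_model <- match.arg(fit_model)
  det <- detect_qds(image, min_distance_px, threshold_sigma, pixel_size_nm)
  n <- min(nrow(det), max_qds)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- list(row = det$row[i], col = det$col[i],
                x_nm = det$x_nm[i], y_nm = det$y_nm[i],
                integrated_brightness_counts = NA_real_,
                blinking_pixel_ratio = NA_real_, fwhm_nm = NA_real_,
                fit_model = fit_model, n_considered_px = NA_integer_)
    ro <- extract_roi(image, c(det$row[i], det$col[i]), roi_halfwidth_px)
    res <- tryCatch({
      pred <- qd_radial_prediction(ro$roi, pixel_size_nm,
                                   fwhm_nm = known_fwhm_nm,
                                   model = fit_model)
      bm <- compute_blink_map(ro$roi, pred, off_fraction_cutoff,
                              considered_floor)
      rec$blinking_pixel_ratio <- blinking_pixel_ratio(bm)
      rec$integrated_brightness_counts <-
        integrated_brightness(ro$roi, bm, pixels = brightness_pixels)
      rec$n_considered_px <- sum(bm$considered_mask)
      rec$fwhm_nm <- if (is.null(known_fwhm_nm)) pred$fwhm_nm
      else tryCatch(
        fit_line_profile(
          line_profile(ro$roi, round(pred$center_px[1]),
                       pixel_size_nm)$position_nm,
          ro$roi[round(pred$center_px[1]), ], fit_model)$fwhm_nm,
        error = function(e) NA_real_)
      rec
    }, error = function(e) rec)
    rows[[i]] <- res
  }
  do.call(rbind, c(lapply(rows, function(r) as.data.frame(r)),
                   list(make.row.names = FALSE))) %||%
    data.frame(row = integer(0), col = integer(0), x_nm = numeric(0),
               y_nm = numeric(0), integrated_brightness_counts = numeric(0),
               blinking_pixel_ratio = numeric(0), fwhm_nm = numeric(0),
               fit_model = character(0), n_considered_px = integer(0))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stage sequence of a full experiment on synthetic data:
#' simulate the acquisition, subtract the STED-only background, detect dots
#' and measure blinking/brightness/FWHM, classify single versus cluster from
#' the STED-only donut, and compute colocalization statistics against the
#' scene masks. Every stage's output is persisted under the configured
#' output directory (TIFF images and masks, CSV records, a YAML copy of the
#' parameters, and a log of every threshold used).
#'
#' @param config An `analysis_config` (see [read_analysis_config()]), or a
#'   path to a YAML file.
#' @param mode One of `"simulate"` (write images + ground truth only),
#'   `"photophysics"`, `"coloc"`, or `"full"`.
#' @return Invisibly, a list with the artifacts produced (paths and the key
#'   data.frames / statistics).
#' @export
run_pipeline <- function(config, mode = c("full", "simulate",
                                          "photophysics", "coloc")) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "qdsted.log")
  logf <- function(stage, ...) cat(sprintf("[%s] %s\n", stage,
                                           sprintf(...)),
                                  file = log_path, append = TRUE)
  cat(sprintf("# qdsted pipeline, mode=%s, seed=%d, config=%s\n", mode,
              config$seed, config_hash(config)),
      file = log_path)
  logf("config", "thresholds: %s",
       paste(names(config$thresholds), unlist(config$thresholds),
             sep = "=", collapse = ", "))
  stage <- "simulate"
  res <- tryCatch({
    sim <- config$simulate
    scene <- generate_cell_scene(
      n_qds = sim$n_qds %||% 40,
      n_vesicles = sim$n_vesicles %||% 8,
      vesicle_radius_nm = sim$vesicle_radius_nm %||% 250,
      fraction_inside = sim$fraction_inside %||% 0.5,
      tubulin_density = sim$tubulin_density %||% 6,
      fraction_near_tubulin = sim$fraction_near_tubulin %||% 0.8,
      near_distance_nm = config$thresholds$near_distance_nm,
      config = config$scan,
      cluster_fraction_inside = sim$cluster_fraction_inside %||% 0.3,
      cluster_fraction_outside = sim$cluster_fraction_outside %||% 0.3,
      max_multiplicity = sim$max_multiplicity %||% 4,
      min_separation_nm = sim$min_separation_nm %||% 0,
      seed = config$seed)
    field <- scene_to_field(scene, photon_rate_per_us =
                              sim$photon_rate_per_us %||% 3)
    stk <- simulate_acquisition(
      field, config$scan,
      confocal_fwhm_nm = config$psf$confocal_fwhm_nm,
      sted_fwhm_nm = config$psf$sted_fwhm_nm,
      donut_scale_nm = config$psf$donut_scale_nm,
      background_fraction = config$psf$background_fraction,
      blinking = config$blinking,
      dark_counts_per_us = sim$dark_counts_per_us %||% 0.005,
      seed = config$seed + 1L)
    for (ch in names(stk$channels))
      write_count_tiff(stk$channels[[ch]],
                       file.path(out_dir, paste0(tolower(ch), ".tif")))
    write_mask_tiff(scene$vesicle_mask, file.path(out_dir, "vesicles.tif"))
    write_mask_tiff(scene$tubulin_mask, file.path(out_dir, "tubulin.tif"))
    truth <- scene$sites
    write_results(truth, file.path(out_dir, "ground_truth.csv"),
                  config, config$seed)
    yaml::write_yaml(config$raw, file.path(out_dir, "parameters.yml"))
    logf(stage, "wrote %d QD sites, channels: %s", nrow(truth),
         paste(names(stk$channels), collapse = ", "))
    list(scene = scene, stack = stk)
  }, error = function(e)
    stop(sprintf("stage `%s` failed (inputs: config seed %d): %s", stage,
                 config$seed, conditionMessage(e)), call. = FALSE))
  if (mode == "simulate") return(invisible(res))

  stage <- "process"
  res <- tryCatch({
    res$stack <- add_stedsub(res$stack)
    write_count_tiff(pmax(res$stack$channels$STEDsub, 0),
                     file.path(out_dir, "stedsub.tif"))
    res
  }, error = function(e)
    stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE))

  qds <- NULL
  if (mode %in% c("photophysics", "full")) {
    stage <- "photophysics"
    res <- tryCatch({
      th <- config$thresholds
      qds <- measure_qd_photophysics(
        res$stack$channels$STEDsub, config$scan$pixel_size_nm,
        roi_halfwidth_px = th$roi_halfwidth_px,
        min_distance_px = th$detect_min_distance_px,
        threshold_sigma = th$detect_sigma,
        off_fraction_cutoff = th$off_fraction_cutoff,
        considered_floor = th$considered_floor,
        known_fwhm_nm = config$psf$sted_fwhm_nm)
      write_results(qds, file.path(out_dir, "qds.csv"), config, config$seed)
      logf(stage, "measured %d QDs", nrow(qds))
      res$qds <- qds
      res
    }, error = function(e)
      stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    qds <- res$qds
  }
  if (mode == "photophysics") return(invisible(res))

  stage <- "coloc"
  res <- tryCatch({
    th <- config$thresholds
    if (is.null(qds)) {
      qds <- measure_qd_photophysics(
        res$stack$channels$STEDsub, config$scan$pixel_size_nm,
        roi_halfwidth_px = th$roi_halfwidth_px,
        min_distance_px = th$detect_min_distance_px,
        threshold_sigma = th$detect_sigma,
        known_fwhm_nm = config$psf$sted_fwhm_nm)
    }
    centers <- cbind(qds$x_nm, qds$y_nm)
    if (nrow(centers) == 0L)
      stop("no QDs detected in the STEDsub image")
    # donut central ratio on the STEDonly channel at each detection
    ratios <- vapply(seq_len(nrow(qds)), function(i) {
      ro <- extract_roi(res$stack$channels$STEDonly,
                        c(qds$row[i], qds$col[i]),
                        max(th$roi_halfwidth_px, 5L))
      tryCatch(donut_central_ratio(ro$roi, ro$center),
               error = function(e) NA_real_)
    }, numeric(1))
    cls <- rep("unclassified", length(ratios))
    ok <- !is.na(ratios)
    cls[ok] <- classify_multiplicity(pmax(ratios[ok], 0),
                                     th$cluster_cutoff)
    inside <- qd_inside_mask(centers, res$scene$vesicle_mask,
                             config$scan$pixel_size_nm)
    dists <- distances_to_tubulin(centers, res$scene$tubulin_mask,
                                  config$scan$pixel_size_nm)
    qdfi <- mean(inside)
    sfp <- tryCatch(
      compute_sfp(cls[inside & cls != "unclassified"],
                  cls[!inside & cls != "unclassified"]),
      error = function(e) NA_real_)
    stats_df <- data.frame(
      n_qds = nrow(qds), qdfi = qdfi, sfp = sfp,
      mean_distance_nm = mean(dists),
      median_distance_nm = stats::median(dists),
      fraction_within_near = fraction_within(dists,
                                             th$near_distance_nm))
    coloc <- data.frame(x_nm = centers[, 1], y_nm = centers[, 2],
                        donut_central_ratio = ratios,
                        multiplicity_class = cls, inside_vesicle = inside,
                        distance_to_tubulin_nm = dists)
    write_results(coloc, file.path(out_dir, "coloc.csv"), config,
                  config$seed)
    write_results(stats_df, file.path(out_dir, "stats.csv"), config,
                  config$seed)
    logf(stage, "QDFI %.3f, SFP %.3f, median T %.0f nm", qdfi, sfp,
         stats::median(dists))
    res$coloc <- coloc; res$stats <- stats_df
    res
  }, error = function(e)
    stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  invisible(res)
}

#' Convert a scene phantom's sites into an emitter field
#'
#' Expands the phantom's site table (positions, multiplicity) into a
#' [qd_field] with cluster members offset within `cluster_radius_nm`, ready
#' for [simulate_acquisition()].
#'
#' @param scene A [generate_cell_scene()] phantom.
#' @param photon_rate_per_us Peak ON photon rate per emitter.
#' @param cluster_radius_nm Maximum cluster-member offset. Default 75 nm.
#' @return A `qd_field`.
#' @export
scene_to_field <- function(scene, photon_rate_per_us = 3,
                           cluster_radius_nm = 75) {
  stopifnot(inherits(scene, "scene_phantom"))
  s <- scene$sites
  em_site <- rep(seq_len(nrow(s)), s$multiplicity)
  n_em <- length(em_site)
  off_r <- cluster_radius_nm * sqrt(stats::runif(n_em))
  off_a <- stats::runif(n_em, 0, 2 * pi)
  off_r[s$multiplicity[em_site] == 1L] <- 0
  structure(
    list(sites = data.frame(x_nm = s$x_nm, y_nm = s$y_nm,
                            multiplicity = s$multiplicity),
         emitters = data.frame(site = em_site,
                               x_nm = s$x_nm[em_site] + off_r * cos(off_a),
                               y_nm = s$y_nm[em_site] + off_r * sin(off_a),
                               photon_rate_per_us = photon_rate_per_us),
         cluster_radius_nm = cluster_radius_nm,
         fov_nm = fov_nm(scene$config)),
    class = "qd_field")
}
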