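#' Ground-truth quantum-dot emitter field
#'
#' A `qd_field` holds the positions, brightness and multiplicity of the
#' emission sites in a synthetic scene. A site of multiplicity 1 is a single
#' quantum dot; a site of multiplicity k > 1 is a cluster of k co-located
#' dots at random offsets within `cluster_radius_nm` of the site centre, each
#' blinking independently.
#'
#' @name qd_field
#' @section Fields:
#' `sites`: data.frame with `x_nm`, `y_nm`, `multiplicity`;
#' `emitters`: data.frame with one row per physical emitter (`site`, `x_nm`,
#' `y_nm`, `photon_rate_per_us`); `cluster_radius_nm`; `fov_nm`.
NULL

#' Generate a random field of quantum-dot emission sites
#'
#' Sites are placed uniformly in the field of view with a minimum pairwise
#' separation (dart throwing with a bounded retry budget). Each site is
#' independently a cluster with probability `cluster_probability`; cluster
#' multiplicity is drawn uniformly from `2:max_multiplicity` and the member
#' dots are offset uniformly within a disk of radius `cluster_radius_nm`.
#'
#' @param n_sites Number of emission sites (>= 0).
#' @param fov A [scan_config()] (defines the field of view) .
#' @param photon_rate_per_us Expected detected photons per microsecond per
#'   emitter at the PSF peak while ON.
#' @param cluster_probability Probability a site is a cluster, in \[0, 1\].
#' @param max_multiplicity Maximum number of dots per cluster (>= 2 when
#'   `cluster_probability > 0`).
#' @param cluster_radius_nm Maximum offset of a cluster member from the site
#'   centre, in nm. Default 75 nm: dots confined within a vesicle-sized
#'   region, unresolved or barely resolved at STED resolution.
#' @param min_separation_nm Minimum distance between site centres, in nm.
#' @param edge_margin_nm Margin kept free of sites along the image border.
#' @param seed Optional integer seed.
#' @param max_tries Retry budget per site before a placement error.
#' @return An object of class `qd_field`; see [qd_field].
#' @examples
#' cfg <- scan_config(30, c(64, 64), 20)
#' f <- generate_qd_field(5, cfg, seed = 1)
#' f$sites
#' @export
generate_qd_field <- function(n_sites, fov, photon_rate_per_us = 1,
                              cluster_probability = 0,
                              max_multiplicity = 4L,
                              cluster_radius_nm = 75,
                              min_separation_nm = 0,
                              edge_margin_nm = 300,
                              seed = NULL, max_tries = 2000L) {
  stopifnot(inherits(fov, "scan_config"))
  if (!is.numeric(n_sites) || n_sites < 0)
    stop("`n_sites` must be >= 0", call. = FALSE)
  if (photon_rate_per_us <= 0)
    stop("`photon_rate_per_us` must be > 0", call. = FALSE)
  if (cluster_probability < 0 || cluster_probability > 1)
    stop("`cluster_probability` must be in [0, 1]", call. = FALSE)
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ext <- fov_nm(fov)
  lo <- c(edge_margin_nm, edge_margin_nm)
  hi <- ext - edge_margin_nm
  if (n_sites > 0 && any(hi <= lo))
    stop("field of view too small for the requested edge margin",
         call. = FALSE)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n_sites)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::runif(1, lo[1], hi[1]); y <- stats::runif(1, lo[2], hi[2])
      if (length(xs) == 0 ||
          min((xs - x)^2 + (ys - y)^2) >= min_separation_nm^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %d sites with separation %g nm (placed %d)",
        n_sites, min_separation_nm, length(xs)), call. = FALSE)
  }
  mult <- rep(1L, n_sites)
  if (n_sites > 0 && cluster_probability > 0) {
    is_cl <- stats::runif(n_sites) < cluster_probability
    if (any(is_cl)) {
      if (max_multiplicity < 2L)
        stop("`max_multiplicity` must be >= 2 when clusters are possible",
             call. = FALSE)
      mults <- 2:max_multiplicity
      mult[is_cl] <- mults[sample.int(length(mults), sum(is_cl),
                                      replace = TRUE)]
    }
  }
  sites <- data.frame(x_nm = xs, y_nm = ys, multiplicity = mult)
  # expand to physical emitters with in-disk offsets for cluster members
  em_site <- rep(seq_len(n_sites), mult)
  n_em <- length(em_site)
  off_r <- cluster_radius_nm * sqrt(stats::runif(n_em))
  off_a <- stats::runif(n_em, 0, 2 * pi)
  single <- mult[em_site] == 1L
  off_r[single] <- 0
  emitters <- data.frame(
    site = em_site,
    x_nm = sites$x_nm[em_site] + off_r * cos(off_a),
    y_nm = sites$y_nm[em_site] + off_r * sin(off_a),
    photon_rate_per_us = rep(photon_rate_per_us, length.out = n_em))
  structure(list(sites = sites, emitters = emitters,
                 cluster_radius_nm = cluster_radius_nm, fov_nm = ext),
            class = "qd_field")
}

#' @export
print.qd_field <- function(x, ...) {
  cat(sprintf("QD field: %d sites (%d clusters), %d emitters, FOV %.1f x %.1f um\n",
              nrow(x$sites), sum(x$sites$multiplicity > 1L),
              nrow(x$emitters), x$fov_nm[1] / 1e3, x$fov_nm[2] / 1e3))
  invisible(x)
}
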