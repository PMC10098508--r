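#' Distance map to the nearest true pixel of a mask
#'
#' Euclidean distance from every pixel centre of the grid to the nearest
#' true pixel centre of `mask`, in nm (0 inside the mask). Exact brute-force
#' minimum, computed in row blocks to bound memory.
#'
#' @param mask Logical (or 0/1) matrix with at least one true pixel.
#' @param pixel_size_nm Pixel size in nm.
#' @return Numeric matrix of distances, same shape as `mask`.
#' @export
mask_distance_map <- function(mask, pixel_size_nm) {
  mask <- mask != 0
  if (!any(mask)) stop("mask has no true pixels", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  px <- which(mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  blk <- max(1L, floor(4e6 / nrow(px)))
  for (i0 in seq(1L, nr, by = blk)) {
    rows <- i0:min(nr, i0 + blk - 1L)
    dr2 <- outer(rows, px[, 1], function(a, b) (a - b)^2)  # |rows| x npx
    for (j in seq_len(nc)) {
      d2 <- dr2 + matrix((j - px[, 2])^2, nrow = length(rows),
                         ncol = nrow(px), byrow = TRUE)
      out[rows, j] <- sqrt(apply(d2, 1, min))
    }
  }
  out * pixel_size_nm
}

# binary dilation by a disk of radius r pixels
dilate_disk <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  r <- ceiling(r_px)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    if (di^2 + dj^2 > r_px^2) next
    si <- max(1, 1 + di):min(nr, nr + di)
    ti <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    tj <- max(1, 1 - dj):min(nc, nc - dj)
    out[ti, tj] <- out[ti, tj] | mask[si, sj]
  }
  out
}

# rasterize a straight segment (nm endpoints) at 1-pixel width
rasterize_segment <- function(mask, p0_nm, p1_nm, pixel_size_nm) {
  len <- sqrt(sum((p1_nm - p0_nm)^2))
  n <- max(2L, ceiling(len / (pixel_size_nm / 2)))
  t <- seq(0, 1, length.out = n)
  xs <- p0_nm[1] + t * (p1_nm[1] - p0_nm[1])
  ys <- p0_nm[2] + t * (p1_nm[2] - p0_nm[2])
  cols <- pmin(pmax(floor(xs / pixel_size_nm) + 1L, 1L), ncol(mask))
  rows <- pmin(pmax(floor(ys / pixel_size_nm) + 1L, 1L), nrow(mask))
  mask[cbind(rows, cols)] <- TRUE
  mask
}

#' Generate a synthetic cell scene with known colocalization truth
#'
#' Builds a phantom of the endocytosis experiment: disk-shaped endocytic
#' vesicle masks, microtubule strands (random straight lines rasterized at
#' one pixel width, then dilated to `tubulin_width_nm`), and quantum-dot
#' sites placed *constructively* so that the realized fraction inside
#' vesicles, fraction near tubulin (distance `< near_distance_nm`), and
#' cluster fractions inside/outside match the requested values exactly:
#' counts are rounded once and positions are drawn from the matching
#' inside/outside x near/far region pixels, with dots at pixel centres.
#' Ground-truth flags and distances are filled from the construction.
#'
#' @param n_qds Number of quantum-dot sites.
#' @param n_vesicles Number of vesicles.
#' @param vesicle_radius_nm Vesicle disk radius in nm.
#' @param fraction_inside Requested fraction of dots inside vesicles.
#' @param tubulin_density Number of microtubule strands across the FOV.
#' @param fraction_near_tubulin Requested fraction of dots with tubulin
#'   distance below `near_distance_nm`.
#' @param near_distance_nm "Near" threshold in nm (strict `<`).
#' @param config A [scan_config()] defining the grid.
#' @param cluster_fraction_inside,cluster_fraction_outside Fractions of
#'   sites that are clusters among inside/outside dots (rounded to counts).
#' @param max_multiplicity Cluster multiplicity drawn from
#'   `2:max_multiplicity`.
#' @param tubulin_width_nm Dilated strand width in nm.
#' @param min_separation_nm Minimum distance between QD sites, in nm
#'   (default 0: sites may share a vesicle at sub-resolution spacing).
#' @param seed Optional integer seed.
#' @param max_tries Whole-scene retry budget when a required region
#'   (e.g. inside-and-near) has too few pixels.
#' @return An object of class `scene_phantom`: `sites` (data.frame with
#'   `x_nm`, `y_nm`, `multiplicity`, `inside`, `near_tubulin`,
#'   `distance_nm`), `vesicle_mask`, `tubulin_mask`, `tubulin_distance_map`,
#'   `config`, and the generating parameters.
#' @export
generate_cell_scene <- function(n_qds, n_vesicles = 8L,
                                vesicle_radius_nm = 250,
                                fraction_inside = 0.5,
                                tubulin_density = 6L,
                                fraction_near_tubulin = 0.8,
                                near_distance_nm = 200,
                                config = scan_config(40, c(200, 200), 10),
                                cluster_fraction_inside = 0.3,
                                cluster_fraction_outside = 0.3,
                                max_multiplicity = 4L,
                                tubulin_width_nm = 100,
                                min_separation_nm = 0,
                                seed = NULL, max_tries = 20L) {
  stopifnot(inherits(config, "scan_config"))
  for (f in c(fraction_inside, fraction_near_tubulin,
              cluster_fraction_inside, cluster_fraction_outside))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  px <- config$pixel_size_nm
  nr <- config$image_shape_px[1]; nc <- config$image_shape_px[2]
  ext <- fov_nm(config)

  n_in <- round(fraction_inside * n_qds)
  n_near <- round(fraction_near_tubulin * n_qds)
  # joint allocation: distribute the near dots over inside/outside in
  # proportion, then fix up rounding
  n_in_near <- min(n_in, round(fraction_near_tubulin * n_in))
  n_out_near <- n_near - n_in_near
  if (n_out_near > n_qds - n_in) {
    n_in_near <- n_in_near + (n_out_near - (n_qds - n_in))
    n_out_near <- n_qds - n_in
  }
  if (n_in_near < 0 || n_in_near > n_in || n_out_near < 0)
    stop("requested fractions are jointly infeasible", call. = FALSE)
  need <- c(in_near = n_in_near, in_far = n_in - n_in_near,
            out_near = n_out_near,
            out_far = (n_qds - n_in) - n_out_near)

  for (attempt in seq_len(max_tries)) {
    # tubulin strands: random chords of the FOV
    tub <- matrix(FALSE, nr, nc)
    for (s in seq_len(tubulin_density)) {
      ang <- stats::runif(1, 0, pi)
      mid <- stats::runif(2, 0.1, 0.9) * ext
      dvec <- c(cos(ang), sin(ang)) * sum(ext)
      tub <- rasterize_segment(tub, mid - dvec, mid + dvec, px)
    }
    tub <- dilate_disk(tub, (tubulin_width_nm / 2) / px)
    dmap <- mask_distance_map(tub, px)

    # vesicles: disks kept inside the FOV, centres separated when possible
    ves <- matrix(FALSE, nr, nc)
    r_px_v <- vesicle_radius_nm / px
    cx <- cy <- numeric(0)
    for (v in seq_len(n_vesicles)) {
      for (k in seq_len(200L)) {
        x <- stats::runif(1, vesicle_radius_nm, ext[1] - vesicle_radius_nm)
        y <- stats::runif(1, vesicle_radius_nm, ext[2] - vesicle_radius_nm)
        if (!length(cx) || min((cx - x)^2 + (cy - y)^2) >=
            (2 * vesicle_radius_nm)^2 || k == 200L) {
          cx <- c(cx, x); cy <- c(cy, y); break
        }
      }
    }
    if (length(cx)) {
      ctr_x <- (seq_len(nc) - 0.5) * px
      ctr_y <- (seq_len(nr) - 0.5) * px
      for (v in seq_along(cx)) {
        d2 <- outer((ctr_y - cy[v])^2, (ctr_x - cx[v])^2, `+`)
        ves <- ves | (d2 <= vesicle_radius_nm^2)
      }
    }

    near <- dmap < near_distance_nm
    regions <- list(in_near = ves & near, in_far = ves & !near,
                    out_near = !ves & near, out_far = !ves & !near)
    if (all(vapply(regions, sum, 0L) >= need)) {
      # sequential rejection sampling keeps sites min_separation apart
      sx <- sy <- numeric(0)
      ok_scene <- TRUE
      picks <- lapply(names(need), function(nm) {
        idx <- which(regions[[nm]])
        chosen <- integer(0)
        for (q in seq_len(need[[nm]])) {
          placed <- FALSE
          for (t in seq_len(500L)) {
            cand <- idx[sample.int(length(idx), 1L)]
            ci <- (cand - 1L) %% nr + 1L; cj <- (cand - 1L) %/% nr + 1L
            cxn <- (cj - 0.5) * px; cyn <- (ci - 0.5) * px
            if (cand %in% chosen) next
            if (!length(sx) ||
                min((sx - cxn)^2 + (sy - cyn)^2) >= min_separation_nm^2) {
              chosen <- c(chosen, cand)
              sx <<- c(sx, cxn); sy <<- c(sy, cyn)
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok_scene <<- FALSE; break }
        }
        chosen
      })
      if (!ok_scene) next
      idx <- unlist(picks)
      rows <- (idx - 1L) %% nr + 1L
      cols <- (idx - 1L) %/% nr + 1L
      sites <- data.frame(
        x_nm = (cols - 0.5) * px, y_nm = (rows - 0.5) * px,
        inside = rep(c(TRUE, TRUE, FALSE, FALSE), need),
        near_tubulin = rep(c(TRUE, FALSE, TRUE, FALSE), need),
        distance_nm = dmap[cbind(rows, cols)])
      # constructive cluster assignment inside and outside
      sites$multiplicity <- 1L
      for (grp in c(TRUE, FALSE)) {
        sel <- which(sites$inside == grp)
        frac <- if (grp) cluster_fraction_inside else cluster_fraction_outside
        n_cl <- round(frac * length(sel))
        if (n_cl > 0) {
          cl <- sel[sample.int(length(sel), n_cl)]
          mults <- 2:max_multiplicity
          sites$multiplicity[cl] <- mults[sample.int(length(mults), n_cl,
                                                     replace = TRUE)]
        }
      }
      return(structure(
        list(sites = sites, vesicle_mask = ves, tubulin_mask = tub,
             tubulin_distance_map = dmap, config = config,
             params = list(n_qds = n_qds, n_vesicles = n_vesicles,
                           vesicle_radius_nm = vesicle_radius_nm,
                           fraction_inside = fraction_inside,
                           fraction_near_tubulin = fraction_near_tubulin,
                           near_distance_nm = near_distance_nm,
                           tubulin_width_nm = tubulin_width_nm,
                           seed = seed)),
        class = "scene_phantom"))
    }
  }
  stop("infeasible geometry: could not realize the requested fractions in ",
       max_tries, " attempts", call. = FALSE)
}

#' @export
print.scene_phantom <- function(x, ...) {
  cat(sprintf(
    "Cell-scene phantom: %d QD sites (%d clusters), %d%% inside vesicles, %d%% near tubulin\n",
    nrow(x$sites), sum(x$sites$multiplicity > 1L),
    round(100 * mean(x$sites$inside)),
    round(100 * mean(x$sites$near_tubulin))))
  invisible(x)
}
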