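#' Spectral bleed-through matrix from single-label acquisitions
#'
#' Quantifies channel crosstalk in multicolour imaging: each fluorophore is
#' imaged alone in every detection channel, and the bleed-through ratio into
#' a non-target channel is the background-subtracted mean signal over the
#' fluorophore's own structure mask in that channel, divided by the same
#' quantity in its own channel. The diagonal is 1 by definition. Background
#' per channel is the median outside the mask.
#'
#' @param single_label_images Named list (fluorophore) of named lists
#'   (channel) of 2D matrices: the images of each fluorophore acquired alone
#'   in every channel.
#' @param detection_masks Named list (fluorophore) of logical masks marking
#'   the labelled structure.
#' @param own_channel Named character vector mapping each fluorophore to its
#'   own detection channel; defaults to the channel with the fluorophore's
#'   name.
#' @return Matrix of ratios with fluorophores as rows and channels as
#'   columns.
#' @export
bleedthrough_matrix <- function(single_label_images, detection_masks,
                                own_channel = NULL) {
  fls <- names(single_label_images)
  if (is.null(fls) || !length(fls))
    stop("`single_label_images` must be a named list per fluorophore",
         call. = FALSE)
  channels <- names(single_label_images[[1]])
  if (is.null(own_channel)) {
    if (!all(fls %in% channels))
      stop("cannot infer own channels: fluorophore names must match ",
           "channel names or `own_channel` must be given", call. = FALSE)
    own_channel <- stats::setNames(fls, fls)
  }
  out <- matrix(NA_real_, length(fls), length(channels),
                dimnames = list(fluorophore = fls, channel = channels))
  for (f in fls) {
    mask <- detection_masks[[f]] != 0
    if (is.null(mask) || !any(mask))
      stop("empty or missing detection mask for ", f, call. = FALSE)
    own_sig <- masked_signal(single_label_images[[f]][[own_channel[[f]]]],
                             mask)
    if (own_sig <= 0)
      stop("degenerate input: zero own-channel signal for ", f,
           call. = FALSE)
    for (ch in channels) {
      out[f, ch] <- if (ch == own_channel[[f]]) 1
      else max(masked_signal(single_label_images[[f]][[ch]], mask), 0) /
        own_sig
    }
  }
  out
}

# background-subtracted mean signal over a structure mask
masked_signal <- function(image, mask) {
  stopifnot(is.matrix(image), identical(dim(image), dim(mask)))
  bg <- stats::median(image[!mask])
  if (!is.finite(bg)) bg <- 0
  mean(image[mask]) - bg
}
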