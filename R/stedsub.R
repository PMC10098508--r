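#' Multi-channel image stack
#'
#' Container for a registered multi-channel acquisition: a named list of
#' equally shaped 2D count matrices (roles such as `confocal`, `STED`,
#' `STEDonly`, `STEDsub`, or dye channels), an optional per-channel
#' line-repeat stack (`repeat x row x col` arrays), the [scan_config()] and
#' free-form acquisition metadata (powers, wavelengths, detection band).
#'
#' @param channels Named list of 2D matrices sharing one shape.
#' @param config Optional [scan_config()].
#' @param line_repeat_stack Optional named list of 3D arrays
#'   (`repeat x row x col`).
#' @param expected Optional named list of noise-free mean images (filled by
#'   [simulate_acquisition()]).
#' @param metadata Optional list of acquisition metadata.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, config = NULL, line_repeat_stack = NULL,
                        expected = NULL, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a named list of matrices", call. = FALSE)
  shapes <- lapply(channels, dim)
  if (length(unique(lapply(shapes, as.integer))) > 1L) {
    s <- vapply(shapes, paste, "", collapse = "x")
    stop("channel shapes differ: ",
         paste(sprintf("%s=%s", names(s), s), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config)) stopifnot(inherits(config, "scan_config"))
  structure(list(channels = channels, line_repeat_stack = line_repeat_stack,
                 expected = expected, config = config, metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Image stack: %d channel(s) [%s], %d x %d px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2]))
  if (!is.null(x$line_repeat_stack))
    cat(sprintf("  line-repeat stacks kept for: %s\n",
                paste(names(x$line_repeat_stack), collapse = ", ")))
  invisible(x)
}

#' Sum a repeated-line stack into a single image
#'
#' Imaging of blinking quantum dots is performed by adding up repeatedly
#' scanned lines; this collapses a `repeat x row x col` count stack by
#' summing over the repeat axis.
#'
#' @param line_repeat_stack A 3D array (`repeat x row x col`) of counts.
#' @return An integer matrix (`row x col`).
#' @export
accumulate_line_repeats <- function(line_repeat_stack) {
  if (!is.array(line_repeat_stack) || length(dim(line_repeat_stack)) != 3L ||
      any(dim(line_repeat_stack) == 0L))
    stop("`line_repeat_stack` must be a non-empty repeat x row x col array",
         call. = FALSE)
  out <- apply(line_repeat_stack, c(2, 3), sum)
  storage.mode(out) <- "integer"
  out
}

#' STED minus STED-only background subtraction
#'
#' Removes the donut-shaped halo caused by direct excitation from the
#' depletion beam: `STEDsub = STED - scale * STEDonly`. With equal
#' acquisition settings for the two images the scale is 1; it is exposed for
#' unequal dwell or power. Shot noise makes negative differences inevitable;
#' by default they are preserved (fits and statistics should run on the
#' signed image to avoid bias), with `clip_negative = TRUE` available for
#' display and detection.
#'
#' @param sted 2D count matrix (STED channel).
#' @param stedonly 2D count matrix (STED-only channel), same shape.
#' @param scale Subtraction scale applied to `stedonly`. Default 1.
#' @param clip_negative If `TRUE`, set negative differences to 0.
#' @return A matrix of the same shape; signed if unclipped.
#' @examples
#' compute_stedsub(matrix(5, 2, 2), matrix(2, 2, 2))
#' @export
compute_stedsub <- function(sted, stedonly, scale = 1, clip_negative = FALSE) {
  if (!is.matrix(sted) || !is.matrix(stedonly))
    stop("`sted` and `stedonly` must be matrices", call. = FALSE)
  if (!identical(dim(sted), dim(stedonly)))
    stop(sprintf("shape mismatch: sted is %s, stedonly is %s",
                 paste(dim(sted), collapse = "x"),
                 paste(dim(stedonly), collapse = "x")), call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L)
    stop("`scale` must be a single number", call. = FALSE)
  out <- sted - scale * stedonly
  if (clip_negative) out[out < 0] <- 0
  out
}

#' Add a STEDsub channel to an image stack
#'
#' Convenience wrapper applying [compute_stedsub()] to the `STED` and
#' `STEDonly` channels of a stack.
#'
#' @param stack An [image_stack()] with `STED` and `STEDonly` channels.
#' @inheritParams compute_stedsub
#' @return The stack with a `STEDsub` channel added.
#' @export
add_stedsub <- function(stack, scale = 1, clip_negative = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (!all(c("STED", "STEDonly") %in% names(stack$channels)))
    stop("stack must contain `STED` and `STEDonly` channels", call. = FALSE)
  stack$channels$STEDsub <- compute_stedsub(stack$channels$STED,
                                            stack$channels$STEDonly,
                                            scale, clip_negative)
  stack
}
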