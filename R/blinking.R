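#' Two-state quantum-dot blinking model
#'
#' Blinking is modelled as a stationary alternating (telegraph) renewal
#' process: the emitter switches between an emissive ON state and a dark OFF
#' state, with independent exponentially distributed dwell times in each
#' state. Dark-state lifetimes of CdTe quantum dots under these imaging
#' conditions are on the order of 0.1-1 ms, which sets the defaults.
#' Depletion illumination suppresses blinking; this is modelled as a
#' multiplicative extension of the mean ON dwell (`suppression_factor`)
#' applied in the STED and STED-only channels.
#'
#' @param tau_on_ms Mean ON dwell time in ms (> 0).
#' @param tau_off_ms Mean OFF (dark-state) dwell time in ms (> 0).
#' @param p_on_initial Probability that a trace starts ON. `NULL` (default)
#'   uses the stationary occupancy `tau_on / (tau_on + tau_off)`.
#' @param suppression_factor Factor (>= 1) multiplying `tau_on` under
#'   depletion illumination.
#' @return An object of class `blinking_model`.
#' @examples
#' bm <- blinking_model(0.45, 0.45, suppression_factor = 1.5)
#' on_occupancy(bm)
#' @export
blinking_model <- function(tau_on_ms = 0.45, tau_off_ms = 0.45,
                           p_on_initial = NULL, suppression_factor = 1.5) {
  if (!is.numeric(tau_on_ms) || tau_on_ms <= 0)
    stop("`tau_on_ms` must be > 0", call. = FALSE)
  if (!is.numeric(tau_off_ms) || tau_off_ms <= 0)
    stop("`tau_off_ms` must be > 0", call. = FALSE)
  if (is.null(p_on_initial))
    p_on_initial <- tau_on_ms / (tau_on_ms + tau_off_ms)
  if (!is.numeric(p_on_initial) || p_on_initial < 0 || p_on_initial > 1)
    stop("`p_on_initial` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(suppression_factor) || suppression_factor < 1)
    stop("`suppression_factor` must be >= 1", call. = FALSE)
  structure(list(tau_on_ms = as.numeric(tau_on_ms),
                 tau_off_ms = as.numeric(tau_off_ms),
                 p_on_initial = as.numeric(p_on_initial),
                 suppression_factor = as.numeric(suppression_factor)),
            class = "blinking_model")
}

#' @export
print.blinking_model <- function(x, ...) {
  cat(sprintf(
    "Telegraph blinking model: tau_on %g ms, tau_off %g ms (ON occupancy %.2f)\n",
    x$tau_on_ms, x$tau_off_ms, on_occupancy(x)))
  if (x$suppression_factor != 1)
    cat(sprintf("  depletion suppression: tau_on x %g in STED channels\n",
                x$suppression_factor))
  invisible(x)
}

#' Stationary ON occupancy of a blinking model
#'
#' `tau_on / (tau_on + tau_off)`: the long-run fraction of time spent ON.
#'
#' @param model A [blinking_model()].
#' @param suppressed If `TRUE`, apply the depletion suppression factor to
#'   `tau_on` first.
#' @return ON occupancy in \[0, 1\].
#' @export
on_occupancy <- function(model, suppressed = FALSE) {
  stopifnot(inherits(model, "blinking_model"))
  ton <- model$tau_on_ms * if (suppressed) model$suppression_factor else 1
  ton / (ton + model$tau_off_ms)
}

# Internal: blinking model with suppression folded into tau_on
suppressed_model <- function(model) {
  blinking_model(model$tau_on_ms * model$suppression_factor,
                 model$tau_off_ms, model$p_on_initial, 1)
}

#' Simulate a telegraph ON/OFF blinking trace
#'
#' Draws alternating exponentially distributed ON and OFF dwell segments
#' until the requested duration is tiled exactly; the final segment is
#' truncated at `duration_ms`.
#'
#' @param model A [blinking_model()].
#' @param duration_ms Trace duration in ms (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame of class `blink_trace` with columns `state`
#'   (`"on"`/`"off"`), `start_ms`, `end_ms`; contiguous, non-overlapping,
#'   alternating segments covering `[0, duration_ms]`.
#' @examples
#' tr <- simulate_blink_trace(blinking_model(0.5, 0.5), 10, seed = 1)
#' sum((tr$end_ms - tr$start_ms)[tr$state == "on"]) / 10  # ON fraction
#' @export
simulate_blink_trace <- function(model, duration_ms, seed = NULL) {
  stopifnot(inherits(model, "blinking_model"))
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("`duration_ms` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  state_on <- stats::runif(1) < model$p_on_initial
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  t <- 0
  # draw dwells in blocks to limit R-level looping
  while (t < duration_ms) {
    n_blk <- max(16L, ceiling(2 * (duration_ms - t) /
                                (model$tau_on_ms + model$tau_off_ms)))
    first_on <- state_on
    odd <- seq_len(n_blk) %% 2L == 1L
    # states alternate starting from `first_on`
    seg_on <- if (first_on) odd else !odd
    dw <- stats::rexp(n_blk, rate = 1 /
                        ifelse(seg_on, model$tau_on_ms, model$tau_off_ms))
    seg_start <- t + c(0, cumsum(dw[-n_blk]))
    seg_end <- t + cumsum(dw)
    keep <- seg_start < duration_ms
    starts <- c(starts, seg_start[keep])
    ends <- c(ends, pmin(seg_end[keep], duration_ms))
    states <- c(states, ifelse(seg_on[keep], "on", "off"))
    t <- seg_end[n_blk]
    state_on <- !seg_on[n_blk]
  }
  out <- data.frame(state = states, start_ms = starts, end_ms = ends,
                    stringsAsFactors = FALSE)
  class(out) <- c("blink_trace", "data.frame")
  out
}

#' ON-time fraction of a blink trace within time windows
#'
#' For each window `[t_start, t_start + width]` returns the fraction of the
#' window during which the trace is ON. Computed exactly from the segment
#' boundaries through the cumulative ON-time function.
#'
#' @param trace A [simulate_blink_trace()] result.
#' @param t_start_us Window start times in microseconds.
#' @param width_us Window width in microseconds (scalar).
#' @return Numeric vector of ON fractions in \[0, 1\].
#' @export
trace_on_fraction <- function(trace, t_start_us, width_us) {
  stopifnot(inherits(trace, "blink_trace"), width_us > 0)
  # cumulative ON time C(t) (in ms) at segment boundaries; piecewise linear
  br <- c(trace$start_ms[1], trace$end_ms)
  on_len <- (trace$end_ms - trace$start_ms) * (trace$state == "on")
  cum <- c(0, cumsum(on_len))
  t0 <- t_start_us / 1e3
  t1 <- (t_start_us + width_us) / 1e3
  tmax <- trace$end_ms[nrow(trace)]
  c0 <- stats::approx(br, cum, xout = pmin(pmax(t0, br[1]), tmax),
                      rule = 2)$y
  c1 <- stats::approx(br, cum, xout = pmin(pmax(t1, br[1]), tmax),
                      rule = 2)$y
  (c1 - c0) / (width_us / 1e3)
}

#' Mean ON fraction of a whole trace
#' @param trace A [simulate_blink_trace()] result.
#' @return ON-time fraction over the full trace duration.
#' @export
trace_on_time_fraction <- function(trace) {
  stopifnot(inherits(trace, "blink_trace"))
  dur <- trace$end_ms[nrow(trace)] - trace$start_ms[1]
  sum((trace$end_ms - trace$start_ms)[trace$state == "on"]) / dur
}

#' Standard error of the time-averaged occupancy of a telegraph process
#'
#' Asymptotic standard error of the ON-time fraction measured over a window
#' of length `duration_ms`, from the exponential autocovariance of the
#' two-state Markov process:
#' `Var = 2 tau_on^2 tau_off^2 / ((tau_on + tau_off)^3 * T)`.
#'
#' @param model A [blinking_model()].
#' @param duration_ms Averaging duration in ms.
#' @return Standard error of the occupancy estimate.
#' @export
occupancy_se <- function(model, duration_ms) {
  stopifnot(inherits(model, "blinking_model"))
  ton <- model$tau_on_ms; toff <- model$tau_off_ms
  sqrt(2 * ton^2 * toff^2 / ((ton + toff)^3 * duration_ms))
}
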