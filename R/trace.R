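#' Construct a respiratory trace
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param amplitude Respiratory amplitude, arbitrary units; larger values mean
#'   more inhaled.
#' @return A tibble of class `breathing_trace` with columns `time_s`,
#'   `amplitude`.
#' @examples
#' t <- seq(0, 30, by = 0.04)
#' breathing_trace(t, sin(2 * pi * t / 5))
#' @export
breathing_trace <- function(time_s, amplitude) {
  if (is.data.frame(time_s)) {
    df <- time_s
    stopifnot(all(c("time_s", "amplitude") %in% names(df)))
    time_s <- df$time_s; amplitude <- df$amplitude
  }
  stopifnot(length(time_s) == length(amplitude), length(time_s) >= 2L,
            all(is.finite(time_s)), all(is.finite(amplitude)))
  if (any(diff(time_s) <= 0))
    stop("trace times must be strictly increasing (no duplicate timestamps)",
         call. = FALSE)
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        amplitude = as.numeric(amplitude))
  class(out) <- c("breathing_trace", class(out))
  out
}

# local maxima indices with topographic prominence >= min_prominence and
# spacing >= min_period. Prominence of a peak: height above the higher of the
# two minima separating it from the nearest higher terrain on either side.
find_inhale_peaks <- function(time_s, amplitude, min_prominence, min_period) {
  n <- length(amplitude)
  d <- diff(amplitude)
  # strict rise then fall; plateaus resolved to their first sample
  cand <- which(d[-1] <= 0 & d[-(n - 1)] > 0) + 1L
  cand <- cand[amplitude[cand] > amplitude[pmax(cand - 1L, 1L)]]
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- amplitude[i]
    left <- amplitude[seq_len(i - 1L)]
    right <- amplitude[seq(i + 1L, n)]
    lhigher <- which(left > h)
    rhigher <- which(right > h)
    lmin <- if (length(lhigher) == 0L) min(left) else
      min(left[seq(max(lhigher), length(left))])
    rmin <- if (length(rhigher) == 0L) min(right) else
      min(right[seq_len(min(rhigher))])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  # enforce minimum spacing, keeping the more prominent peak
  ord <- order(-promk)
  sel <- logical(length(keep))
  for (j in ord) {
    tj <- time_s[keep[j]]
    if (!any(sel & abs(time_s[keep] - tj) < min_period)) sel[j] <- TRUE
  }
  sort(keep[sel])
}

#' Segment a respiratory trace into breathing cycles
#'
#' Cycles run between successive points of maximum inhalation; partial cycles
#' at either end of the trace are discarded so only complete cycles remain.
#' For each cycle the halfway amplitude `(max + min) / 2` splits the cycle
#' into inhale time (`t_in`, amplitude above halfway) and exhale time
#' (`t_ex`, at or below halfway), with threshold crossings located by linear
#' interpolation between samples.
#'
#' @param trace A [breathing_trace()] (or data frame with `time_s`,
#'   `amplitude`).
#' @param min_prominence Minimum peak prominence, amplitude units; default
#'   20% of the interquartile range of the amplitudes.
#' @param min_period Minimum spacing between inhalation maxima, seconds.
#' @return A tibble with one row per complete cycle: `cycle`, `start_time`,
#'   `end_time`, `max_amp`, `min_amp`, `halfway_amp`, `t_in`, `t_ex`,
#'   `f_in` (= `t_in / (t_in + t_ex)`).
#' @examples
#' t <- seq(0, 30, by = 0.04)
#' detect_cycles(breathing_trace(t, sin(2 * pi * t / 5)))
#' @export
detect_cycles <- function(trace, min_prominence = NULL, min_period = 1.5) {
  trace <- breathing_trace(trace$time_s, trace$amplitude)
  if (is.null(min_prominence))
    min_prominence <- 0.2 * stats::IQR(trace$amplitude)
  peaks <- find_inhale_peaks(trace$time_s, trace$amplitude,
                             min_prominence, min_period)
  if (length(peaks) < 2L)
    stop(sprintf(
      "no complete breathing cycle found (min_prominence = %.4g, min_period = %.4g s)",
      min_prominence, min_period), call. = FALSE)
  purrr::map_dfr(seq_len(length(peaks) - 1L), function(k) {
    i0 <- peaks[k]; i1 <- peaks[k + 1L]
    seg_t <- trace$time_s[i0:i1]
    seg_a <- trace$amplitude[i0:i1]
    h <- (max(seg_a) + min(seg_a)) / 2
    tin <- time_above_threshold(seg_t, seg_a, h)
    total <- seg_t[length(seg_t)] - seg_t[1]
    tibble::tibble(cycle = k, start_time = seg_t[1],
                   end_time = seg_t[length(seg_t)],
                   max_amp = max(seg_a), min_amp = min(seg_a),
                   halfway_amp = h, t_in = tin, t_ex = total - tin,
                   f_in = tin / total)
  })
}

# time with amplitude strictly above h over a piecewise-linear signal;
# samples exactly at h count as exhale (deterministic tie rule)
time_above_threshold <- function(t, a, h) {
  x <- a - h
  tin <- 0
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    x0 <- x[i]; x1 <- x[i + 1L]
    if (x0 > 0 && x1 > 0) tin <- tin + dt
    else if (x0 > 0 && x1 <= 0) tin <- tin + dt * x0 / (x0 - x1)
    else if (x0 <= 0 && x1 > 0) tin <- tin + dt * x1 / (x1 - x0)
  }
  tin
}

#' Inhale/exhale split of one breathing cycle
#'
#' @param cycle One row of the tibble from [detect_cycles()].
#' @param trace The trace the cycle was detected in.
#' @return Named numeric `c(t_in, t_ex)` in seconds.
#' @export
cycle_fractions <- function(cycle, trace) {
  trace <- breathing_trace(trace$time_s, trace$amplitude)
  sel <- trace$time_s >= cycle$start_time & trace$time_s <= cycle$end_time
  if (!any(sel)) stop("cycle lies outside the trace extent", call. = FALSE)
  seg_t <- trace$time_s[sel]; seg_a <- trace$amplitude[sel]
  tin <- time_above_threshold(seg_t, seg_a, cycle$halfway_amp)
  c(t_in = tin, t_ex = (seg_t[length(seg_t)] - seg_t[1]) - tin)
}

#' Exhale/inhale phase weights from a respiratory trace
#'
#' The fraction of breathing time spent in the exhale (below halfway
#' amplitude) and inhale (above halfway) halves of the cycle, used to weight
#' two-phase dose accumulation. The default averages the per-cycle inhale
#' fractions over all complete cycles; `method = "pooled"` instead pools the
#' times, `sum(t_in) / sum(t_in + t_ex)`.
#'
#' @inheritParams detect_cycles
#' @param method `"per_cycle"` (unweighted mean of per-cycle fractions,
#'   default) or `"pooled"` (ratio of pooled times).
#' @return An object of class `phase_weights` with fields `w_ex`, `w_in`,
#'   `n_cycles`, `method` and the per-cycle table `cycles`. Supports
#'   [generics::tidy()] (per-cycle rows) and [generics::glance()] (one-row
#'   summary).
#' @examples
#' t <- seq(0, 30, by = 0.04)
#' phase_weights(breathing_trace(t, sin(2 * pi * t / 5)))
#' @export
phase_weights <- function(trace, min_prominence = NULL, min_period = 1.5,
                          method = c("per_cycle", "pooled")) {
  method <- match.arg(method)
  cycles <- detect_cycles(trace, min_prominence, min_period)
  w_in <- if (method == "per_cycle") mean(cycles$f_in) else
    sum(cycles$t_in) / sum(cycles$t_in + cycles$t_ex)
  structure(
    list(w_ex = 1 - w_in, w_in = w_in, n_cycles = nrow(cycles),
         method = method, cycles = cycles,
         trace = breathing_trace(trace$time_s, trace$amplitude)),
    class = "phase_weights")
}

#' @export
print.phase_weights <- function(x, ...) {
  cat("<phase_weights>\n")
  cat(sprintf("  w_ex = %.3f, w_in = %.3f  (%d complete cycles, %s)\n",
              x$w_ex, x$w_in, x$n_cycles, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname phase_weights
#' @param x A `phase_weights` object.
#' @param ... Unused.
#' @export
tidy.phase_weights <- function(x, ...) x$cycles

#' @rdname phase_weights
#' @method glance phase_weights
#' @export
glance.phase_weights <- function(x, ...) {
  tibble::tibble(w_ex = x$w_ex, w_in = x$w_in, n_cycles = x$n_cycles,
                 method = x$method)
}

#' @rdname phase_weights
#' @param object A `phase_weights` object.
#' @method autoplot phase_weights
#' @export
autoplot.phase_weights <- function(object, ...) {
  tr <- object$trace
  cyc <- object$cycles
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(cyc$start_time,
                                       cyc$end_time[nrow(cyc)]),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_segment(
      data = cyc,
      ggplot2::aes(x = .data$start_time, xend = .data$end_time,
                   y = .data$halfway_amp, yend = .data$halfway_amp),
      colour = "firebrick", inherit.aes = FALSE) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (a.u.)",
      title = sprintf("breathing trace: w_ex = %.2f, w_in = %.2f (%d cycles)",
                      object$w_ex, object$w_in, object$n_cycles)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
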