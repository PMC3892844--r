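#' Detection configuration
#'
#' Tuning parameters of the inertial-sensor step analysis.
#'
#' The flight threshold is the heel-strike offset beyond which a step is
#' classified as having lost ground contact. Its default of 0.03 s is the
#' empirically calibrated ground-contact force transmission offset between
#' the vertical-acceleration minimum and the heel-strike transient; it is a
#' configurable parameter, not a constant, so that it can be re-calibrated
#' from an agreement analysis against a reference system.
#'
#' @param cutoff_hz Low-pass filter cutoff, Hz. Must be below the Nyquist
#'   frequency of the trace it is applied to.
#' @param flight_threshold Offset threshold in seconds; a step is illegal
#'   iff its offset exceeds this strictly.
#' @param min_peak_separation Minimum time between successive detected
#'   events of the same kind, seconds. Should be somewhat less than the
#'   step period.
#' @param peak_prominence Minimum height of an anteroposterior peak to be
#'   accepted as a heel strike, in g.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(cutoff_hz = 20,
                             flight_threshold = 0.03,
                             min_peak_separation = 0.2,
                             peak_prominence = 0.5) {
  stopifnot(cutoff_hz > 0, min_peak_separation > 0, peak_prominence >= 0)
  if (flight_threshold < 0) stop("`flight_threshold` must be >= 0")
  structure(list(cutoff_hz = cutoff_hz,
                 flight_threshold = flight_threshold,
                 min_peak_separation = min_peak_separation,
                 peak_prominence = peak_prominence),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(
    "<detection_config> cutoff %g Hz, flight threshold %g s,\n  min separation %g s, prominence %g g\n",
    x$cutoff_hz, x$flight_threshold, x$min_peak_separation,
    x$peak_prominence))
  invisible(x)
}

#' Zero-phase low-pass filter an acceleration trace
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase) to all three channels, so event timing is not shifted by
#' filtering. Passband gain is within 1% of unity below half the cutoff
#' and attenuation is monotone above the cutoff.
#'
#' @param trace An [accel_trace()].
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `sample_rate / 2`.
#' @return The filtered [accel_trace()].
#' @export
lowpass_filter <- function(trace, cutoff = 20) {
  stopifnot(inherits(trace, "accel_trace"))
  nyq <- trace$sample_rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, nyq))
  if (length(trace) == 0L) return(trace)
  bw <- signal::butter(4, cutoff / nyq, type = "low")
  f <- function(x) {
    if (stats::sd(x) == 0) return(x)  # constant channel: DC gain is 1
    as.numeric(signal::filtfilt(bw, x))
  }
  accel_trace(f(trace$ap), f(trace$vert), f(trace$ml),
              trace$sample_rate, trace$start_time)
}

#' Detect vertical-acceleration step-cycle minima
#'
#' Locates the bottom-most point of each step cycle in the vertical
#' channel: local minima lying below the channel mean, separated by at
#' least `min_peak_separation`. These are the step-cycle landmarks of the
#' vertical acceleration step cycle (VASC) method.
#'
#' @param trace A filtered [accel_trace()].
#' @param config A [detection_config()].
#' @return Strictly increasing numeric vector of minimum times, one per
#'   detected step cycle, in seconds.
#' @export
detect_vertical_minima <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "accel_trace"),
            inherits(config, "detection_config"))
  x <- trace$vert
  if (length(x) == 0L || stats::sd(x) < 1e-12)
    stop("no step cycles: vertical channel is empty or constant")
  d <- max(1L, as.integer(round(config$min_peak_separation *
                                  trace$sample_rate)))
  pk <- pracma::findpeaks(-x, minpeakheight = mean(-x),
                          minpeakdistance = d)
  if (is.null(pk))
    stop("no step cycles: no vertical minima below the channel mean")
  idx <- sort(pk[, 2])
  trace$start_time + (idx - 1) / trace$sample_rate
}

#' Detect heel strikes in the anteroposterior channel
#'
#' Finds the dominant positive anteroposterior peaks: local maxima
#' exceeding `peak_prominence`, separated by at least
#' `min_peak_separation`. Steps whose impact transient never rises above
#' the prominence floor yield no event (a gap), never a fabricated time.
#'
#' @inheritParams detect_vertical_minima
#' @return Strictly increasing numeric vector of heel-strike times in
#'   seconds; empty (with a warning) if no peak clears the prominence
#'   floor.
#' @export
detect_heel_strikes <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "accel_trace"),
            inherits(config, "detection_config"))
  x <- trace$ap
  # height is measured from the channel median so a DC offset on the
  # accelerometer cannot change which peaks clear the prominence floor
  if (length(x) > 0L) x <- x - stats::median(x)
  if (length(x) == 0L || max(x) < config$peak_prominence) {
    warning("no heel strikes: no anteroposterior peak above ",
            config$peak_prominence, " g")
    return(numeric(0))
  }
  d <- max(1L, as.integer(round(config$min_peak_separation *
                                  trace$sample_rate)))
  pk <- pracma::findpeaks(x, minpeakheight = config$peak_prominence,
                          minpeakdistance = d)
  if (is.null(pk)) {
    warning("no heel strikes: no anteroposterior peak above ",
            config$peak_prominence, " g")
    return(numeric(0))
  }
  idx <- sort(pk[, 2])
  trace$start_time + (idx - 1) / trace$sample_rate
}

#' Assess step legality from paired events
#'
#' Pairs each vertical-cycle minimum with the nearest heel strike at or
#' just after it (within half the median inter-minimum interval, with a
#' small pre-window for detection jitter), computes the per-step offset
#' `heel_strike_time - vert_min_time`, and classifies the step: flight is
#' deemed to have occurred when the heel strike falls after the flight
#' threshold, i.e. `offset > flight_threshold` strictly. A heel strike
#' coincident with the minimum, or one at exactly the threshold, is legal.
#'
#' Minima with no pairable heel strike are excluded from the result and
#' counted in the `n_unpaired_minima` attribute; unused heel strikes are
#' reported in the `orphan_heel_strikes` attribute. If both inputs are
#' non-empty but nothing can be paired, a structured error names the
#' orphan events.
#'
#' @param vert_min_times Times of vertical-cycle minima, seconds.
#' @param heel_strike_times Times of detected heel strikes, seconds.
#' @param config A [detection_config()].
#' @return A data frame of class `step_assessment` with columns
#'   `step_index`, `vert_min_time`, `heel_strike_time`, `offset` and
#'   `verdict` (`"legal"`/`"illegal"`), plus attributes
#'   `n_unpaired_minima`, `orphan_heel_strikes` and `flight_threshold`.
#' @export
assess_steps <- function(vert_min_times, heel_strike_times,
                         config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  vm <- sort(as.numeric(vert_min_times))
  hs <- sort(as.numeric(heel_strike_times))
  tol <- if (length(vm) >= 2) 0.5 * stats::median(diff(vm))
         else 2 * config$min_peak_separation
  pre <- 0.2 * tol  # small allowance for hs detected a sample early
  used <- logical(length(hs))
  m_vm <- numeric(0); m_hs <- numeric(0); m_idx <- integer(0)
  unpaired <- 0L
  for (i in seq_along(vm)) {
    dtime <- hs - vm[i]
    cand <- which(!used & dtime >= -pre & dtime <= tol)
    if (length(cand) == 0L) { unpaired <- unpaired + 1L; next }
    # prefer the earliest heel strike at or after the minimum
    after <- cand[dtime[cand] >= 0]
    j <- if (length(after)) after[which.min(dtime[after])]
         else cand[which.max(dtime[cand])]
    used[j] <- TRUE
    m_idx <- c(m_idx, i); m_vm <- c(m_vm, vm[i]); m_hs <- c(m_hs, hs[j])
  }
  orphans <- hs[!used]
  if (length(m_vm) == 0L && length(vm) > 0L && length(hs) > 0L)
    stop("unpairable event sequences: ", length(vm),
         " vertical minima and ", length(hs),
         " heel strikes share no pairs; orphan heel strikes at ",
         paste(sprintf("%.3f", utils::head(orphans, 5)), collapse = ", "),
         " s")
  offset <- m_hs - m_vm
  out <- data.frame(step_index = seq_along(m_vm),
                    vert_min_time = m_vm,
                    heel_strike_time = m_hs,
                    offset = offset,
                    verdict = ifelse(offset > config$flight_threshold,
                                     "illegal", "legal"))
  attr(out, "n_unpaired_minima") <- unpaired
  attr(out, "orphan_heel_strikes") <- orphans
  attr(out, "flight_threshold") <- config$flight_threshold
  class(out) <- c("step_assessment", "data.frame")
  out
}

#' Run the full sensor analysis on a raw trace
#'
#' Convenience wrapper: low-pass filters the trace, detects vertical
#' step-cycle minima and anteroposterior heel strikes, and assesses each
#' step against the flight threshold.
#'
#' @param trace A raw [accel_trace()].
#' @param config A [detection_config()].
#' @return A `step_assessment` data frame (see [assess_steps()]).
#' @export
detect_steps <- function(trace, config = detection_config()) {
  filt <- lowpass_filter(trace, config$cutoff_hz)
  vm <- detect_vertical_minima(filt, config)
  hs <- detect_heel_strikes(filt, config)
  assess_steps(vm, hs, config)
}
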