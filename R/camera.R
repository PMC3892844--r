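#' Convert a camera frame count to time
#'
#' The camera measurement converts a count of capture frames between two
#' gait events to seconds as `t = n / Hz`, where `Hz` is the capture rate.
#' One frame at 125 Hz is 0.008 s, the smallest non-zero flight time the
#' camera can resolve.
#'
#' @param frame_count Number of frames between the events (>= 0).
#' @param camera_rate Capture rate in Hz (> 0).
#' @return Time in seconds.
#' @export
#' @examples
#' camera_flight_time(1, 125)  # 0.008 s
camera_flight_time <- function(frame_count, camera_rate) {
  if (!is.numeric(camera_rate) || length(camera_rate) != 1L ||
      camera_rate <= 0)
    stop("`camera_rate` must be a single positive number")
  if (any(frame_count < 0)) stop("`frame_count` must be non-negative")
  frame_count / camera_rate
}

#' Signed ground-contact overlap from camera frames
#'
#' Computes `(toe_off_frame - heel_strike_frame) / camera_rate`: the signed
#' time between the contralateral heel strike and toe-off. Positive values
#' indicate double support (toe-off after the contralateral heel strike),
#' negative values indicate flight (loss of ground contact), and zero
#' means both events fell in the same capture frame — the threshold case.
#'
#' @param toe_off_frame,heel_strike_frame Frame indices of toe-off of one
#'   foot and heel strike of the contralateral foot.
#' @param camera_rate Capture rate in Hz (> 0).
#' @return Signed overlap in seconds, vectorised.
#' @export
#' @examples
#' camera_ground_overlap(101, 100, 125)  # +0.008: one frame double support
#' camera_ground_overlap(98, 100, 125)   # -0.016: flight, illegal
camera_ground_overlap <- function(toe_off_frame, heel_strike_frame,
                                  camera_rate) {
  if (!is.numeric(camera_rate) || length(camera_rate) != 1L ||
      camera_rate <= 0)
    stop("`camera_rate` must be a single positive number")
  (toe_off_frame - heel_strike_frame) / camera_rate
}

#' Label camera overlap values
#'
#' Partitions signed overlap times at zero: `"illegal"` below zero (flight),
#' `"threshold"` at exactly zero (toe-off and heel strike in the same
#' capture frame) and `"legal"` above zero. Threshold steps are pooled with
#' legal steps in downstream accuracy bookkeeping.
#'
#' @param overlap Signed overlap time(s), seconds.
#' @return Character vector of labels.
#' @export
label_overlap <- function(overlap) {
  ifelse(overlap < 0, "illegal", ifelse(overlap == 0, "threshold", "legal"))
}

#' Compute per-step camera results from an annotation
#'
#' Applies the frame-difference overlap computation and the sign-based
#' labelling rule to every step of a camera annotation.
#'
#' @param annotation A [camera_annotation()].
#' @return A data frame of class `camera_step_result` with columns
#'   `step_index`, `overlap_time` (signed seconds) and `label`
#'   (`"legal"`, `"illegal"` or `"threshold"`).
#' @export
label_camera_steps <- function(annotation) {
  stopifnot(inherits(annotation, "camera_annotation"))
  rate <- attr(annotation, "camera_rate")
  ov <- camera_ground_overlap(annotation$toe_off_frame,
                              annotation$heel_strike_frame, rate)
  out <- data.frame(step_index = annotation$step_index,
                    overlap_time = ov,
                    label = label_overlap(ov))
  class(out) <- c("camera_step_result", "data.frame")
  out
}

#' Operator-reliability trial on repeated frame identifications
#'
#' Summarises a table of repeated video-frame identifications of the same
#' gait events (one row per event, one column per repeat): for each event,
#' the count of repeats that differ from the modal frame and the largest
#' deviation from it, in frames. Ties for the mode are broken toward the
#' earliest frame.
#'
#' @param frames Numeric matrix or data frame, events x repeats, with at
#'   least two repeats per event and no missing entries (a ragged table is
#'   rejected).
#' @return A data frame with columns `event`, `modal_frame`, `n_disagree`
#'   and `max_deviation` (frames).
#' @export
reliability_trial <- function(frames) {
  m <- as.matrix(frames)
  if (!is.numeric(m)) stop("`frames` must be numeric")
  if (anyNA(m)) stop("ragged table: missing frame identifications")
  if (ncol(m) < 2L) stop("at least two repeats per event are required")
  modal <- apply(m, 1, function(x) {
    tab <- table(x)
    as.numeric(names(tab)[which.max(tab)])  # which.max -> earliest on ties
  })
  data.frame(event = seq_len(nrow(m)),
             modal_frame = modal,
             n_disagree = rowSums(m != modal),
             max_deviation = apply(abs(m - modal), 1, max))
}
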