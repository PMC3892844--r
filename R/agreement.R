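#' Pair camera and sensor results step by step
#'
#' Joins per-step camera overlap measurements with per-step sensor
#' assessments on `step_index`, producing the comparison table that feeds
#' the agreement statistics and the confusion summary. The sensor's signed
#' timing, `sensor_overlap = flight_threshold - offset`, is on the same
#' scale and sign convention as the camera overlap: positive indicates a
#' legal step, negative indicates flight.
#'
#' @param camera_results A `camera_step_result` data frame from
#'   [label_camera_steps()].
#' @param assessments A `step_assessment` data frame from
#'   [assess_steps()] or [detect_steps()].
#' @param flight_threshold Flight threshold in seconds; defaults to the
#'   one recorded on `assessments`.
#' @return A data frame of class `step_comparison` with columns
#'   `step_index`, `camera_overlap`, `camera_label`, `sensor_offset`,
#'   `sensor_overlap` and `sensor_verdict`.
#' @export
compare_steps <- function(camera_results, assessments,
                          flight_threshold =
                            attr(assessments, "flight_threshold")) {
  stopifnot(is.data.frame(camera_results), is.data.frame(assessments))
  if (is.null(flight_threshold)) flight_threshold <- 0.03
  if (nrow(camera_results) != nrow(assessments))
    warning(sprintf(
      "step counts differ (camera %d, sensor %d); comparing matched indices only",
      nrow(camera_results), nrow(assessments)))
  merged <- merge(
    data.frame(step_index = camera_results$step_index,
               camera_overlap = camera_results$overlap_time,
               camera_label = camera_results$label),
    data.frame(step_index = assessments$step_index,
               sensor_offset = assessments$offset,
               sensor_verdict = assessments$verdict),
    by = "step_index")
  merged$sensor_overlap <- flight_threshold - merged$sensor_offset
  out <- merged[order(merged$step_index),
                c("step_index", "camera_overlap", "camera_label",
                  "sensor_offset", "sensor_overlap", "sensor_verdict")]
  rownames(out) <- NULL
  class(out) <- c("step_comparison", "data.frame")
  out
}

#' Limits-of-agreement statistics for sensor vs camera
#'
#' Validates the sensor (practical) measure against the camera (criterion)
#' with the limits-of-agreement statistics: Pearson correlation, typical
#' error of the estimate, and mean bias.
#'
#' The typical error of the estimate (TEE) is the standard error of the
#' estimate from ordinary least-squares regression of the sensor measure
#' on the camera measure: `sqrt(RSS / (n - 2))`. Its 95% confidence limits
#' come from the chi-square distribution with `n - 2` degrees of freedom.
#' The bias is `mean(sensor - camera)`; the spread attached to it is the
#' standard deviation of those differences.
#'
#' @param pairs A `step_comparison` data frame (or any data frame with
#'   columns `camera_overlap` and `sensor_overlap`, or `camera` and
#'   `sensor`), at least 3 rows, finite values, non-constant camera
#'   values.
#' @return An object of class `agreement_report`: a list with `n`,
#'   `pearson_r`, `tee`, `tee_lower_cl`, `tee_upper_cl`, `bias_mean`,
#'   `bias_sd` (all time quantities in seconds).
#' @export
agreement <- function(pairs) {
  v <- .agreement_columns(pairs)
  x <- v$camera; y <- v$sensor
  n <- length(x)
  if (n < 3L) stop("agreement requires at least 3 paired steps, got ", n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("agreement requires finite camera and sensor values")
  if (stats::sd(x) == 0)
    stop("criterion (camera) values are constant; TEE is undefined")
  fit <- stats::lm(y ~ x)
  df <- n - 2L
  tee <- sqrt(sum(stats::residuals(fit)^2) / df)
  d <- y - x
  out <- list(n = n,
              pearson_r = stats::cor(x, y),
              tee = tee,
              tee_lower_cl = tee * sqrt(df / stats::qchisq(0.975, df)),
              tee_upper_cl = tee * sqrt(df / stats::qchisq(0.025, df)),
              bias_mean = mean(d),
              bias_sd = stats::sd(d))
  class(out) <- "agreement_report"
  out
}

.agreement_columns <- function(pairs) {
  if (is.data.frame(pairs)) {
    if (all(c("camera_overlap", "sensor_overlap") %in% names(pairs)))
      return(list(camera = pairs$camera_overlap,
                  sensor = pairs$sensor_overlap))
    if (all(c("camera", "sensor") %in% names(pairs)))
      return(list(camera = pairs$camera, sensor = pairs$sensor))
  }
  stop("`pairs` must be a data frame with camera/sensor columns")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  n = %d paired steps\n", x$n))
  cat(sprintf("  Pearson r    : %.2f\n", x$pearson_r))
  cat(sprintf("  TEE          : %.3f s (95%% CL %.3f to %.3f)\n",
              x$tee, x$tee_lower_cl, x$tee_upper_cl))
  cat(sprintf("  mean bias    : %.3f (+/- %.3f) s\n",
              x$bias_mean, x$bias_sd))
  invisible(x)
}

#' Operator-reliability statistics for repeated identifications
#'
#' Quantifies operator error in repeated video-frame identifications with
#' the measures-of-reliability approach: the typical error (within-event
#' standard deviation, the square root of the mean-square error of a
#' one-way decomposition by event) with 95% chi-square confidence limits,
#' and the intraclass correlation in its two-way mixed, consistency,
#' single-measure form — repeat-to-repeat constant shifts do not lower it.
#'
#' @param frames Numeric matrix or data frame, events x repeats (>= 2
#'   events, >= 2 repeats, no missing values).
#' @return An object of class `reliability_report`: a list with
#'   `typical_error`, `te_lower_cl`, `te_upper_cl` (frames), `icc`
#'   (`NA` when between-event variance is zero), `n_events`, `n_repeats`.
#' @export
reliability <- function(frames) {
  m <- as.matrix(frames)
  if (!is.numeric(m)) stop("`frames` must be numeric")
  if (anyNA(m)) stop("ragged table: missing frame identifications")
  ne <- nrow(m); nr <- ncol(m)
  if (ne < 2L || nr < 2L)
    stop("reliability requires at least 2 events and 2 repeats")
  long <- data.frame(value = as.vector(m),
                     event = factor(rep(seq_len(ne), times = nr)),
                     rep = factor(rep(seq_len(nr), each = ne)))
  # typical error: residual mean square of the one-way (by event) fit
  one <- stats::aov(value ~ event, data = long)
  df_w <- stats::df.residual(one)
  te <- sqrt(stats::deviance(one) / df_w)
  # ICC(3,1): two-way fit, event and repeat effects
  # only the mean squares are used, so the F-test warning on a perfect
  # fit (zero residual) is irrelevant here
  two <- suppressWarnings(
    stats::anova(stats::aov(value ~ event + rep, data = long)))
  ms_b <- two["event", "Mean Sq"]
  ms_e <- two["Residuals", "Mean Sq"]
  icc <- if (ms_b <= 0 || (ms_b < 1e-12 && ms_e < 1e-12)) NA_real_
         else (ms_b - ms_e) / (ms_b + (nr - 1) * ms_e)
  out <- list(typical_error = te,
              te_lower_cl = te * sqrt(df_w / stats::qchisq(0.975, df_w)),
              te_upper_cl = te * sqrt(df_w / stats::qchisq(0.025, df_w)),
              icc = icc,
              n_events = ne, n_repeats = nr)
  class(out) <- "reliability_report"
  out
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  cat(sprintf("  %d events x %d repeats\n", x$n_events, x$n_repeats))
  cat(sprintf("  typical error: %.2f frames (95%% CL %.2f to %.2f)\n",
              x$typical_error, x$te_lower_cl, x$te_upper_cl))
  cat(sprintf("  ICC (3,1)    : %s\n",
              if (is.na(x$icc)) "undefined (no between-event variance)"
              else sprintf("%.2f", x$icc)))
  invisible(x)
}

#' Confusion summary of sensor verdicts against camera labels
#'
#' Tallies per-step agreement between the camera reference and the sensor
#' verdict. Camera `"threshold"` steps (toe-off and heel strike in the
#' same capture frame) count as legal. Two accuracy figures are reported:
#' overall agreement, and the variant that penalises only wrongly flagged
#' legal steps, `100 * (total - legal_flagged) / total` — the rate at
#' which the sensor avoids flagging a legal step as illegal.
#'
#' @param pairs A `step_comparison` data frame (columns `camera_label`
#'   and `sensor_verdict`); must be non-empty.
#' @return An object of class `confusion_summary`: a list with counts
#'   `illegal_agree`, `illegal_missed`, `legal_agree`, `legal_flagged`,
#'   `total`, and percentages `accuracy_pct` and `illegal_only_pct`.
#' @export
confusion <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) stop("confusion requires at least one paired step")
  if (!all(c("camera_label", "sensor_verdict") %in% names(pairs)))
    stop("`pairs` must have columns camera_label and sensor_verdict")
  cam_illegal <- pairs$camera_label == "illegal"
  sen_illegal <- pairs$sensor_verdict == "illegal"
  n <- nrow(pairs)
  out <- list(illegal_agree = sum(cam_illegal & sen_illegal),
              illegal_missed = sum(cam_illegal & !sen_illegal),
              legal_agree = sum(!cam_illegal & !sen_illegal),
              legal_flagged = sum(!cam_illegal & sen_illegal),
              total = n)
  out$accuracy_pct <- 100 * (out$illegal_agree + out$legal_agree) / n
  out$illegal_only_pct <- 100 * (n - out$legal_flagged) / n
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>\n")
  cat(sprintf("  camera illegal: %d agreed, %d missed by sensor\n",
              x$illegal_agree, x$illegal_missed))
  cat(sprintf("  camera legal  : %d agreed, %d flagged by sensor\n",
              x$legal_agree, x$legal_flagged))
  cat(sprintf("  accuracy      : %.2f%% (%.0f%%); illegal-only %.2f%%\n",
              x$accuracy_pct, round(x$accuracy_pct), x$illegal_only_pct))
  invisible(x)
}
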