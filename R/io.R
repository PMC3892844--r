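#' Write an acceleration trace to CSV
#'
#' Columns: `time_s`, `ap_g`, `vert_g`, `ml_g` (comma separator, dot
#' decimal, header row).
#'
#' @param trace An [accel_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read an acceleration trace from CSV
#'
#' @param path CSV file with columns `time_s`, `ap_g`, `vert_g`, `ml_g`.
#' @param sample_rate Sampling rate in Hz; inferred from the time column
#'   when `NULL`.
#' @return An [accel_trace()].
#' @export
read_trace_csv <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "ap_g", "vert_g", "ml_g")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(sample_rate)) {
    if (nrow(df) < 2L)
      stop("cannot infer sample rate from fewer than 2 samples")
    sample_rate <- 1 / stats::median(diff(df$time_s))
  }
  accel_trace(df$ap_g, df$vert_g, df$ml_g, sample_rate,
              start_time = if (nrow(df)) df$time_s[1] else 0)
}

#' Write a camera annotation to JSON
#'
#' @param annotation A [camera_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_json <- function(annotation, path) {
  stopifnot(inherits(annotation, "camera_annotation"))
  obj <- list(camera_rate = attr(annotation, "camera_rate"),
              steps = as.data.frame(unclass(annotation)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a camera annotation from JSON
#'
#' @param path JSON file as written by [write_annotation_json()].
#' @return A [camera_annotation()].
#' @export
read_annotation_json <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  steps <- obj$steps
  if (is.null(steps) || length(steps) == 0L || NROW(steps) == 0L)
    return(camera_annotation(integer(0), integer(0), obj$camera_rate))
  camera_annotation(steps$toe_off_frame, steps$heel_strike_frame,
                    obj$camera_rate)
}

#' Write ground truth to JSON
#' @param truth A `gait_truth` data frame from [simulate_walk()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(as.data.frame(unclass(truth)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write step assessments to CSV
#'
#' Columns: `step_index`, `vert_min_time_s`, `heel_strike_time_s`,
#' `offset_s`, `verdict`.
#'
#' @param assessments A `step_assessment` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assessments_csv <- function(assessments, path) {
  df <- data.frame(step_index = assessments$step_index,
                   vert_min_time_s = assessments$vert_min_time,
                   heel_strike_time_s = assessments$heel_strike_time,
                   offset_s = assessments$offset,
                   verdict = assessments$verdict)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read step assessments from CSV
#' @param path CSV as written by [write_assessments_csv()].
#' @param flight_threshold Threshold recorded on the result attribute.
#' @return A `step_assessment` data frame.
#' @export
read_assessments_csv <- function(path, flight_threshold = 0.03) {
  if (!file.exists(path)) stop("assessments file not found: ", path)
  df <- utils::read.csv(path)
  out <- data.frame(step_index = df$step_index,
                    vert_min_time = df$vert_min_time_s,
                    heel_strike_time = df$heel_strike_time_s,
                    offset = df$offset_s,
                    verdict = df$verdict)
  attr(out, "flight_threshold") <- flight_threshold
  class(out) <- c("step_assessment", "data.frame")
  out
}

#' Write camera step results to CSV
#'
#' Columns: `step_index`, `overlap_s`, `label`.
#'
#' @param results A `camera_step_result` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_camera_results_csv <- function(results, path) {
  df <- data.frame(step_index = results$step_index,
                   overlap_s = results$overlap_time,
                   label = results$label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read camera step results from CSV
#' @param path CSV as written by [write_camera_results_csv()].
#' @return A `camera_step_result` data frame.
#' @export
read_camera_results_csv <- function(path) {
  if (!file.exists(path)) stop("camera results file not found: ", path)
  df <- utils::read.csv(path)
  out <- data.frame(step_index = df$step_index,
                    overlap_time = df$overlap_s,
                    label = df$label)
  class(out) <- c("camera_step_result", "data.frame")
  out
}

#' Write the merged step comparison to CSV
#' @param pairs A `step_comparison` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(pairs, path) {
  df <- data.frame(step_index = pairs$step_index,
                   camera_overlap_s = pairs$camera_overlap,
                   camera_label = pairs$camera_label,
                   sensor_offset_s = pairs$sensor_offset,
                   sensor_overlap_s = pairs$sensor_overlap,
                   sensor_verdict = pairs$sensor_verdict)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a merged step comparison from CSV
#' @param path CSV as written by [write_comparison_csv()].
#' @return A `step_comparison` data frame.
#' @export
read_comparison_csv <- function(path) {
  if (!file.exists(path)) stop("comparison file not found: ", path)
  df <- utils::read.csv(path)
  out <- data.frame(step_index = df$step_index,
                    camera_overlap = df$camera_overlap_s,
                    camera_label = df$camera_label,
                    sensor_offset = df$sensor_offset_s,
                    sensor_overlap = df$sensor_overlap_s,
                    sensor_verdict = df$sensor_verdict)
  class(out) <- c("step_comparison", "data.frame")
  out
}

#' Write agreement and confusion reports to JSON
#'
#' @param agreement_report An `agreement_report`, or `NULL`.
#' @param confusion_summary A `confusion_summary`, or `NULL`.
#' @param path Output file path.
#' @param manifest Optional named list echoed under `"manifest"`.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(agreement_report = NULL,
                              confusion_summary = NULL,
                              path, manifest = NULL) {
  obj <- list()
  if (!is.null(agreement_report))
    obj$agreement <- unclass(agreement_report)
  if (!is.null(confusion_summary))
    obj$confusion <- unclass(confusion_summary)
  if (!is.null(manifest)) obj$manifest <- manifest
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
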