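#' Pipeline configuration
#'
#' Assembles the configuration of the end-to-end pipeline. In simulate
#' mode the input trace and annotation are generated by [simulate_walk()];
#' otherwise they are read from `trace_path` and `annotation_path`.
#'
#' @param out_dir Directory where artefacts are written.
#' @param simulate Logical: generate the inputs synthetically?
#' @param gait GaitParams for simulate mode (a [gait_params()] object).
#' @param detection A [detection_config()].
#' @param trace_path,annotation_path Input files for non-simulate mode.
#' @param camera_rate Camera rate used when the annotation does not carry
#'   one.
#' @param write_plot Logical: also write the quadrant plot (PDF)?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            gait = gait_params(),
                            detection = detection_config(),
                            trace_path = NULL,
                            annotation_path = NULL,
                            camera_rate = 125,
                            write_plot = FALSE) {
  stopifnot(inherits(detection, "detection_config"))
  if (simulate) stopifnot(inherits(gait, "gait_params"))
  structure(list(out_dir = out_dir, simulate = simulate, gait = gait,
                 detection = detection, trace_path = trace_path,
                 annotation_path = annotation_path,
                 camera_rate = camera_rate, write_plot = write_plot),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the CLI flags one-to-one: `out_dir`, `simulate`,
#' `trace_path`, `annotation_path`, `camera_rate`, `write_plot`, plus any
#' [gait_params()] argument under `gait:` and any [detection_config()]
#' argument under `detection:`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  gait <- do.call(gait_params, as.list(y$gait))
  detection <- do.call(detection_config, as.list(y$detection))
  pipeline_config(out_dir = y$out_dir,
                  simulate = isTRUE(y$simulate) || is.null(y$trace_path),
                  gait = gait, detection = detection,
                  trace_path = y$trace_path,
                  annotation_path = y$annotation_path,
                  camera_rate = if (is.null(y$camera_rate)) 125
                                else y$camera_rate,
                  write_plot = isTRUE(y$write_plot))
}

#' Run the full sensor-validation pipeline
#'
#' Executes simulate (optional) -> detect -> camera-label -> compare ->
#' agreement/confusion, writing every artefact to `config$out_dir` along
#' with a run manifest recording the configuration actually used. Each
#' stage logs a structured line; a failure is re-signalled with the stage
#' name and offending input attached.
#'
#' With zero steps the pipeline warns and returns an empty report rather
#' than failing.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `comparison`,
#'   `agreement` (or `NULL` when fewer than 3 steps), `confusion` (or
#'   `NULL` when no steps), `truth` (simulate mode only) and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    trace = file.path(config$out_dir, "trace.csv"),
    annotation = file.path(config$out_dir, "annotation.json"),
    truth = file.path(config$out_dir, "truth.json"),
    assessments = file.path(config$out_dir, "assessments.csv"),
    camera = file.path(config$out_dir, "camera_results.csv"),
    comparison = file.path(config$out_dir, "comparison.csv"),
    report = file.path(config$out_dir, "report.json"),
    manifest = file.path(config$out_dir, "manifest.json"))

  stage <- function(name, input, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed on %s: %s",
                   name, input, conditionMessage(e)), call. = FALSE)
    })
  }
  log_stage <- function(name, n_in, n_out)
    message(sprintf("[%s] in=%s out=%s", name, n_in, n_out))

  truth <- NULL
  if (config$simulate) {
    sim <- stage("simulate", "gait_params", simulate_walk(config$gait))
    trace <- sim$trace; annotation <- sim$annotation; truth <- sim$truth
    write_trace_csv(trace, paths$trace)
    write_annotation_json(annotation, paths$annotation)
    write_truth_json(truth, paths$truth)
    log_stage("simulate", config$gait$n_steps, length(trace))
  } else {
    trace <- stage("read-trace", config$trace_path %||% "<missing>", {
      if (is.null(config$trace_path)) stop("no trace path configured")
      read_trace_csv(config$trace_path)
    })
    annotation <- stage("read-annotation",
                        config$annotation_path %||% "<missing>", {
      if (is.null(config$annotation_path))
        stop("no annotation path configured")
      read_annotation_json(config$annotation_path)
    })
    log_stage("read", 2, length(trace))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("flightcheck")),
    simulate = config$simulate,
    seed = if (config$simulate) config$gait$seed,
    n_steps = if (config$simulate) config$gait$n_steps,
    flight_threshold = config$detection$flight_threshold,
    cutoff_hz = config$detection$cutoff_hz,
    min_peak_separation = config$detection$min_peak_separation,
    peak_prominence = config$detection$peak_prominence)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  if (length(trace) == 0L || nrow(annotation) == 0L) {
    warning("zero steps: writing an empty report")
    write_report_json(NULL, NULL, paths$report, manifest = manifest)
    out <- list(comparison = NULL, agreement = NULL, confusion = NULL,
                truth = truth, paths = paths)
    class(out) <- "pipeline_result"
    return(out)
  }

  assessments <- stage("detect", paths$trace,
                       detect_steps(trace, config$detection))
  write_assessments_csv(assessments, paths$assessments)
  log_stage("detect", length(trace), nrow(assessments))
  n_unpaired <- attr(assessments, "n_unpaired_minima")
  # a cycle or two at the trace edges routinely has no heel strike in the
  # analysis window; warn only when interior steps go undetected
  if (n_unpaired > max(2L, 0.05 * nrow(assessments)))
    warning(n_unpaired, " step cycles had no pairable heel strike")

  camera <- stage("camera-label", paths$annotation,
                  label_camera_steps(annotation))
  write_camera_results_csv(camera, paths$camera)
  log_stage("camera-label", nrow(annotation), nrow(camera))

  pairs <- stage("compare", paths$comparison,
                 compare_steps(camera, assessments))
  write_comparison_csv(pairs, paths$comparison)
  log_stage("compare", nrow(camera), nrow(pairs))

  agr <- if (nrow(pairs) >= 3L && stats::sd(pairs$camera_overlap) > 0)
    stage("agreement", paths$comparison, agreement(pairs)) else NULL
  conf <- if (nrow(pairs) > 0L)
    stage("confusion", paths$comparison, confusion(pairs)) else NULL
  write_report_json(agr, conf, paths$report, manifest = manifest)

  if (isTRUE(config$write_plot) && nrow(pairs) > 0L) {
    qr <- quadrant_report(pairs)
    paths$plot <- file.path(config$out_dir, "quadrant.pdf")
    ggplot2::ggsave(paths$plot, qr$plot, width = 6, height = 6)
  }

  out <- list(comparison = pairs, agreement = agr, confusion = conf,
              truth = truth, paths = paths)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (is.null(x$comparison)) {
    cat("  empty run (zero steps)\n")
  } else {
    cat(sprintf("  %d paired steps; artefacts in %s\n",
                nrow(x$comparison), dirname(x$paths$report)))
    if (!is.null(x$confusion))
      cat(sprintf("  accuracy %.2f%%\n", x$confusion$accuracy_pct))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
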