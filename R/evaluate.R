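#' Success-radius scoring of a single localization
#'
#' A localization succeeds when the estimated center lies within
#' `radius_px` (inclusive) of the true center, the circle criterion of the
#' original evaluation (43.5 px = 0.5 cm at 87 px/cm). An absent estimate
#' is a failure, not an error.
#'
#' @param estimate Estimated center `(col, row)`, or `NULL`.
#' @param truth True center `(col, row)`.
#' @param radius_px Success radius in pixels (default 43.5).
#' @return Logical success flag.
#' @export
score_localization <- function(estimate, truth, radius_px = 43.5) {
  if (radius_px <= 0) stop_config("radius_px must be > 0")
  if (is.null(estimate) || anyNA(estimate)) return(FALSE)
  sqrt(sum((estimate - truth)^2)) <= radius_px
}

#' Evaluate localization results against ground truth
#'
#' Joins results and truths by `scene_id` and reports per-scenario and
#' overall success under the success-radius criterion. Results whose
#' status is not `"ok"` (degenerate, out-of-frame, missing second frame,
#' not found) count as failures with their reason retained.
#'
#' @param results data.frame with columns `scene_id`, `scenario`,
#'   `case_id`, `center_col`, `center_row`, `status`.
#' @param truths data.frame with columns `scene_id`, `truth_col`,
#'   `truth_row`.
#' @param radius_px Success radius in pixels (default 43.5).
#' @return An object of class `evaluation_report`: `per_scenario`
#'   data.frame (scenario, n, successes, accuracy), `overall` list (n,
#'   successes, accuracy), `failures` data.frame, `radius_px`.
#' @export
evaluate_localizations <- function(results, truths, radius_px = 43.5) {
  if (!setequal(results$scene_id, truths$scene_id) ||
      nrow(results) != nrow(truths))
    stop_config("results and truths must be keyed by the same scene ids")
  truths <- truths[, c("scene_id", "truth_col", "truth_row"), drop = FALSE]
  m <- merge(results, truths, by = "scene_id", sort = TRUE)
  dist <- sqrt((m$center_col - m$truth_col)^2 +
               (m$center_row - m$truth_row)^2)
  ok <- !is.na(dist) & dist <= radius_px & m$status == "ok"
  m$success <- ok
  m$error_px <- dist
  per <- do.call(rbind, lapply(split(m, m$scenario), function(d) {
    data.frame(scenario = d$scenario[1], n = nrow(d),
               successes = sum(d$success),
               accuracy = sum(d$success) / nrow(d))
  }))
  if (is.null(per)) {
    per <- data.frame(scenario = character(0), n = integer(0),
                      successes = integer(0), accuracy = numeric(0))
  }
  rownames(per) <- NULL
  failures <- m[!m$success,
                c("scene_id", "scenario", "case_id", "status", "error_px"),
                drop = FALSE]
  rownames(failures) <- NULL
  structure(
    list(per_scenario = per,
         overall = list(n = nrow(m), successes = sum(m$success),
                        accuracy = if (nrow(m)) sum(m$success) / nrow(m)
                                   else NA_real_),
         failures = failures,
         radius_px = radius_px,
         details = m),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> radius %.1f px\n", x$radius_px))
  print(x$per_scenario, row.names = FALSE)
  cat(sprintf("overall: %d/%d = %.1f%%\n", x$overall$successes,
              x$overall$n, 100 * (x$overall$accuracy %||% NA)))
  invisible(x)
}

#' Write an evaluation report as JSON and/or CSV
#'
#' @param report An [evaluate_localizations()] report.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(radius_px = report$radius_px,
           overall = report$overall,
           per_scenario = report$per_scenario,
           failures = report$failures),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(report$per_scenario, csv_path, row.names = FALSE)
  invisible(report)
}

#' Simulate, localize and score a full synthetic benchmark
#'
#' End-to-end driver: generates the seeded benchmark, renders each scene,
#' runs the full pipeline (smooth, threshold, blob extraction, region
#' assignment, case dispatch, localization) and scores every scene with
#' the success-radius criterion. Scenes are rendered and processed one at
#' a time so memory stays flat.
#'
#' @param counts Scenes per scenario (see [make_benchmark()]).
#' @param seed RNG seed.
#' @param layout,g,b_range,l,photometry Passed to [make_benchmark()].
#' @param radius_px Success radius (default 43.5).
#' @param threshold,min_area,kernel Pipeline parameters (see
#'   [locate_frame()]).
#' @return List with `report` (an `evaluation_report`), `results`
#'   (per-scene data.frame) and `manifest`.
#' @export
run_benchmark <- function(counts = default_benchmark_counts(), seed = 1L,
                          layout = build_layout(), g = rig_geometry(),
                          b_range = c(1, 10), l = 4,
                          photometry = scene_photometry(),
                          radius_px = 43.5, threshold = 4, min_area = 20L,
                          kernel = 3L) {
  bench <- make_benchmark(counts = counts, seed = seed, layout = layout,
                          g = g, b_range = b_range, l = l,
                          photometry = photometry)
  rows <- lapply(bench$scenes, function(scene) {
    frames <- render_frames(scene, layout)
    res <- locate_frame(frames[[1]], layout, g,
                        frame2 = if (length(frames) > 1L) frames[[2]] else NULL,
                        l = scene$l, threshold = threshold,
                        min_area = min_area, kernel = kernel)
    data.frame(
      scene_id = scene$scene_id, scenario = scene$scenario,
      case_id = as.character(res$case_id),
      center_col = if (is.null(res$center)) NA_real_ else res$center[1],
      center_row = if (is.null(res$center)) NA_real_ else res$center[2],
      a_cm = if (is.null(res$solver)) NA_real_ else unname(res$solver["a"]),
      b_cm = if (is.null(res$solver)) NA_real_ else unname(res$solver["b"]),
      status = res$status
    )
  })
  results <- do.call(rbind, rows)
  report <- evaluate_localizations(results, bench$manifest,
                                   radius_px = radius_px)
  list(report = report, results = results, manifest = bench$manifest)
}
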