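#' Lines in the image plane
#'
#' Lines are stored as a base point plus a unit direction and treated as
#' infinite for intersection purposes (the rule system's "connect" and
#' "perpendicular" constructions intersect line extensions).
#'
#' @param p1,p2 Two distinct points `(col, row)`.
#' @return An object of class `line_seg`.
#' @export
line_through <- function(p1, p2) {
  d <- p2 - p1
  n <- sqrt(sum(d^2))
  if (n == 0) stop_config("line endpoints must be distinct")
  structure(list(p = p1, dir = d / n), class = "line_seg")
}

#' @rdname line_through
#' @param p Base point `(col, row)`.
#' @param dir Direction vector (normalized internally).
#' @export
line_dir <- function(p, dir) {
  n <- sqrt(sum(dir^2))
  if (n == 0) stop_config("line direction must be nonzero")
  structure(list(p = p, dir = dir / n), class = "line_seg")
}

stop_parallel <- function(msg) {
  stop(structure(class = c("fluorloc_parallel_lines", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Intersect two lines
#'
#' Unique intersection point of the infinite extensions, at sub-pixel
#' precision. Lines whose directions differ by less than `angular_eps`
#' radians are rejected as parallel, signalling an unlocalizable frame.
#'
#' @param l1,l2 Lines from [line_through()] / [line_dir()].
#' @param angular_eps Angular tolerance in radians (default 1e-6).
#' @return Intersection point `(col, row)`.
#' @export
intersect_lines <- function(l1, l2, angular_eps = 1e-6) {
  cross <- l1$dir[1] * l2$dir[2] - l1$dir[2] * l2$dir[1]
  if (abs(cross) < angular_eps)
    stop_parallel("lines are parallel within the angular tolerance")
  dp <- l2$p - l1$p
  t <- (dp[1] * l2$dir[2] - dp[2] * l2$dir[1]) / cross
  unname(l1$p + t * l1$dir)
}

#' Line through a point perpendicular to a mirror edge
#'
#' The rule system's "vertical line of the mirror edge through" a blob is
#' read as the line through the blob center along the edge's inward
#' normal, i.e. perpendicular to the mirror edge (the direction in which a
#' reflection displaces the plant's image).
#'
#' @param p Point `(col, row)` (typically a blob centroid).
#' @param edge A mirror edge from a [build_layout()] (`layout$edges$TL`
#'   etc.): list with `p1`, `p2` and inward `normal`.
#' @return A `line_seg` through `p` along the edge normal.
#' @export
perpendicular_through <- function(p, edge) {
  normal <- edge$normal %||% {
    d <- edge$p2 - edge$p1
    c(-d[2], d[1]) / sqrt(sum(d^2))
  }
  line_dir(p, normal)
}

# signed coordinate of pixel point p along a unit axis, about the layout
# center, in world units
axis_coord_world <- function(p, axis, layout, g) {
  sum((p - layout$center) * axis) / g$pixel_scale
}

# signed pixel coordinate along the axis rotated 90 deg (along-edge)
perp_axis <- function(axis) c(-axis[2], axis[1])

#' Signed cross-frame travel shift for a mirror
#'
#' The published two-frame relation shifts the plant's mirror-axis
#' coordinate by `l * sin(theta)` between frames. For a camera moving
#' along `travel_axis`, the shift along a specific mirror's axis is
#' `-l * sin(theta) * sign(travel_axis . mirror_axis)`: positive for
#' mirrors behind the direction of travel, negative ahead of it. The
#' renderer and the solver share this helper, so the convention cannot
#' drift between them.
#'
#' @param mirror Mirror label (`"TL"`, `"TR"`, `"BL"`, `"BR"`).
#' @param g A [rig_geometry()].
#' @param l Camera travel between frames (cm).
#' @return Signed shift of the plant's axis coordinate (cm).
#' @export
travel_shift <- function(mirror, g, l) {
  ax <- mirror_table()[[mirror]]$axis
  dp <- sum(g$travel_axis * ax)
  if (abs(dp) < 1e-9)
    stop_config("travel axis is parallel to the mirror edge: no usable parallax")
  -sign(dp) * l * sin(g$theta_deg * pi / 180)
}

primary_centroid <- function(assign, region) {
  b <- assign$primary[[region]]
  c(b$centroid_col, b$centroid_row)
}

localization_result <- function(case_id, scenario, center = NULL,
                                solver = NULL, status = "ok",
                                diagnostics = list(), layout = NULL) {
  if (!is.null(center) && !is.null(layout) && status == "ok") {
    inside <- center[1] >= 0.5 && center[1] <= layout$width + 0.5 &&
              center[2] >= 0.5 && center[2] <= layout$height + 0.5
    if (!inside) status <- "out_of_frame"
  }
  structure(
    list(case_id = case_id, scenario = scenario, center = center,
         solver = solver, status = status, diagnostics = diagnostics),
    class = "localization_result"
  )
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization> case %s (scenario %s), status %s",
              as.character(x$case_id), x$scenario, x$status))
  if (!is.null(x$center))
    cat(sprintf(", center (%.2f, %.2f)", x$center[1], x$center[2]))
  if (!is.null(x$solver))
    cat(sprintf(", a = %.3f cm, b = %.3f cm", x$solver["a"], x$solver["b"]))
  cat("\n")
  invisible(x)
}

# match the frame-1 blob to a frame-2 blob in the same region: nearest
# centroid after undoing the expected whole-scene travel
match_second_frame <- function(blob1_px, assign2, region, g, l) {
  rows <- assign2$blobs[assign2$blobs$region == region, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_degenerate(sprintf("no frame-2 blob in region %s to match", region))
  expected <- blob1_px - l * g$pixel_scale * g$travel_axis
  d2 <- (rows$centroid_col - expected[1])^2 + (rows$centroid_row - expected[2])^2
  rows[which.min(d2), , drop = FALSE]
}

#' Compute the plant center from a region assignment
#'
#' Executes the sixteen-case rule system: direct extraction when the
#' central area shows fluorescence (Case 1); diagonal connections and
#' mirror-edge perpendiculars with line intersection for the multi-mirror
#' cases (Cases 2-10); the opposing-mirror solver for the two opposite
#' pairs (Cases 11-12); and the two-frame parallax solver for single
#' mirrors (Cases 13-16, which require the second frame and the camera
#' travel `l`). For the solver cases the recovered 1-D lateral position is
#' placed along the mirror-pair axis through the frame center and the
#' along-edge pixel coordinate is taken from the blob centroids (mean of
#' the pair for Cases 11-12, frame-1 blob for Cases 13-16), under the
#' assumption that reflection preserves the coordinate parallel to the
#' mirror edge.
#'
#' Failure paths (no fluorescence, insufficient parallax, parallel
#' construction lines, missing second frame, off-frame intersection)
#' return a typed `status` rather than a fabricated center.
#'
#' @param assign A [assign_blobs()] result for frame 1.
#' @param layout The [build_layout()] used for the assignment.
#' @param g A [rig_geometry()].
#' @param second_frame_assign Optional [assign_blobs()] result for frame 2
#'   (required for Cases 13-16).
#' @param l Camera travel between the two frames (cm; required for Cases
#'   13-16).
#' @return A `localization_result`: `case_id`, `scenario`, `center`
#'   (`(col, row)` or `NULL`), `solver` (`c(a, b)` for Cases 11-16),
#'   `status`, `diagnostics`.
#' @export
locate_center <- function(assign, layout, g,
                          second_frame_assign = NULL, l = NULL) {
  cls <- classify_case(assign)
  cid <- cls$case_id
  scen <- cls$scenario
  if (identical(cid, "NOT_FOUND"))
    return(localization_result(cid, scen, status = "not_found",
                               diagnostics = list(reason = "no fluorescence detected")))

  run <- function(expr) {
    tryCatch(expr,
      fluorloc_degenerate_observation = function(e)
        localization_result(cid, scen, status = "degenerate",
                            diagnostics = list(reason = conditionMessage(e))),
      fluorloc_singular_geometry = function(e)
        localization_result(cid, scen, status = "degenerate",
                            diagnostics = list(reason = conditionMessage(e))),
      fluorloc_parallel_lines = function(e)
        localization_result(cid, scen, status = "parallel_lines",
                            diagnostics = list(reason = conditionMessage(e))))
  }

  mt <- mirror_table()

  if (cid == 1L)
    return(localization_result(cid, scen,
                               center = primary_centroid(assign, "MC"),
                               diagnostics = list(source = "MC blob"),
                               layout = layout))

  if (cid == 2L) {
    return(run({
      l1 <- line_through(primary_centroid(assign, "TL"),
                         primary_centroid(assign, "BR"))
      l2 <- line_through(primary_centroid(assign, "TR"),
                         primary_centroid(assign, "BL"))
      localization_result(cid, scen, center = intersect_lines(l1, l2),
                          diagnostics = list(lines = c("TL-BR", "TR-BL")),
                          layout = layout)
    }))
  }

  if (cid %in% 3:6) {
    members <- case_definitions()[[as.character(cid)]]
    pair <- if (all(c("TL", "BR") %in% members)) c("TL", "BR") else c("TR", "BL")
    third <- setdiff(members, pair)
    return(run({
      l1 <- line_through(primary_centroid(assign, pair[1]),
                         primary_centroid(assign, pair[2]))
      l2 <- perpendicular_through(primary_centroid(assign, third),
                                  layout$edges[[third]])
      localization_result(cid, scen, center = intersect_lines(l1, l2),
                          diagnostics = list(
                            lines = c(paste(pair, collapse = "-"),
                                      paste0("perp@", third))),
                          layout = layout)
    }))
  }

  if (cid %in% 7:10) {
    members <- case_definitions()[[as.character(cid)]]
    return(run({
      l1 <- perpendicular_through(primary_centroid(assign, members[1]),
                                  layout$edges[[members[1]]])
      l2 <- perpendicular_through(primary_centroid(assign, members[2]),
                                  layout$edges[[members[2]]])
      localization_result(cid, scen, center = intersect_lines(l1, l2),
                          diagnostics = list(
                            lines = paste0("perp@", members)),
                          layout = layout)
    }))
  }

  if (cid %in% 11:12) {
    pair_id <- if (cid == 12L) "pair_TLBR" else "pair_TRBL"
    pr <- layout$pairs[[pair_id]]
    axis <- mt[[pr["primary"]]]$axis
    tax <- perp_axis(axis)
    p_pri <- primary_centroid(assign, pr["primary"])
    p_sec <- primary_centroid(assign, pr["secondary"])
    return(run({
      x <- axis_coord_world(p_pri, axis, layout, g)
      x1 <- axis_coord_world(p_sec, axis, layout, g)
      sol <- solve_opposite(x, x1, g)
      t_px <- mean(c(sum((p_pri - layout$center) * tax),
                     sum((p_sec - layout$center) * tax)))
      center <- layout$center + sol["a"] * g$pixel_scale * axis + t_px * tax
      localization_result(cid, scen, center = unname(center), solver = sol,
                          diagnostics = list(pair = pair_id,
                                             x = x, x1 = x1),
                          layout = layout)
    }))
  }

  # Cases 13-16: single mirror across two frames
  mirror <- case_definitions()[[as.character(cid)]]
  if (is.null(second_frame_assign) || is.null(l)) {
    return(localization_result(cid, scen, status = "missing_second_frame",
                               diagnostics = list(
                                 reason = "single-mirror case needs a second frame and travel distance")))
  }
  axis <- mt[[mirror]]$axis
  tax <- perp_axis(axis)
  p1 <- primary_centroid(assign, mirror)
  run({
    b2 <- match_second_frame(p1, second_frame_assign, mirror, g, l)
    p2 <- c(b2$centroid_col, b2$centroid_row)
    x1 <- axis_coord_world(p1, axis, layout, g)
    x2 <- axis_coord_world(p2, axis, layout, g)
    shift <- travel_shift(mirror, g, l)
    sol <- solve_single_mirror(x1, x2, g, l, signed_shift = shift)
    t_px <- sum((p1 - layout$center) * tax)
    center <- layout$center + sol["a"] * g$pixel_scale * axis + t_px * tax
    localization_result(cid, scen, center = unname(center), solver = sol,
                        diagnostics = list(mirror = mirror, x1 = x1, x2 = x2,
                                           shift_cm = shift),
                        layout = layout)
  })
}

#' Full single-frame (or two-frame) localization from images
#'
#' Convenience wrapper chaining [smooth_frame()], [segment_frame()],
#' [extract_blobs()], [assign_blobs()] and [locate_center()].
#'
#' @param frame A [gray_frame()].
#' @param layout A [build_layout()].
#' @param g A [rig_geometry()].
#' @param frame2 Optional second frame for the single-mirror cases.
#' @param l Camera travel between frames (cm), when `frame2` is given.
#' @param threshold Segmentation threshold (default 4).
#' @param min_area Minimum blob area in px (default 20).
#' @param kernel Smoothing kernel size (default 3).
#' @return A `localization_result`.
#' @export
locate_frame <- function(frame, layout, g, frame2 = NULL, l = NULL,
                         threshold = 4, min_area = 20L, kernel = 3L) {
  process <- function(f) {
    sm <- smooth_frame(f, kernel = kernel)
    assign_blobs(extract_blobs(segment_frame(sm, threshold), sm,
                               min_area = min_area), layout)
  }
  a1 <- process(frame)
  a2 <- if (!is.null(frame2)) process(frame2) else NULL
  locate_center(a1, layout, g, second_frame_assign = a2, l = l)
}
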