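#' Default photometry of the synthetic fluorescence signal
#'
#' Isotropic Gaussian blob of peak 200 (8-bit scale) and sigma 3 px over a
#' background offset of 2, with i.i.d. Gaussian sensor noise; emulates a
#' bright systemic-dye cotyledon signal against the near-black chamber
#' background whose measured ceiling motivates the default threshold of 4.
#'
#' @param peak Blob peak intensity above background (default 200).
#' @param sigma_px Blob standard deviation in pixels (default 3).
#' @param background Background offset in intensity levels (default 2).
#' @param noise_sigma Sensor noise standard deviation (default 2).
#' @return List of photometry parameters.
#' @export
scene_photometry <- function(peak = 200, sigma_px = 3, background = 2,
                             noise_sigma = 2) {
  if (peak <= 4) stop_config("blob peak must exceed the segmentation threshold")
  if (background > 4) stop_config("background offset must not exceed the threshold")
  list(peak = peak, sigma_px = sigma_px, background = background,
       noise_sigma = noise_sigma)
}

scenario_names <- function() {
  c("central", "four", "three", "two_nonopposite", "two_opposite", "one")
}

sample_occupancy <- function(scenario) {
  switch(scenario,
    central = "MC",
    four = mirror_names(),
    three = case_definitions()[[as.character(sample(3:6, 1L))]],
    two_nonopposite = case_definitions()[[as.character(sample(7:10, 1L))]],
    two_opposite = case_definitions()[[as.character(sample(11:12, 1L))]],
    one = sample(mirror_names(), 1L),
    stop_config(sprintf("unknown scenario '%s'", scenario))
  )
}

in_rect_margin <- function(p, r, margin) {
  p[1] >= r[1] + margin && p[1] <= r[2] - margin &&
    p[2] >= r[3] + margin && p[2] <= r[4] - margin
}

# forward-project the plant into every occupied region; returns NULL when a
# projection is singular or a blob leaves its designated region
project_scene <- function(p, b, occ, layout, g, margin) {
  mt <- mirror_table()
  blob <- list()
  mirrors <- intersect(occ, mirror_names())
  done <- character(0)
  if ("MC" %in% occ) blob$MC <- p
  for (pid in names(layout$pairs)) {
    pr <- layout$pairs[[pid]]
    if (all(pr %in% mirrors)) {
      axis <- mt[[pr[["primary"]]]]$axis
      tax <- perp_axis(axis)
      a <- axis_coord_world(p, axis, layout, g)
      t_px <- sum((p - layout$center) * tax)
      xs <- tryCatch(forward_opposite_pair(a, b, g), error = function(e) NULL)
      if (is.null(xs)) return(NULL)
      blob[[pr[["primary"]]]] <-
        layout$center + xs["x"] * g$pixel_scale * axis + t_px * tax
      blob[[pr[["secondary"]]]] <-
        layout$center + xs["x1"] * g$pixel_scale * axis + t_px * tax
      done <- c(done, pr)
    }
  }
  for (m in setdiff(mirrors, done)) {
    axis <- mt[[m]]$axis
    tax <- perp_axis(axis)
    a <- axis_coord_world(p, axis, layout, g)
    t_px <- sum((p - layout$center) * tax)
    x <- tryCatch(forward_single_view(a, b, g), error = function(e) NULL)
    if (is.null(x)) return(NULL)
    blob[[m]] <- layout$center + x * g$pixel_scale * axis + t_px * tax
  }
  for (m in names(blob)) {
    if (!in_rect_margin(blob[[m]], layout$rects[[m]], margin)) return(NULL)
  }
  blob
}

#' Sample a synthetic scene for an occlusion scenario
#'
#' Draws a ground-truth plant position uniformly in the central crop
#' area's footprint and a fluorescence height `b` uniformly in `b_range`,
#' selects which regions show fluorescence according to the scenario, and
#' forward-projects the fluorescence into every designated mirror view
#' with the same equations the solvers invert. Draws are rejected until
#' every designated view lands inside its region with a safety margin
#' (i.e. the sampled pose is actually visible in those mirrors), so the
#' accepted `b` marginal is truncated by the rig geometry.
#'
#' @param scenario One of `"central"`, `"four"`, `"three"`,
#'   `"two_nonopposite"`, `"two_opposite"`, `"one"`.
#' @param layout A [build_layout()].
#' @param g A [rig_geometry()].
#' @param b_range Range of the fluorescence height prior (cm; default
#'   `c(1, 10)`, the cotyledon height scale).
#' @param l Camera travel between the two frames of the single-mirror
#'   scenario (cm, default 4).
#' @param photometry A [scene_photometry()].
#' @param margin_px Safety margin (px) every blob center must keep from
#'   its region's boundary (default 10, about three blob sigmas).
#' @param max_tries Rejection-sampling cap (default 5000).
#' @return An object of class `synthetic_scene`: scenario, occupied
#'   regions, `truth_center_px`, fluorescence height `b`, per-region blob
#'   centers, the second-frame blob for the single-mirror scenario, `l`,
#'   photometry and a per-scene noise seed.
#' @export
sample_scene <- function(scenario, layout = build_layout(),
                         g = rig_geometry(), b_range = c(1, 10), l = 4,
                         photometry = scene_photometry(), margin_px = 10,
                         max_tries = 5000L) {
  scenario <- match.arg(scenario, scenario_names())
  occ <- sample_occupancy(scenario)
  mc <- layout$rects$MC
  for (try in seq_len(max_tries)) {
    p <- c(stats::runif(1, mc[1] + margin_px, mc[2] - margin_px),
           stats::runif(1, mc[3] + margin_px, mc[4] - margin_px))
    b <- stats::runif(1, b_range[1], b_range[2])
    blob <- project_scene(p, b, occ, layout, g, margin_px)
    if (is.null(blob)) next
    blob2 <- NULL
    if (scenario == "one") {
      m <- occ
      axis <- mirror_table()[[m]]$axis
      tax <- perp_axis(axis)
      a1 <- axis_coord_world(p, axis, layout, g)
      shift <- travel_shift(m, g, l)
      xs <- tryCatch(forward_two_frames(a1, b, g, l, signed_shift = shift),
                     error = function(e) NULL)
      if (is.null(xs)) next
      p2 <- p - l * g$pixel_scale * g$travel_axis  # plant in frame-2 rig coords
      t2_px <- sum((p2 - layout$center) * tax)
      blob2 <- layout$center + xs["x2"] * g$pixel_scale * axis + t2_px * tax
      if (!in_rect_margin(blob2, layout$rects[[m]], margin_px)) next
      blob[[m]] <- layout$center + xs["x1"] * g$pixel_scale * axis +
        sum((p - layout$center) * tax) * tax
      if (!in_rect_margin(blob[[m]], layout$rects[[m]], margin_px)) next
    }
    return(structure(
      list(scenario = scenario, occupied = sort(occ), truth_center_px = p,
           b = b, blob_px = blob, frame2_blob_px = blob2,
           mirror = if (scenario == "one") occ else NULL,
           l = if (scenario == "one") l else NULL,
           photometry = photometry,
           noise_seed = sample.int(.Machine$integer.max, 1L)),
      class = "synthetic_scene"))
  }
  stop_config(sprintf(
    "could not sample a visible '%s' scene in %d tries; geometry too restrictive",
    scenario, max_tries))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene '%s'> truth (%.1f, %.1f) px, b = %.2f cm, regions: %s\n",
              x$scenario, x$truth_center_px[1], x$truth_center_px[2], x$b,
              paste(x$occupied, collapse = ", ")))
  invisible(x)
}

add_gaussian_blob <- function(m, pos, peak, sigma) {
  h <- nrow(m); w <- ncol(m)
  r <- ceiling(4 * sigma)
  c0 <- max(1L, floor(pos[1] - r)); c1 <- min(w, ceiling(pos[1] + r))
  r0 <- max(1L, floor(pos[2] - r)); r1 <- min(h, ceiling(pos[2] + r))
  if (c0 > c1 || r0 > r1) return(m)
  cc <- c0:c1; rr <- r0:r1
  d2 <- outer((rr - pos[2])^2, (cc - pos[1])^2, `+`)
  m[rr, cc] <- m[rr, cc] + peak * exp(-d2 / (2 * sigma^2))
  m
}

render_one_frame <- function(blob_px, layout, phot, frame_id) {
  m <- matrix(phot$background, layout$height, layout$width)
  for (pos in blob_px) m <- add_gaussian_blob(m, pos, phot$peak, phot$sigma_px)
  if (phot$noise_sigma > 0)
    m <- m + stats::rnorm(length(m), 0, phot$noise_sigma)
  m <- floor(m + 0.5)
  m[m < 0] <- 0
  m[m > 255] <- 255
  gray_frame(m, frame_id = frame_id)
}

#' Render the frame(s) of a synthetic scene
#'
#' Background offset plus isotropic Gaussian blobs at the scene's
#' per-region positions plus i.i.d. Gaussian sensor noise, clipped and
#' quantized to 8 bits. The single-mirror scenario yields two frames
#' (before and after the camera travel); all others yield one. Rendering
#' is reproducible: the scene's noise seed is applied locally and the
#' caller's RNG state restored.
#'
#' @param scene A [sample_scene()].
#' @param layout A [build_layout()] (must match the one used to sample).
#' @return List of one or two [gray_frame()]s.
#' @export
render_frames <- function(scene, layout = build_layout()) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!is.null(scene$noise_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(scene$noise_seed)
  }
  f1 <- render_one_frame(scene$blob_px, layout, scene$photometry, "frame1")
  if (scene$scenario != "one") return(list(f1))
  blobs2 <- list()
  blobs2[[scene$mirror]] <- scene$frame2_blob_px
  f2 <- render_one_frame(blobs2, layout, scene$photometry, "frame2")
  list(f1, f2)
}

default_benchmark_counts <- function() {
  c(central = 32L, four = 67L, three = 54L, two_nonopposite = 65L,
    two_opposite = 44L, one = 38L)
}

#' Generate a seeded benchmark of synthetic scenes
#'
#' Reproducible labeled dataset with the benchmark case mix of the
#' original 300-image evaluation: 32 central, 67 four-mirror, 54
#' three-mirror, 65 non-opposite two-mirror, 44 opposite two-mirror and 38
#' single-mirror scenes by default.
#'
#' @param counts Named integer vector of scenes per scenario (names as in
#'   [sample_scene()]); default the benchmark mix above.
#' @param seed Global RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#' @param layout,g,b_range,l,photometry,margin_px Passed to
#'   [sample_scene()].
#' @param out_dir Optional directory: frames are written as PNG and the
#'   manifest as `manifest.csv`.
#' @return An object of class `benchmark_set`: list with `scenes`,
#'   `manifest` (data.frame scene_id, scenario, truth_col, truth_row, b,
#'   frames), `counts`, `seed`.
#' @export
make_benchmark <- function(counts = default_benchmark_counts(), seed = 1L,
                           layout = build_layout(), g = rig_geometry(),
                           b_range = c(1, 10), l = 4,
                           photometry = scene_photometry(),
                           margin_px = 10, out_dir = NULL) {
  if (is.null(names(counts)) || !all(names(counts) %in% scenario_names()))
    stop_config("counts must be named by scenario")
  if (any(counts < 0)) stop_config("counts must be >= 0")
  set.seed(seed)
  scenes <- list()
  rows <- list()
  k <- 0L
  for (sc in names(counts)) {
    for (i in seq_len(counts[[sc]])) {
      k <- k + 1L
      scene <- sample_scene(sc, layout, g, b_range = b_range, l = l,
                            photometry = photometry, margin_px = margin_px)
      scene$scene_id <- sprintf("scene_%03d", k)
      scenes[[k]] <- scene
      rows[[k]] <- data.frame(
        scene_id = scene$scene_id, scenario = sc,
        truth_col = scene$truth_center_px[1],
        truth_row = scene$truth_center_px[2],
        b = scene$b,
        n_frames = if (sc == "one") 2L else 1L
      )
    }
  }
  manifest <- if (k) do.call(rbind, rows) else
    data.frame(scene_id = character(0), scenario = character(0),
               truth_col = numeric(0), truth_row = numeric(0),
               b = numeric(0), n_frames = integer(0))
  bench <- structure(
    list(scenes = scenes, manifest = manifest, counts = counts, seed = seed),
    class = "benchmark_set")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (scene in scenes) {
      frames <- render_frames(scene, layout)
      for (j in seq_along(frames))
        write_frame_png(frames[[j]],
                        file.path(out_dir, sprintf("%s_f%d.png",
                                                   scene$scene_id, j)))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  bench
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set> %d scenes (seed %d)\n",
              length(x$scenes), x$seed))
  print(x$counts)
  invisible(x)
}
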