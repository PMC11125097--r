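# Shared fixtures and independent oracles for the test suite.

# geometry with the worked-example parameters (c = 100, d = 10)
example_rig <- function(...) {
  rig_geometry(camera_height_cm = 100, mirror_offset_cm = 10, ...)
}

# independent hand convolution: k x k mean with edge replication and
# round-half-up, written as an explicit per-pixel double loop
oracle_smooth <- function(m, k = 3L) {
  h <- nrow(m); w <- ncol(m); r <- (k - 1L) %/% 2L
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1L), h)
      jj <- min(max(j + dj, 1L), w)
      acc <- acc + m[ii, jj]
    }
    out[i, j] <- as.integer(floor(acc / k^2 + 0.5))
  }
  out
}

# independent case classifier: a literal transcription of the rule
# system's IF-chain, keyed on the missing mirror / explicit sets rather
# than the package's definition table
oracle_case <- function(occ) {
  mirrors <- c("TL", "TR", "BL", "BR")
  occ_m <- intersect(occ, mirrors)
  if ("MC" %in% occ) return(1L)
  if (length(occ_m) == 4L) return(2L)
  if (length(occ_m) == 3L) {
    missing <- setdiff(mirrors, occ_m)
    return(c(BL = 3L, TR = 4L, BR = 5L, TL = 6L)[[missing]])
  }
  if (length(occ_m) == 2L) {
    key <- paste(sort(occ_m), collapse = "+")
    return(switch(key,
                  "BR+TR" = 7L, "BL+TL" = 8L, "TL+TR" = 9L, "BL+BR" = 10L,
                  "BL+TR" = 11L, "BR+TL" = 12L))
  }
  if (length(occ_m) == 1L)
    return(c(TL = 13L, BL = 14L, TR = 15L, BR = 16L)[[occ_m]])
  "NOT_FOUND"
}

# all 32 occupancy patterns of {MC, TL, TR, BL, BR}
all_occupancy_patterns <- function() {
  regions <- c("MC", "TL", "TR", "BL", "BR")
  lapply(0:31, function(k) regions[bitwAnd(k, 2^(0:4)) > 0])
}

# independent numeric root search for the mirror equations (pracma),
# solving the printed projections for (a, b) from observed coordinates
oracle_solve_opposite <- function(x, x1, g, start = c(0, 2)) {
  f <- function(p) {
    n <- (p[2] + g$d) * (g$c + g$d)
    c(n / (-p[1] + p[2] + g$c + 2 * g$d) - x,
      n / (p[2] - p[1] - g$c) - x1)
  }
  pracma::fsolve(f, start)$x
}

oracle_solve_single <- function(x1, x2, g, shift, start = c(0, 2)) {
  f <- function(p) {
    n <- (p[2] + g$d) * (g$c + g$d)
    c(n / (-p[1] + p[2] + g$c + 2 * g$d) - x1,
      n / (-(p[1] + shift) + p[2] + g$c + 2 * g$d) - x2)
  }
  pracma::fsolve(f, start)$x
}

# build a region_assignment directly from exact blob positions (bypassing
# rendering) so solver tests can check machine-precision round trips
assignment_from_points <- function(points, layout) {
  blobs <- do.call(rbind, lapply(names(points), function(nm) {
    p <- points[[nm]]
    data.frame(centroid_col = p[1], centroid_row = p[2], area = 100L,
               mean_intensity = 100, max_intensity = 200L,
               min_intensity = 5L,
               bbox_col0 = as.integer(floor(p[1])) - 5L,
               bbox_row0 = as.integer(floor(p[2])) - 5L,
               bbox_col1 = as.integer(ceiling(p[1])) + 5L,
               bbox_row1 = as.integer(ceiling(p[2])) + 5L)
  }))
  assign_blobs(blobs, layout)
}

# render a scene and run the full pipeline; returns localization + error
pipeline_error <- function(scene, layout, g, ...) {
  frames <- render_frames(scene, layout)
  res <- locate_frame(frames[[1]], layout, g,
                      frame2 = if (length(frames) > 1L) frames[[2]] else NULL,
                      l = scene$l, ...)
  err <- if (is.null(res$center) || res$status != "ok") Inf
         else sqrt(sum((res$center - scene$truth_center_px)^2))
  list(result = res, error_px = err)
}
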