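test_that("line intersection is exact and rejects parallels", {
  # symmetric diagonal cross
  l1 <- line_through(c(0, 0), c(100, 100))
  l2 <- line_through(c(100, 0), c(0, 100))
  expect_equal(intersect_lines(l1, l2), c(50, 50))
  # lines through the origin along y = x and y = -x
  expect_equal(intersect_lines(line_dir(c(5, 5), c(1, 1)),
                               line_dir(c(-3, 3), c(1, -1))),
               c(0, 0))
  expect_error(intersect_lines(line_dir(c(0, 0), c(1, 1)),
                               line_dir(c(5, 0), c(2, 2))),
               class = "fluorloc_parallel_lines")
  # substitute-back: intersection satisfies both line equations
  set.seed(71)
  for (i in 1:100) {
    p1 <- runif(2, -50, 50); d1 <- runif(2, -1, 1)
    p2 <- runif(2, -50, 50); d2 <- runif(2, -1, 1)
    cr <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(cr) < 1e-3) next
    pt <- intersect_lines(line_dir(p1, d1), line_dir(p2, d2))
    r1 <- (pt - p1); r2 <- (pt - p2)
    expect_lt(abs(r1[1] * d1[2] - r1[2] * d1[1]), 1e-9)
    expect_lt(abs(r2[1] * d2[2] - r2[2] * d2[1]), 1e-9)
  }
})

test_that("perpendicular-through follows the edge normal", {
  horiz <- list(p1 = c(0, 20), p2 = c(100, 20))
  pl <- perpendicular_through(c(10, 10), horiz)
  expect_equal(abs(pl$dir), c(0, 1))          # vertical line at col 10
  expect_equal(pl$p, c(10, 10))
  # point on the edge: perpendicular at the foot
  on_edge <- perpendicular_through(c(50, 20), horiz)
  expect_equal(on_edge$p, c(50, 20))
  # oblique edge along (1, 1): perpendicular direction (1, -1)
  ob <- list(p1 = c(0, 0), p2 = c(10, 10))
  pd <- perpendicular_through(c(0, 10), ob)
  expect_equal(abs(sum(pd$dir * c(1, 1) / sqrt(2))), 0, tolerance = 1e-12)
})

test_that("central-area blobs are extracted directly as the plant center", {
  lay <- build_layout()
  g <- rig_geometry()
  asg <- assignment_from_points(list(MC = c(512.0, 512.0)), lay)
  res <- locate_center(asg, lay, g)
  expect_equal(res$case_id, 1L)
  expect_equal(res$center, c(512, 512))
  expect_equal(res$status, "ok")
  # MC wins even when mirrors also contain blobs
  asg2 <- assignment_from_points(
    list(MC = c(500, 520), TL = c(150, 150), BR = c(900, 900)), lay)
  expect_equal(locate_center(asg2, lay, g)$case_id, 1L)
})

test_that("connection and perpendicular cases recover rendered truth within a pixel", {
  lay <- build_layout()
  g <- rig_geometry()
  phot <- scene_photometry(noise_sigma = 0)
  set.seed(72)
  for (sc in c("four", "three", "two_nonopposite")) {
    for (rep in 1:5) {
      scene <- sample_scene(sc, lay, g, photometry = phot)
      out <- pipeline_error(scene, lay, g)
      expect_lt(out$error_px, 1)
      expect_equal(out$result$scenario,
                   c(four = "b", three = "c", two_nonopposite = "e")[[sc]])
    }
  }
})

test_that("opposite-pair solver case recovers center and height", {
  lay <- build_layout()
  g <- rig_geometry()
  # exact observation (no rendering): solver output matches truth to 1e-6 cm
  set.seed(73)
  for (rep in 1:10) {
    scene <- sample_scene("two_opposite", lay, g,
                          photometry = scene_photometry(noise_sigma = 0))
    asg <- assignment_from_points(scene$blob_px, lay)
    res <- locate_center(asg, lay, g)
    expect_true(res$case_id %in% c(11L, 12L))
    expect_lt(sqrt(sum((res$center - scene$truth_center_px)^2)), 1e-6)
    expect_lt(abs(res$solver[["b"]] - scene$b), 1e-6)
    # rendered pipeline: within a pixel
    out <- pipeline_error(scene, lay, g)
    expect_lt(out$error_px, 1)
  }
})

test_that("single-mirror case needs a second frame and then solves by parallax", {
  lay <- build_layout()
  g <- rig_geometry()
  set.seed(74)
  scene <- sample_scene("one", lay, g,
                        photometry = scene_photometry(noise_sigma = 0))
  asg <- assignment_from_points(scene$blob_px, lay)
  # without the second frame: typed failure, no fabricated center
  res0 <- locate_center(asg, lay, g)
  expect_equal(res0$status, "missing_second_frame")
  expect_null(res0$center)
  # with exact observations: recover truth and height
  pts2 <- list(); pts2[[scene$mirror]] <- scene$frame2_blob_px
  asg2 <- assignment_from_points(pts2, lay)
  res <- locate_center(asg, lay, g, second_frame_assign = asg2, l = scene$l)
  expect_true(res$case_id %in% 13:16)
  expect_equal(res$status, "ok")
  expect_lt(sqrt(sum((res$center - scene$truth_center_px)^2)), 1e-6)
  expect_lt(abs(res$solver[["b"]] - scene$b), 1e-6)
  # rendered two-frame pipeline stays within the success radius noise-free
  out <- pipeline_error(scene, lay, g)
  expect_lt(out$error_px, 43.5)
})

test_that("no region occupancy yields NOT_FOUND without a center", {
  lay <- build_layout()
  g <- rig_geometry()
  empty <- assign_blobs(extract_blobs(matrix(FALSE, 16, 16),
                                      gray_frame(matrix(0L, 16, 16))), lay)
  res <- locate_center(empty, lay, g)
  expect_identical(res$case_id, "NOT_FOUND")
  expect_null(res$center)
  expect_equal(res$status, "not_found")
})

test_that("localization is equivariant under a 180-degree scene rotation", {
  # The connection/perpendicular constructions are rotation-symmetric for
  # any far-mirror variant; the opposing-pair and two-frame solvers are
  # equivariant under the symmetric variant (the as-printed far-mirror
  # projection is deliberately not the mirror image of the near-mirror
  # one, so the printed variant has no such symmetry).
  lay <- build_layout()
  phot <- scene_photometry(noise_sigma = 0)
  rot_pt <- function(p) c(lay$width + 1 - p[1], lay$height + 1 - p[2])
  rot_frame <- function(f) gray_frame(f$pixels[lay$height:1, lay$width:1])
  set.seed(75)
  g <- rig_geometry()
  for (sc in c("four", "three", "two_nonopposite")) {
    scene <- sample_scene(sc, lay, g, photometry = phot)
    fr <- render_frames(scene, lay)[[1]]
    res <- locate_frame(fr, lay, g)
    res_rot <- locate_frame(rot_frame(fr), lay, g)
    expect_equal(res_rot$status, "ok")
    expect_equal(res_rot$center, rot_pt(res$center), tolerance = 1e-6)
  }
  gs <- rig_geometry(eq4_variant = "symmetric")
  scene <- sample_scene("two_opposite", lay, gs, photometry = phot)
  fr <- render_frames(scene, lay)[[1]]
  res <- locate_frame(fr, lay, gs)
  res_rot <- locate_frame(rot_frame(fr), lay, gs)
  expect_equal(res_rot$status, "ok")
  expect_equal(res_rot$center, rot_pt(res$center), tolerance = 1e-6)
  # two-frame case: rotating the scene also reverses the camera travel
  scene1 <- sample_scene("one", lay, gs, photometry = phot)
  frs <- render_frames(scene1, lay)
  res <- locate_frame(frs[[1]], lay, gs, frame2 = frs[[2]], l = scene1$l)
  gs_rev <- rig_geometry(eq4_variant = "symmetric", travel_axis = c(-1, 0))
  res_rot <- locate_frame(rot_frame(frs[[1]]), lay, gs_rev,
                          frame2 = rot_frame(frs[[2]]), l = scene1$l)
  expect_equal(res_rot$status, "ok")
  expect_equal(res_rot$center, rot_pt(res$center), tolerance = 1e-6)
})

test_that("redundant views agree: direct extraction vs mirror connections", {
  lay <- build_layout()
  g <- rig_geometry()
  phot <- scene_photometry(noise_sigma = 0)
  set.seed(76)
  for (rep in 1:5) {
    scene <- sample_scene("four", lay, g, photometry = phot)
    scene$blob_px$MC <- scene$truth_center_px   # plant also visible directly
    frames <- render_frames(scene, lay)
    sm <- smooth_frame(frames[[1]])
    asg <- assign_blobs(extract_blobs(segment_frame(sm, 4), sm, 20L), lay)
    res_direct <- locate_center(asg, lay, g)
    expect_equal(res_direct$case_id, 1L)
    # drop the MC blob and relocalize through the mirrors alone
    asg_mirrors <- asg
    asg_mirrors$blobs <- asg$blobs[asg$blobs$region != "MC", ]
    asg_mirrors$occupied <- setdiff(asg$occupied, "MC")
    asg_mirrors$primary$MC <- NULL
    res_mirror <- locate_center(asg_mirrors, lay, g)
    expect_equal(res_mirror$case_id, 2L)
    expect_lt(sqrt(sum((res_direct$center - res_mirror$center)^2)), 2)
  }
})

test_that("off-frame intersections are flagged, not clipped", {
  lay <- build_layout()
  g <- rig_geometry()
  # fabricated opposite-pair observation whose solved lateral position
  # lies beyond the frame edge
  asg <- assignment_from_points(list(TL = c(150, 150), BR = c(900, 900)), lay)
  res <- locate_center(asg, lay, g)
  expect_equal(res$case_id, 12L)
  expect_equal(res$status, "out_of_frame")
  expect_false(is.null(res$center))
})
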