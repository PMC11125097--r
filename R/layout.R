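#' @keywords internal
# Canonical mirror bookkeeping. Axis vectors are unit (col, row) directions
# from the frame center toward each mirror corner; the along-edge direction
# is the axis rotated by 90 degrees ((-y, x)). Opposing pairs are TL-BR and
# TR-BL; within a pair the positive-axis mirror carries the near-mirror
# projection and the other mirror the opposing-mirror projection.
mirror_table <- function() {
  s2 <- 1 / sqrt(2)
  list(
    TL = list(axis = c(-s2, -s2), edge = c(s2, -s2)),
    TR = list(axis = c(s2, -s2),  edge = c(s2, s2)),
    BL = list(axis = c(-s2, s2),  edge = c(-s2, -s2)),
    BR = list(axis = c(s2, s2),   edge = c(-s2, s2))
  )
}

mirror_names <- function() c("TL", "TR", "BL", "BR")

# pair id -> c(primary (positive axis side), secondary)
pair_table <- function() list(
  pair_TLBR = c(primary = "BR", secondary = "TL"),
  pair_TRBL = c(primary = "TR", secondary = "BL")
)

pair_of_mirror <- function(m) {
  if (m %in% c("TL", "BR")) "pair_TLBR" else "pair_TRBL"
}

opposite_mirror <- function(m) {
  c(TL = "BR", BR = "TL", TR = "BL", BL = "TR")[[m]]
}

#' Build the six-region frame layout
#'
#' Partitions a frame into the central crop area (MC), four mirror areas
#' (TL, TR, BL, BR) and the background (BG). The default layout is a
#' centered MC rectangle spanning the middle `mc_fraction` of each
#' dimension, corner rectangles of side `mirror_fraction` for the mirror
#' areas, and the remainder as BG. The mirror edge of each corner area is
#' the 45-degree segment across its inner corner, oriented with the inward
#' normal (the mirror's axis direction reversed) pointing toward the frame
#' center; the normal is what the perpendicular constructions of the
#' localization rules use.
#'
#' @param width,height Frame dimensions in pixels.
#' @param mc_fraction Fraction of each dimension covered by MC (default
#'   0.4, i.e. the central 40 percent).
#' @param mirror_fraction Fraction of each dimension covered by each corner
#'   mirror area (default 0.3). Must not overlap MC:
#'   `mirror_fraction <= (1 - mc_fraction) / 2`.
#' @return An object of class `region_layout`.
#' @export
build_layout <- function(width = 1024L, height = 1024L,
                         mc_fraction = 0.4, mirror_fraction = 0.3) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 8L || height < 8L) stop_layout("frame too small for a layout")
  if (mc_fraction <= 0 || mc_fraction >= 1)
    stop_layout("mc_fraction must lie in (0, 1)")
  if (mirror_fraction <= 0)
    stop_layout("mirror_fraction must be positive")
  if (mirror_fraction > (1 - mc_fraction) / 2 + 1e-12)
    stop_layout("mirror areas would overlap MC: mirror_fraction too large")
  lo <- (1 - mc_fraction) / 2
  hi <- 1 - lo
  # region rectangles as (col0, col1, row0, row1) in continuous pixel coords
  mc <- c(lo * width, hi * width, lo * height, hi * height)
  mw <- mirror_fraction * width; mh <- mirror_fraction * height
  rects <- list(
    MC = mc,
    TL = c(0, mw, 0, mh),
    TR = c(width - mw, width, 0, mh),
    BL = c(0, mw, height - mh, height),
    BR = c(width - mw, width, height - mh, height)
  )
  if (mc[1] >= mc[2] || mc[3] >= mc[4])
    stop_layout("degenerate MC rectangle")
  mt <- mirror_table()
  edges <- list(
    TL = list(p1 = c(0, mh), p2 = c(mw, 0)),
    TR = list(p1 = c(width - mw, 0), p2 = c(width, mh)),
    BL = list(p1 = c(0, height - mh), p2 = c(mw, height)),
    BR = list(p1 = c(width - mw, height), p2 = c(width, height - mh))
  )
  for (m in mirror_names()) edges[[m]]$normal <- -mt[[m]]$axis
  structure(
    list(width = width, height = height, rects = rects, edges = edges,
         center = c((width + 1) / 2, (height + 1) / 2),
         pairs = pair_table()),
    class = "region_layout"
  )
}

stop_layout <- function(msg) {
  stop(structure(class = c("fluorloc_layout_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @export
print.region_layout <- function(x, ...) {
  cat(sprintf("<region_layout> %d x %d px\n", x$width, x$height))
  for (nm in names(x$rects)) {
    r <- x$rects[[nm]]
    cat(sprintf("  %s: cols [%.1f, %.1f], rows [%.1f, %.1f]\n",
                nm, r[1], r[2], r[3], r[4]))
  }
  cat("  BG: remainder\n")
  invisible(x)
}

in_rect <- function(p, r) {
  p[1] >= r[1] && p[1] <= r[2] && p[2] >= r[3] && p[2] <= r[4]
}

#' Region containing a point
#'
#' Boundary points are resolved by first match in the fixed order MC, TL,
#' TR, BL, BR; anything else is BG.
#'
#' @param p Point `(col, row)` in pixel coordinates.
#' @param layout A [build_layout()].
#' @return Region label string.
#' @export
region_of_point <- function(p, layout) {
  for (nm in c("MC", "TL", "TR", "BL", "BR"))
    if (in_rect(p, layout$rects[[nm]])) return(nm)
  "BG"
}

#' Region areas of the layout tiling
#'
#' @param layout A [build_layout()].
#' @return Named vector of polygon areas in px^2 (BG by complement); the
#'   six areas sum to `width * height`.
#' @export
layout_areas <- function(layout) {
  a <- vapply(layout$rects, function(r) (r[2] - r[1]) * (r[4] - r[3]),
              numeric(1))
  c(a, BG = layout$width * layout$height - sum(a))
}

#' Assign blobs to layout regions
#'
#' Each blob is assigned by its centroid through [region_of_point()]; every
#' blob lands in exactly one region. The largest blob per region is the
#' region's primary blob (ties resolved by the blob-table order). BG blobs
#' are recorded but never used for localization.
#'
#' @param blobs Blob data.frame from [extract_blobs()].
#' @param layout A [build_layout()].
#' @return An object of class `region_assignment`: list with `blobs` (the
#'   table plus a `region` column), `occupied` (sorted labels of non-BG
#'   regions containing at least one blob), and `primary` (named list of
#'   one-row blob data.frames).
#' @export
assign_blobs <- function(blobs, layout) {
  region <- character(nrow(blobs))
  for (i in seq_len(nrow(blobs)))
    region[i] <- region_of_point(
      c(blobs$centroid_col[i], blobs$centroid_row[i]), layout)
  blobs$region <- region
  informative <- setdiff(unique(region), "BG")
  primary <- list()
  for (nm in informative) {
    rows <- blobs[blobs$region == nm, , drop = FALSE]
    primary[[nm]] <- rows[which.max(rows$area), , drop = FALSE]
  }
  structure(
    list(blobs = blobs,
         occupied = sort(informative),
         primary = primary),
    class = "region_assignment"
  )
}

#' @export
print.region_assignment <- function(x, ...) {
  cat("<region_assignment>", nrow(x$blobs), "blob(s); occupied:",
      if (length(x$occupied)) paste(x$occupied, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

case_definitions <- function() {
  list(
    `2`  = c("BL", "BR", "TL", "TR"),
    `3`  = c("BR", "TL", "TR"),
    `4`  = c("BL", "BR", "TL"),
    `5`  = c("BL", "TL", "TR"),
    `6`  = c("BL", "BR", "TR"),
    `7`  = c("BR", "TR"),
    `8`  = c("BL", "TL"),
    `9`  = c("TL", "TR"),
    `10` = c("BL", "BR"),
    `11` = c("BL", "TR"),
    `12` = c("BR", "TL"),
    `13` = "TL",
    `14` = "BL",
    `15` = "TR",
    `16` = "BR"
  )
}

scenario_of_case <- function(case_id) {
  if (identical(case_id, "NOT_FOUND")) return("g")
  switch(as.character(case_id),
         `1` = "a", `2` = "b",
         `3` = , `4` = , `5` = , `6` = "c",
         `7` = , `8` = , `9` = , `10` = "e",
         `11` = , `12` = "d",
         `13` = , `14` = , `15` = , `16` = "f")
}

#' Classify the occlusion case from region occupancy
#'
#' Pure function of the set of informative (non-BG) regions containing at
#' least one blob: any occupancy that includes MC is Case 1; otherwise the
#' mirror-occupancy pattern selects Cases 2-16 per the rule system (all
#' four mirrors; the four three-mirror sets keyed by which opposing pair is
#' complete; the four adjacent two-mirror sets; the two opposing pairs; the
#' four single mirrors); the empty set is NOT_FOUND.
#'
#' @param x A `region_assignment`, or a character vector of occupied
#'   region labels.
#' @return List with `case_id` (integer 1-16 or `"NOT_FOUND"`) and
#'   `scenario` (letter a-g).
#' @export
classify_case <- function(x) {
  occ <- if (inherits(x, "region_assignment")) x$occupied
         else sort(unique(as.character(x)))
  occ <- setdiff(occ, "BG")
  bad <- setdiff(occ, c("MC", mirror_names()))
  if (length(bad))
    stop_config(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")))
  if ("MC" %in% occ)
    return(list(case_id = 1L, scenario = "a"))
  mirrors <- sort(intersect(occ, mirror_names()))
  if (!length(mirrors))
    return(list(case_id = "NOT_FOUND", scenario = "g"))
  defs <- case_definitions()
  for (id in names(defs)) {
    if (identical(defs[[id]], mirrors)) {
      cid <- as.integer(id)
      return(list(case_id = cid, scenario = scenario_of_case(cid)))
    }
  }
  stop("internal error: unmatched occupancy pattern")  # unreachable: defs cover all subsets
}

#' Render a labeled overlay of the region layout
#'
#' Writes a PNG with the region rectangles and mirror edges drawn over a
#' frame (or a blank canvas) for visual verification.
#'
#' @param layout A [build_layout()].
#' @param path Output PNG path.
#' @param frame Optional [gray_frame()] backdrop.
#' @return `path`, invisibly.
#' @export
render_layout_png <- function(layout, path, frame = NULL) {
  h <- layout$height; w <- layout$width
  base <- if (is.null(frame)) matrix(0, h, w) else frame$pixels / 255
  arr <- array(rep(base, 3L), dim = c(h, w, 3L))
  paint_seg <- function(arr, p1, p2, channel) {
    n <- max(2L, ceiling(max(abs(p2 - p1))) * 2L)
    t <- seq(0, 1, length.out = n)
    cc <- pmin(pmax(round(p1[1] + t * (p2[1] - p1[1])), 1L), w)
    rr <- pmin(pmax(round(p1[2] + t * (p2[2] - p1[2])), 1L), h)
    arr[cbind(rr, cc, channel)] <- 1
    arr
  }
  for (nm in c("MC", mirror_names())) {
    r <- layout$rects[[nm]]
    cr <- pmin(pmax(r, 1), c(w, w, h, h))
    corners <- list(c(cr[1], cr[3]), c(cr[2], cr[3]), c(cr[2], cr[4]),
                    c(cr[1], cr[4]))
    ch <- if (nm == "MC") 2L else 3L
    for (k in 1:4)
      arr <- paint_seg(arr, corners[[k]], corners[[k %% 4 + 1]], ch)
  }
  for (m in mirror_names())
    arr <- paint_seg(arr, layout$edges[[m]]$p1, layout$edges[[m]]$p2, 1L)
  png::writePNG(arr, target = path)
  invisible(path)
}
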