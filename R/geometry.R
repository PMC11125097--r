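#' Rig geometry of the five-view imaging chamber
#'
#' Bundles the world-unit parameters shared by the mirror-geometry solvers
#' and the synthetic renderer: camera height `c`, mirror offset `d` (distance
#' from the bottom edge of a mirror to the chamber center in the reference
#' plane), mirror angle `theta` (angle between the mirror edge and the
#' direction of travel), the pixel scale, and the in-plane travel direction
#' of the camera.
#'
#' All solver math runs in world units (centimeters); pixel coordinates are
#' converted at module boundaries through `pixel_scale`.
#'
#' @param camera_height_cm Camera height above the reference plane (cm).
#' @param mirror_offset_cm Distance from the mirror bottom edge to the
#'   chamber center in the reference plane (cm).
#' @param mirror_angle_deg Angle between the mirror edge and the direction
#'   of travel, degrees in (0, 180).
#' @param pixel_scale Pixels per centimeter in the reference plane. The
#'   default 87 px/cm makes 0.5 cm equal the 43.5 px success radius.
#' @param travel_axis Unit direction of camera motion in the image plane,
#'   `(col, row)` components. Normalized internally.
#' @param eq4_variant `"printed"` uses the opposite-mirror projection with
#'   denominator `b - a - c` exactly as published; `"symmetric"` uses the
#'   mirror image of the near-mirror equation (denominator `a + b + c + 2d`,
#'   negated coordinate). The solvers invert whichever variant is selected.
#' @param parallax_epsilon Minimum coordinate separation (world units) below
#'   which an observation pair is rejected as degenerate.
#' @return An object of class `rig_geometry`.
#' @examples
#' g <- rig_geometry()
#' forward_single_view(a = 5, b = 3, g = rig_geometry(100, 10))
#' @export
rig_geometry <- function(camera_height_cm = 75,
                         mirror_offset_cm = 4,
                         mirror_angle_deg = 45,
                         pixel_scale = 87,
                         travel_axis = c(1, 0),
                         eq4_variant = c("printed", "symmetric"),
                         parallax_epsilon = 1e-6) {
  eq4_variant <- match.arg(eq4_variant)
  stopifnot(
    is.numeric(camera_height_cm), length(camera_height_cm) == 1L,
    is.numeric(mirror_offset_cm), length(mirror_offset_cm) == 1L,
    is.numeric(mirror_angle_deg), length(mirror_angle_deg) == 1L,
    is.numeric(pixel_scale), length(pixel_scale) == 1L,
    is.numeric(travel_axis), length(travel_axis) == 2L,
    is.numeric(parallax_epsilon), parallax_epsilon > 0
  )
  if (camera_height_cm <= 0) stop_config("camera_height_cm must be > 0")
  if (mirror_offset_cm <= 0) stop_config("mirror_offset_cm must be > 0")
  if (mirror_angle_deg <= 0 || mirror_angle_deg >= 180)
    stop_config("mirror_angle_deg must lie strictly between 0 and 180")
  if (pixel_scale <= 0) stop_config("pixel_scale must be > 0")
  nrm <- sqrt(sum(travel_axis^2))
  if (nrm == 0) stop_config("travel_axis must be a nonzero vector")
  structure(
    list(
      c = camera_height_cm,
      d = mirror_offset_cm,
      theta_deg = mirror_angle_deg,
      pixel_scale = pixel_scale,
      travel_axis = travel_axis / nrm,
      eq4_variant = eq4_variant,
      parallax_epsilon = parallax_epsilon
    ),
    class = "rig_geometry"
  )
}

#' @export
print.rig_geometry <- function(x, ...) {
  cat("<rig_geometry>\n")
  cat(sprintf("  camera height c    : %g cm\n", x$c))
  cat(sprintf("  mirror offset d    : %g cm\n", x$d))
  cat(sprintf("  mirror angle theta : %g deg\n", x$theta_deg))
  cat(sprintf("  pixel scale        : %g px/cm\n", x$pixel_scale))
  cat(sprintf("  travel axis        : (%.3f, %.3f)\n",
              x$travel_axis[1], x$travel_axis[2]))
  cat(sprintf("  far-mirror variant : %s\n", x$eq4_variant))
  invisible(x)
}

# condition helpers -----------------------------------------------------

stop_config <- function(msg) {
  stop(structure(class = c("fluorloc_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_singular <- function(msg) {
  stop(structure(class = c("fluorloc_singular_geometry", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("fluorloc_degenerate_observation", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# shared numerator (b + d)(c + d) = bc + dc + bd + d^2
geom_numerator <- function(b, g) (b + g$d) * (g$c + g$d)

#' Project a fluorescence point into its near-mirror view coordinate
#'
#' Forward model of a single inclined mirror: a fluorescence source at
#' signed lateral position `a` (measured from the chamber center along the
#' mirror axis, positive toward the mirror) and height `b` above the
#' reference plane images at mirror-view coordinate
#' `x = (b + d)(c + d) / (b - a + c + 2d)`, in world units along the same
#' axis.
#'
#' @param a Signed lateral position of the fluorescence (cm).
#' @param b Height of the fluorescence above the reference plane (cm).
#' @param g A [rig_geometry()].
#' @return Mirror-view coordinate `x` (cm).
#' @export
forward_single_view <- function(a, b, g) {
  den <- -a + b + g$c + 2 * g$d
  if (abs(den) < g$parallax_epsilon)
    stop_singular("singular geometry: -a + b + c + 2d is zero")
  geom_numerator(b, g) / den
}

#' Project a fluorescence point into both mirrors of an opposing pair
#'
#' Returns the pair `(x, x1)` of mirror-view coordinates along the pair
#' axis: `x` in the mirror on the positive side of the axis and `x1` in the
#' opposing mirror. The positive-side projection is
#' `x = (b+d)(c+d)/(b - a + c + 2d)`; the opposing-side projection is, in
#' the `"printed"` variant, `x1 = (b+d)(c+d)/(b - a - c)` and, in the
#' `"symmetric"` variant, `x1 = -(b+d)(c+d)/(a + b + c + 2d)`. The
#' synthetic renderer and [solve_opposite()] share this convention, so the
#' pipeline is self-consistent under either variant.
#'
#' @inheritParams forward_single_view
#' @return Named numeric vector `c(x = , x1 = )` (cm).
#' @export
forward_opposite_pair <- function(a, b, g) {
  x <- forward_single_view(a, b, g)
  if (g$eq4_variant == "printed") {
    den1 <- b - a - g$c
    if (abs(den1) < g$parallax_epsilon)
      stop_singular("singular geometry: b - a - c is zero")
    x1 <- geom_numerator(b, g) / den1
  } else {
    den1 <- a + b + g$c + 2 * g$d
    if (abs(den1) < g$parallax_epsilon)
      stop_singular("singular geometry: a + b + c + 2d is zero")
    x1 <- -geom_numerator(b, g) / den1
  }
  c(x = unname(x), x1 = unname(x1))
}

#' Recover the fluorescence point from an opposing-mirror observation
#'
#' Closed-form inverse of [forward_opposite_pair()]. With
#' `N = (b+d)(c+d)`, the printed-variant projections give
#' `N/x - N/x1 = 2(c + d)`, hence `b = 2 x x1 / (x1 - x) - d` and
#' `a = b + c + 2d - N/x`. The symmetric variant gives
#' `N (1/x - 1/x1) = 2(b + d) + 2(c + d)` and is solved for `b + d`
#' accordingly.
#'
#' @param x Mirror-view coordinate in the positive-side mirror (cm).
#' @param x1 Mirror-view coordinate in the opposing mirror (cm).
#' @param g A [rig_geometry()].
#' @return Named numeric vector `c(a = , b = )` (cm).
#' @export
solve_opposite <- function(x, x1, g) {
  if (!is.finite(x) || !is.finite(x1))
    stop_degenerate("opposite-mirror observation must be finite")
  if (abs(x1 - x) < g$parallax_epsilon)
    stop_degenerate("opposite-mirror observation degenerate: x equals x1")
  if (x == 0 || x1 == 0)
    stop_degenerate("opposite-mirror observation degenerate: zero coordinate")
  if (g$eq4_variant == "printed") {
    b <- 2 * x * x1 / (x1 - x) - g$d
  } else {
    cd <- g$c + g$d
    s <- 1 / x - 1 / x1
    den <- cd * s - 2
    if (abs(den) < g$parallax_epsilon)
      stop_degenerate("opposite-mirror observation degenerate for symmetric variant")
    b <- 2 * cd / den - g$d
  }
  n <- geom_numerator(b, g)
  a <- b + g$c + 2 * g$d - n / x
  c(a = unname(a), b = unname(b))
}

#' Project a static fluorescence point into one mirror over two frames
#'
#' Forward model of the two-frame single-mirror observation: the camera
#' advances by `l` between frames, shifting the plant's axis coordinate by
#' `signed_shift` (by default `l * sin(theta)`, the published relation for a
#' mirror behind the travel direction), so
#' `x1 = N / (b - a1 + c + 2d)` and `x2 = N / (b - a2 + c + 2d)` with
#' `a2 = a1 + signed_shift` and `N = (b+d)(c+d)`.
#'
#' @param a1 Signed lateral position of the fluorescence at frame 1 (cm).
#' @param b Height of the fluorescence (cm).
#' @param g A [rig_geometry()].
#' @param l Camera travel between the frames (cm), `> 0`.
#' @param signed_shift Signed axis shift of the plant between frames (cm);
#'   defaults to `l * sin(theta)`. Use [travel_shift()] to orient the sign
#'   for a specific mirror.
#' @return Named numeric vector `c(x1 = , x2 = )` (cm).
#' @export
forward_two_frames <- function(a1, b, g, l,
                               signed_shift = l * sin(g$theta_deg * pi / 180)) {
  if (l < 0) stop_config("frame travel l must be >= 0")
  a2 <- a1 + signed_shift
  c(x1 = unname(forward_single_view(a1, b, g)),
    x2 = unname(forward_single_view(a2, b, g)))
}

#' Recover the fluorescence point from a two-frame single-mirror observation
#'
#' Closed-form inverse of [forward_two_frames()]. With `N = (b+d)(c+d)` and
#' shift `s = a2 - a1`, subtracting the two projections gives
#' `N/x1 - N/x2 = -s`, hence `N = s * x1 * x2 / (x2 - x1)`, then
#' `b = N/(c + d) - d` and `a1 = b + c + 2d - N/x1`.
#'
#' @param x1,x2 Mirror-view coordinates at frames 1 and 2 (cm).
#' @param g A [rig_geometry()].
#' @param l Camera travel between frames (cm), `> 0`.
#' @param signed_shift Signed axis shift of the plant between frames (cm);
#'   defaults to `l * sin(theta)`.
#' @return Named numeric vector `c(a = , b = )`, where `a` is the frame-1
#'   lateral position (cm).
#' @export
solve_single_mirror <- function(x1, x2, g, l,
                                signed_shift = l * sin(g$theta_deg * pi / 180)) {
  if (l <= 0) stop_config("frame travel l must be > 0")
  if (abs(sin(g$theta_deg * pi / 180)) < g$parallax_epsilon)
    stop_config("mirror angle has sin(theta) = 0: no cross-frame parallax")
  if (!is.finite(x1) || !is.finite(x2))
    stop_degenerate("two-frame observation must be finite")
  if (abs(x2 - x1) < g$parallax_epsilon)
    stop_degenerate("two-frame observation degenerate: insufficient parallax")
  if (x1 == 0 || x2 == 0)
    stop_degenerate("two-frame observation degenerate: zero coordinate")
  n <- signed_shift * x1 * x2 / (x2 - x1)
  b <- n / (g$c + g$d) - g$d
  a <- b + g$c + 2 * g$d - n / x1
  c(a = unname(a), b = unname(b))
}

#' Convert between pixel and world coordinates
#'
#' Linear scaling about a configured origin: `world = (px - origin) /
#' pixel_scale` and `px = origin + world * pixel_scale`. Applied
#' component-wise, so it converts points (length-2 vectors, `(col, row)`)
#' and scalar lengths (with the default zero origin) alike. The two
#' directions are exact inverses.
#'
#' @param point Numeric vector (a point or a length).
#' @param g A [rig_geometry()].
#' @param direction `"px_to_world"` or `"world_to_px"`.
#' @param origin Pixel-coordinate origin of the world frame (same length as
#'   `point` or scalar); default 0.
#' @return Converted numeric vector.
#' @examples
#' convert_coords(0.5, rig_geometry(), "world_to_px")  # 43.5 px
#' @export
convert_coords <- function(point, g,
                           direction = c("px_to_world", "world_to_px"),
                           origin = 0) {
  direction <- match.arg(direction)
  if (direction == "px_to_world") (point - origin) / g$pixel_scale
  else origin + point * g$pixel_scale
}

#' Read rig geometry (and optional pipeline settings) from a config file
#'
#' Accepts YAML or JSON with keys `camera_height_cm`, `mirror_offset_cm`,
#' `mirror_angle_deg`, `pixel_scale_px_per_cm`, `travel_axis`,
#' `eq4_variant`, `parallax_epsilon`; missing keys fall back to the
#' [rig_geometry()] defaults. Unknown keys are ignored so one file can also
#' hold layout and pipeline settings (see [build_layout()]).
#'
#' @param path Path to a YAML or JSON file.
#' @return A list with elements `geometry` (a `rig_geometry`) and `config`
#'   (the full parsed list).
#' @export
read_rig_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_config("config file must parse to a mapping")
  defaults <- formals(rig_geometry)
  g <- rig_geometry(
    camera_height_cm = cfg$camera_height_cm %||% eval(defaults$camera_height_cm),
    mirror_offset_cm = cfg$mirror_offset_cm %||% eval(defaults$mirror_offset_cm),
    mirror_angle_deg = cfg$mirror_angle_deg %||% eval(defaults$mirror_angle_deg),
    pixel_scale = cfg$pixel_scale_px_per_cm %||% eval(defaults$pixel_scale),
    travel_axis = as.numeric(cfg$travel_axis %||% eval(defaults$travel_axis)),
    eq4_variant = cfg$eq4_variant %||% "printed",
    parallax_epsilon = cfg$parallax_epsilon %||% eval(defaults$parallax_epsilon)
  )
  list(geometry = g, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
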