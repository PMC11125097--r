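#' Construct an 8-bit grayscale frame
#'
#' A frame is an integer matrix of intensities in `[0, 255]`, stored
#' `[row, col]` with the origin at the top-left pixel. Continuous pixel
#' coordinates throughout the package are `(col, row)` with pixel centers
#' at integer positions (pixel `[i, j]` has center `(j, i)`).
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @param frame_id Identifier string.
#' @return An object of class `gray_frame` with fields `pixels` (integer
#'   matrix), `width`, `height`, `frame_id`.
#' @export
gray_frame <- function(pixels, frame_id = "frame") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_config("pixels must be a non-empty matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_config("pixel intensities must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
         frame_id = as.character(frame_id)),
    class = "gray_frame"
  )
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame '%s'> %d x %d px, intensity range [%d, %d]\n",
              x$frame_id, x$width, x$height, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an 8-bit single-channel PNG or TIFF frame
#'
#' Multi-channel images are rejected: the acquisition model is a monochrome
#' camera behind a bandpass filter, so any color payload indicates the
#' wrong input.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param frame_id Identifier; defaults to the file name.
#' @return A [gray_frame()].
#' @export
read_frame <- function(path, frame_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_config(sprintf("unsupported image format '%s' (need PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop_config(sprintf(
        "multi-channel image (%d channels): fluorescence frames must be single-channel",
        dim(img)[3]))
    img <- img[, , 1L]
  }
  gray_frame(round(img * 255), frame_id = frame_id)
}

#' Write a frame (or binary mask) as an 8-bit grayscale PNG
#'
#' @param x A [gray_frame()] or a logical mask matrix (written as 0/255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(x, path) {
  m <- if (inherits(x, "gray_frame")) x$pixels else {
    if (!is.logical(x)) stop_config("x must be a gray_frame or logical mask")
    255L * (x * 1L)
  }
  png::writePNG(m / 255, target = path)
  invisible(path)
}

#' Smooth a frame with a uniform mean filter
#'
#' Box-mean smoothing with edge replication, re-quantized to 8 bits with
#' round-half-up. The default 3x3 kernel mirrors the smoothing step used on
#' the original rig imagery; `kernel` must be odd.
#'
#' @param f A [gray_frame()].
#' @param kernel Odd kernel side length (default 3).
#' @return A smoothed [gray_frame()] of identical dimensions.
#' @export
smooth_frame <- function(f, kernel = 3L) {
  stopifnot(inherits(f, "gray_frame"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop_config("kernel must be a positive odd integer")
  if (kernel == 1L) return(f)
  h <- f$height; w <- f$width; r <- (kernel - 1L) %/% 2L
  pad <- matrix(0, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- f$pixels
  for (k in seq_len(r)) {           # replicate edges outward
    pad[r + 1L - k, ] <- pad[r + 1L, ]
    pad[r + h + k, ] <- pad[r + h, ]
  }
  for (k in seq_len(r)) {
    pad[, r + 1L - k] <- pad[, r + 1L]
    pad[, r + w + k] <- pad[, r + w]
  }
  acc <- matrix(0, h, w)
  for (dr in 0:(kernel - 1L)) for (dc in 0:(kernel - 1L))
    acc <- acc + pad[(1L + dr):(h + dr), (1L + dc):(w + dc)]
  gray_frame(floor(acc / kernel^2 + 0.5), frame_id = f$frame_id)
}

#' Global threshold segmentation
#'
#' Foreground is every pixel with intensity strictly greater than the
#' threshold. The default threshold of 4 equals the measured background
#' ceiling of the unmarked control imagery, so background at or below that
#' ceiling is excluded.
#'
#' @param f A [gray_frame()].
#' @param threshold Intensity threshold in `[0, 255]` (default 4).
#' @return Logical matrix of the same dimensions.
#' @export
segment_frame <- function(f, threshold = 4) {
  stopifnot(inherits(f, "gray_frame"))
  if (threshold < 0 || threshold > 255)
    stop_config("threshold must lie in [0, 255]")
  f$pixels > threshold
}

# Exact 8-connected labeling: EBImage::bwlabel is 4-connected, so labels
# that touch only diagonally are merged through the label adjacency graph.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]     # diagonal (+1, +1)
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]     # diagonal (+1, -1)
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0L) return(lab)
  gr <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, nlab - igraph::vcount(gr)))
  memb <- igraph::components(gr)$membership
  relab <- lab
  relab[lab > 0] <- memb[lab[lab > 0]]
  relab
}

#' Extract fluorescence blobs from a segmentation mask
#'
#' Finds 8-connected foreground components with at least `min_area` pixels
#' and summarizes each as a blob with an intensity-weighted sub-pixel
#' centroid and photometry. The minimum area separates genuine
#' fluorescence signals (hundreds of pixels under the default photometry)
#' from suprathreshold sensor-noise clusters, which stay below roughly ten
#' pixels after smoothing at the default noise level.
#'
#' @param mask Logical matrix from [segment_frame()].
#' @param f The [gray_frame()] the mask was computed from (used for
#'   intensity weighting; typically the smoothed frame).
#' @param min_area Minimum component area in pixels (default 20).
#' @return A data.frame with one row per blob, sorted by decreasing area
#'   (ties by bounding-box top-left, row then column): columns
#'   `centroid_col`, `centroid_row`, `area`, `mean_intensity`,
#'   `max_intensity`, `min_intensity`, `bbox_col0`, `bbox_row0`,
#'   `bbox_col1`, `bbox_row1`.
#' @export
extract_blobs <- function(mask, f, min_area = 20L) {
  stopifnot(inherits(f, "gray_frame"))
  if (!is.logical(mask) || !identical(dim(mask), dim(f$pixels)))
    stop_config("mask must be a logical matrix congruent with the frame")
  empty <- data.frame(
    centroid_col = numeric(0), centroid_row = numeric(0), area = integer(0),
    mean_intensity = numeric(0), max_intensity = integer(0),
    min_intensity = integer(0), bbox_col0 = integer(0), bbox_row0 = integer(0),
    bbox_col1 = integer(0), bbox_row1 = integer(0)
  )
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  idx <- which(lab > 0)
  comp <- lab[idx]
  area <- tabulate(comp)
  keep <- which(area >= min_area)
  if (!length(keep)) return(empty)
  sel <- comp %in% keep
  idx <- idx[sel]; comp <- comp[sel]
  h <- f$height
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  inten <- as.numeric(f$pixels[idx])
  # per-component stats over contiguous slices of the comp-sorted pixels
  ord <- order(comp)
  co <- comp[ord]; ro <- rows[ord]; cl <- cols[ord]; io <- inten[ord]
  brk <- c(0L, which(co[-1L] != co[-length(co)]), length(co))
  ng <- length(brk) - 1L
  agg <- matrix(0, ng, 10L)
  for (k in seq_len(ng)) {
    i <- (brk[k] + 1L):brk[k + 1L]
    r <- ro[i]; cc <- cl[i]; v <- io[i]
    sv <- sum(v)
    agg[k, ] <- c(sum(v * cc) / sv, sum(v * r) / sv, length(i),
                  sv / length(i), max(v), min(v),
                  min(cc), min(r), max(cc), max(r))
  }
  stats <- data.frame(
    centroid_col = agg[, 1], centroid_row = agg[, 2],
    area = as.integer(agg[, 3]), mean_intensity = agg[, 4],
    max_intensity = as.integer(agg[, 5]), min_intensity = as.integer(agg[, 6]),
    bbox_col0 = as.integer(agg[, 7]), bbox_row0 = as.integer(agg[, 8]),
    bbox_col1 = as.integer(agg[, 9]), bbox_row1 = as.integer(agg[, 10])
  )
  ord <- order(-stats$area, stats$bbox_row0, stats$bbox_col0)
  stats <- stats[ord, , drop = FALSE]
  rownames(stats) <- NULL
  stats
}

#' Intensity statistics over a region of interest
#'
#' @param f A [gray_frame()].
#' @param mask Logical matrix selecting the ROI; must be nonempty.
#' @return List with `mean`, `min`, `max` intensity.
#' @export
roi_intensity_stats <- function(f, mask) {
  stopifnot(inherits(f, "gray_frame"))
  if (!is.logical(mask) || !identical(dim(mask), dim(f$pixels)))
    stop_config("mask must be a logical matrix congruent with the frame")
  if (!any(mask)) stop_config("empty ROI mask")
  v <- f$pixels[mask]
  list(mean = mean(v), min = min(v), max = max(v))
}

#' Write a blob table as CSV
#'
#' @param blobs Blob data.frame from [extract_blobs()].
#' @param path Output CSV path.
#' @param frame_id,region Optional annotation columns.
#' @return `path`, invisibly.
#' @export
write_blob_csv <- function(blobs, path, frame_id = NA_character_,
                           region = NA_character_) {
  out <- cbind(frame_id = frame_id, region = region, blobs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a pseudo-colored rendering of a frame
#'
#' Simple linear colormap (black-red-yellow-white heat ramp) for visual
#' inspection of fluorescence intensity; purely a visualization aid.
#'
#' @param f A [gray_frame()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_pseudocolor_png <- function(f, path) {
  stopifnot(inherits(f, "gray_frame"))
  ramp <- grDevices::colorRamp(c("black", "red", "yellow", "white"))
  rgbv <- ramp(as.numeric(f$pixels) / 255) / 255
  arr <- array(0, dim = c(f$height, f$width, 3L))
  for (k in 1:3) arr[, , k] <- matrix(rgbv[, k], f$height, f$width)
  png::writePNG(arr, target = path)
  invisible(path)
}
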