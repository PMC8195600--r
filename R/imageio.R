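#' Single-channel fluorescence image
#'
#' Container for one co-registered 2D intensity grid with pixel calibration.
#' Intensities are arbitrary units (AU) and must be finite and non-negative.
#'
#' @param pixels numeric matrix of intensities (AU), finite and >= 0.
#' @param channel one of `"GFP"`, `"tdTomato"`, `"Cy5"`, `"brightfield"`.
#' @param pixel_size pixel edge length in micrometers per pixel (> 0).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels))) stopf("pixel intensities must be finite")
  if (any(pixels < 0)) stopf("pixel intensities must be >= 0")
  channel <- match.arg(channel, CHANNEL_NAMES)
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  structure(list(pixels = pixels, channel = channel, pixel_size = pixel_size),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d px  pixel_size = %g um/px\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Multi-channel fish image
#'
#' A set of co-registered channels sharing shape and pixel calibration, plus
#' optional per-fish metadata used by the longitudinal workflows.
#'
#' @param channels named list of [channel_image()] objects; names must match
#'   each element's `channel` field. At least one fluorescence channel
#'   (GFP / tdTomato / Cy5) is required.
#' @param fish_id,dpf,group,day optional metadata (identifier, age in days
#'   post-fertilization, experimental group label, observation day).
#' @return An object of class `fish_image`.
#' @export
fish_image <- function(channels, fish_id = NULL, dpf = NULL, group = NULL,
                       day = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    stopf("'channels' must be a non-empty named list of channel_image objects")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stopf("'channels' must be named by channel")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!inherits(ch, "channel_image"))
      stopf("channel '%s' is not a channel_image", nm)
    if (!identical(ch$channel, nm))
      stopf("channel list name '%s' does not match channel field '%s'", nm, ch$channel)
  }
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all channels must share the same shape")
  ps <- vapply(channels, function(ch) ch$pixel_size, numeric(1))
  if (max(ps) - min(ps) > 1e-12 * max(ps))
    stopf("all channels must share the same pixel_size")
  if (!any(names(channels) %in% FLUOR_CHANNELS))
    stopf("at least one fluorescence channel (GFP/tdTomato/Cy5) is required")
  structure(list(channels = channels, fish_id = fish_id, dpf = dpf,
                 group = group, day = day),
            class = "fish_image")
}

#' @export
print.fish_image <- function(x, ...) {
  d <- dim(x$channels[[1]]$pixels)
  cat(sprintf("<fish_image> %d x %d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$fish_id)) cat("  fish_id:", x$fish_id, "\n")
  invisible(x)
}

image_shape <- function(img) dim(img$channels[[1]]$pixels)
image_pixel_size <- function(img) img$channels[[1]]$pixel_size

sidecar_path <- function(path) paste0(path, ".json")

#' Write a fish image as a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per channel; the sidecar (`<path>.json`) records channel
#' names in page order, `pixel_size` (um/px), the storage mode, the intensity
#' scale, and any fish metadata. Integer-valued data within \[0, 65535\] are
#' stored as 16-bit pages (lossless round trip); anything else is stored as
#' 32-bit float pages normalized by the recorded scale.
#'
#' @param img a [fish_image()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_fish_image <- function(img, path, seed = NULL) {
  stopifnot(inherits(img, "fish_image"))
  mats <- lapply(img$channels, `[[`, "pixels")
  allv <- unlist(mats, use.names = FALSE)
  integer16 <- all(allv == floor(allv)) && max(allv) <= 65535
  if (integer16) {
    pages <- lapply(mats, function(m) m / 65535)
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(allv, 1)
    pages <- lapply(mats, function(m) m / scale)
    bits <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(channels = names(img$channels),
               pixel_size = image_pixel_size(img),
               bits = bits, scale = scale,
               fish_id = img$fish_id, dpf = img$dpf, group = img$group,
               day = img$day, seed = seed)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fish image written by [write_fish_image()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` must exist and name
#'   the channels and pixel size.
#' @return A [fish_image()].
#' @export
read_fish_image <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stopf("format error: missing channel metadata sidecar %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$channels) || is.null(meta$pixel_size))
    stopf("format error: sidecar must name 'channels' and 'pixel_size'")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stopf("format error: TIFF has %d pages but metadata names %d channels",
          length(pages), length(meta$channels))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stopf("format error: RGB/multisample pages not supported; one grayscale page per channel")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("format error: mismatched page shapes")
  scale <- meta$scale %||% 1
  chans <- list()
  for (i in seq_along(pages)) {
    nm <- meta$channels[[i]]
    px <- pages[[i]] * scale
    if (identical(meta$bits, 16L) || identical(meta$bits, 16))
      px <- round_half_up(px)
    chans[[nm]] <- channel_image(pmax(px, 0), nm, meta$pixel_size)
  }
  fish_image(chans, fish_id = meta$fish_id, dpf = meta$dpf,
             group = meta$group, day = meta$day)
}

## --- ROI polygons -----------------------------------------------------------

#' ROI polygon in pixel coordinates
#'
#' Vertices are 0-based `(row, col)` pixel centers, ordered along the boundary.
#' The polygon must be simple (non-self-intersecting) with at least 3 vertices.
#'
#' @param vertices numeric matrix or data frame with two columns (row, col).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stopf("format error: ROI vertices must be a two-column numeric table")
  if (nrow(v) < 3L) stopf("format error: an ROI needs at least 3 vertices")
  if (any(!is.finite(v))) stopf("format error: ROI vertices must be finite")
  colnames(v) <- c("row", "col")
  if (polygon_self_intersects(v))
    stopf("validation error: ROI polygon is self-intersecting")
  structure(list(vertices = v), class = "roi_polygon")
}

# Proper-crossing test between non-adjacent edges (shared endpoints allowed).
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])

segments_cross <- function(p1, p2, p3, p4) {
  d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
  d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    cross2(p, q, r) == 0 &&
      min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) || on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

#' Read an ROI polygon from JSON or CSV
#'
#' JSON files must contain a `vertices` array of `[row, col]` pairs (or an
#' object with `row`/`col` arrays); CSV files must have two columns
#' (row, col). Coordinates are 0-based pixel centers.
#'
#' @param path path to a `.json` or `.csv` file.
#' @return A [roi_polygon()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    v <- if (is.list(obj) && !is.null(obj$vertices)) obj$vertices else obj
    if (is.data.frame(v)) v <- as.matrix(v)
    if (is.list(v)) v <- do.call(rbind, v)
    return(roi_polygon(v))
  }
  tab <- read.csv(path)
  roi_polygon(as.matrix(tab[, 1:2]))
}

#' Rasterize an ROI polygon to a binary mask
#'
#' A pixel is included iff its center lies inside the polygon under the
#' even-odd rule, or exactly on the boundary (boundary-inclusive).
#'
#' @param roi a [roi_polygon()].
#' @param shape integer vector `c(rows, cols)` of the target mask.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_polygon"))
  shape <- as.integer(shape)
  v <- roi$vertices
  if (any(v[, 1] < 0) || any(v[, 2] < 0) ||
      any(v[, 1] > shape[1] - 1L) || any(v[, 2] > shape[2] - 1L))
    stopf("bounds error: ROI vertex outside image of shape %d x %d",
          shape[1], shape[2])
  py <- rep(0:(shape[1] - 1L), times = shape[2])   # row coords, column-major
  px <- rep(0:(shape[2] - 1L), each = shape[1])    # col coords
  inside <- rep(FALSE, length(py))
  onb <- rep(FALSE, length(py))
  n <- nrow(v)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    # boundary: point on segment ab
    cr <- (b[1] - a[1]) * (px - a[2]) - (b[2] - a[2]) * (py - a[1])
    onb <- onb | (cr == 0 &
                    py >= min(a[1], b[1]) & py <= max(a[1], b[1]) &
                    px >= min(a[2], b[2]) & px <= max(a[2], b[2]))
    # even-odd crossing of a horizontal ray in +col direction (half-open rule)
    cond <- (a[1] > py) != (b[1] > py)
    xint <- a[2] + (py - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
    hit <- cond & (px < xint)
    inside <- xor(inside, hit & !is.na(hit) & cond)
  }
  matrix(inside | onb, nrow = shape[1], ncol = shape[2])
}
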