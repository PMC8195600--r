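#' Segmentation configuration
#'
#' Parameters of the reporter segmentation pipeline. All thresholds are in
#' absolute intensity units (AU) of the acquired channels.
#'
#' @param gfp_background_thresh GFP intensity at or above which a pixel is
#'   treated as autofluorescent background and excluded from the tdTomato
#'   signal (AU).
#' @param tdt_detect_thresh low tdTomato threshold used to locate reporter
#'   signal and place the crop (AU).
#' @param tdt_segment_thresh higher tdTomato threshold applied within the
#'   masked crop to segment adipocyte signal (AU); must be >=
#'   `tdt_detect_thresh`.
#' @param crop_size fixed crop shape `c(rows, cols)` in pixels; the crop is
#'   shifted, never shrunk, at image borders.
#' @param min_component_px connected components (8-connectivity) smaller than
#'   this are removed from the final mask.
#' @param mask_dilation_px dilation radius (pixels, Chebyshev) applied to the
#'   supra-detect-threshold coarse mask before the high threshold is applied.
#' @param background_mode `"mask"` (default) zeroes tdTomato wherever GFP is
#'   at or above `gfp_background_thresh`; `"subtract"` instead subtracts the
#'   GFP intensity at those pixels, clamped at zero.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(gfp_background_thresh = 300,
                                tdt_detect_thresh = 250,
                                tdt_segment_thresh = 500,
                                crop_size = c(160L, 160L),
                                min_component_px = 20L,
                                mask_dilation_px = 2L,
                                background_mode = c("mask", "subtract")) {
  background_mode <- match.arg(background_mode)
  assert_scalar_num(gfp_background_thresh, "gfp_background_thresh", min = 0)
  assert_scalar_num(tdt_detect_thresh, "tdt_detect_thresh", min = 0)
  assert_scalar_num(tdt_segment_thresh, "tdt_segment_thresh", min = 0)
  if (tdt_segment_thresh < tdt_detect_thresh)
    stopf("tdt_segment_thresh must be >= tdt_detect_thresh")
  crop_size <- as.integer(crop_size)
  stopifnot(length(crop_size) == 2L, all(crop_size > 0L))
  if (min_component_px < 0) stopf("min_component_px must be >= 0")
  if (mask_dilation_px < 0) stopf("mask_dilation_px must be >= 0")
  structure(list(gfp_background_thresh = gfp_background_thresh,
                 tdt_detect_thresh = tdt_detect_thresh,
                 tdt_segment_thresh = tdt_segment_thresh,
                 crop_size = crop_size,
                 min_component_px = as.integer(min_component_px),
                 mask_dilation_px = as.integer(mask_dilation_px),
                 background_mode = background_mode),
            class = "segmentation_config")
}

#' Remove autofluorescent background from the reporter channel
#'
#' Pixels whose GFP intensity is at or above `gfp_background_thresh` are
#' considered gut/gallbladder autofluorescence: in `"mask"` mode their
#' tdTomato value is set to zero; in `"subtract"` mode the GFP value is
#' subtracted from the tdTomato value at those pixels (clamped at zero).
#' All other pixels are unchanged.
#'
#' @param tdt,gfp co-registered [channel_image()]s of equal shape.
#' @param gfp_background_thresh GFP background threshold (AU).
#' @param mode `"mask"` or `"subtract"`.
#' @return A [channel_image()] (tdTomato) with background removed.
#' @export
subtract_background <- function(tdt, gfp, gfp_background_thresh,
                                mode = c("mask", "subtract")) {
  stopifnot(inherits(tdt, "channel_image"), inherits(gfp, "channel_image"))
  mode <- match.arg(mode)
  if (!identical(dim(tdt$pixels), dim(gfp$pixels)))
    stopf("registration error: tdTomato and GFP shapes differ")
  bgpix <- gfp$pixels >= gfp_background_thresh
  out <- tdt$pixels
  if (mode == "mask") {
    out[bgpix] <- 0
  } else {
    out[bgpix] <- pmax(out[bgpix] - gfp$pixels[bgpix], 0)
  }
  channel_image(out, tdt$channel, tdt$pixel_size)
}

#' Place a fixed-size crop around detected reporter signal
#'
#' If any pixel of the background-subtracted tdTomato channel reaches
#' `tdt_detect_thresh`, returns a box of exactly `crop_size` centered on the
#' intensity-weighted centroid of the supra-threshold pixels, shifted (never
#' shrunk) to fit inside the image. Returns `NULL` when nothing is detected.
#'
#' @param tdt_bs background-subtracted tdTomato [channel_image()].
#' @param tdt_detect_thresh detection threshold (AU).
#' @param crop_size crop shape `c(rows, cols)`; must fit in the image.
#' @return Integer vector `c(row0, col0, row1, col1)` (0-based, half-open),
#'   or `NULL` if no pixel reaches the threshold.
#' @export
detect_crop <- function(tdt_bs, tdt_detect_thresh, crop_size) {
  stopifnot(inherits(tdt_bs, "channel_image"))
  d <- dim(tdt_bs$pixels)
  crop_size <- as.integer(crop_size)
  if (any(crop_size > d))
    stopf("configuration error: crop_size %dx%d exceeds image %dx%d",
          crop_size[1], crop_size[2], d[1], d[2])
  supra <- tdt_bs$pixels >= tdt_detect_thresh
  if (!any(supra)) return(NULL)
  idx <- which(supra)
  w <- tdt_bs$pixels[idx]
  r0b <- ((idx - 1L) %% d[1])          # 0-based row
  c0b <- ((idx - 1L) %/% d[1])         # 0-based col
  ctr <- c(sum(r0b * w) / sum(w), sum(c0b * w) / sum(w))
  start <- round_half_up(ctr) - floor((crop_size - 1) / 2)
  start <- pmin(pmax(start, 0), d - crop_size)
  as.integer(c(start[1], start[2], start[1] + crop_size[1], start[2] + crop_size[2]))
}

#' Segment adipose signal within a crop
#'
#' Inside the crop, a coarse mask is formed from pixels at or above
#' `tdt_detect_thresh` and dilated by `mask_dilation_px`; the final mask keeps
#' pixels inside the coarse mask whose value reaches `tdt_segment_thresh`,
#' then removes 8-connected components smaller than `min_component_px`.
#' Everything outside the crop is zero.
#'
#' @param tdt_bs background-subtracted tdTomato [channel_image()].
#' @param crop_box 0-based half-open box `c(row0, col0, row1, col1)`, inside
#'   the image.
#' @param tdt_detect_thresh,tdt_segment_thresh low/high thresholds (AU).
#' @param min_component_px minimum surviving component size in pixels.
#' @param mask_dilation_px coarse-mask dilation radius in pixels.
#' @return Logical matrix, full-image coordinates.
#' @export
segment_in_crop <- function(tdt_bs, crop_box, tdt_detect_thresh,
                            tdt_segment_thresh, min_component_px = 0L,
                            mask_dilation_px = 0L) {
  stopifnot(inherits(tdt_bs, "channel_image"))
  d <- dim(tdt_bs$pixels)
  cb <- as.integer(crop_box)
  if (length(cb) != 4L || cb[1] < 0L || cb[2] < 0L || cb[3] > d[1] ||
      cb[4] > d[2] || cb[3] <= cb[1] || cb[4] <= cb[2])
    stopf("crop_box must be a 0-based half-open box inside the image")
  sub <- tdt_bs$pixels[(cb[1] + 1L):cb[3], (cb[2] + 1L):cb[4], drop = FALSE]
  coarse <- dilate_mask(sub >= tdt_detect_thresh, mask_dilation_px)
  fine <- coarse & (sub >= tdt_segment_thresh)
  fine <- remove_small_components(fine, min_component_px)
  full <- matrix(FALSE, d[1], d[2])
  full[(cb[1] + 1L):cb[3], (cb[2] + 1L):cb[4]] <- fine
  full
}

#' Quantify adipose tissue area in a fish image
#'
#' Composes [subtract_background()], [detect_crop()] and [segment_in_crop()]
#' and reports the pixel count of the final mask together with the calibrated
#' area in square micrometers (`area_px * pixel_size^2`).
#'
#' @param img a [fish_image()] with GFP and tdTomato channels.
#' @param cfg a [segmentation_config()].
#' @return An object of class `segmentation_result` with fields
#'   `adipose_mask` (logical, full-image), `crop_box` (0-based half-open, or
#'   `NULL`), `area_px`, `area_um2`, `thresholds_used` (the config) and
#'   `detected`.
#' @export
quantify_fish <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "fish_image"), inherits(cfg, "segmentation_config"))
  if (!all(c("GFP", "tdTomato") %in% names(img$channels)))
    stopf("input error: quantify_fish needs GFP and tdTomato channels")
  ps <- image_pixel_size(img)
  tdt_bs <- subtract_background(img$channels$tdTomato, img$channels$GFP,
                                cfg$gfp_background_thresh,
                                mode = cfg$background_mode)
  box <- detect_crop(tdt_bs, cfg$tdt_detect_thresh, cfg$crop_size)
  if (is.null(box)) {
    mask <- matrix(FALSE, nrow(tdt_bs$pixels), ncol(tdt_bs$pixels))
    return(segmentation_result(mask, NULL, ps, cfg, detected = FALSE))
  }
  mask <- segment_in_crop(tdt_bs, box, cfg$tdt_detect_thresh,
                          cfg$tdt_segment_thresh, cfg$min_component_px,
                          cfg$mask_dilation_px)
  segmentation_result(mask, box, ps, cfg, detected = any(mask))
}

segmentation_result <- function(mask, crop_box, pixel_size, cfg, detected) {
  area_px <- sum(mask)
  structure(list(adipose_mask = mask, crop_box = crop_box,
                 area_px = area_px, area_um2 = area_px * pixel_size^2,
                 pixel_size = pixel_size, thresholds_used = cfg,
                 detected = detected && area_px > 0),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> detected = %s, area_px = %d, area_um2 = %g\n",
              x$detected, x$area_px, x$area_um2))
  if (!is.null(x$crop_box))
    cat(sprintf("  crop rows [%d,%d), cols [%d,%d)\n",
                x$crop_box[1], x$crop_box[3], x$crop_box[2], x$crop_box[4]))
  invisible(x)
}
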