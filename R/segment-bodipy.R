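#' Automatic intensity threshold (isodata or otsu)
#'
#' The isodata rule iterates `t <- (mean below t + mean at/above t) / 2`
#' starting from the midrange of the image until the update is smaller than
#' 0.5 AU. Otsu maximizes between-class variance on a 256-bin histogram.
#' Both operate on the raw intensity scale of the channel.
#'
#' @param img a [channel_image()] (or bare numeric matrix) with at least two
#'   distinct values.
#' @param method `"isodata"` (default) or `"otsu"`.
#' @param max_iter iteration cap for isodata.
#' @return A list of class `auto_threshold_report` with fields `threshold`
#'   (AU), `method`, `iterations`, `converged`.
#' @export
auto_threshold <- function(img, method = c("isodata", "otsu"), max_iter = 1000L) {
  method <- match.arg(method)
  px <- if (inherits(img, "channel_image")) img$pixels else img
  rng <- range(px)
  if (rng[1] == rng[2])
    stopf("degenerate-input error: constant image, no threshold exists")
  if (method == "isodata") {
    t <- mean(rng)
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      lo <- px[px < t]
      hi <- px[px >= t]
      tn <- if (length(lo) == 0L) mean(hi) else (mean(lo) + mean(hi)) / 2
      if (abs(tn - t) < 0.5) { t <- tn; converged <- TRUE; break }
      t <- tn
      if (iter >= max_iter) break
    }
  } else {
    scaled <- (px - rng[1]) / (rng[2] - rng[1])
    t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
    t <- rng[1] + t01 * (rng[2] - rng[1])
    iter <- 1L
    converged <- TRUE
  }
  structure(list(threshold = t, method = method, iterations = iter,
                 converged = converged),
            class = "auto_threshold_report")
}

#' @export
print.auto_threshold_report <- function(x, ...) {
  cat(sprintf("<auto_threshold> %s: %g AU (%d iterations, converged = %s)\n",
              x$method, x$threshold, x$iterations, x$converged))
  invisible(x)
}

#' Quantify dye-stained adipose area with autofluorescence removal
#'
#' The GFP (dye) channel is auto-thresholded; pixels at or above the Cy5
#' channel's auto-threshold are removed as autofluorescence (mask-level set
#' difference); the result is intersected with a rasterized ROI when one is
#' supplied (otherwise the full image); components smaller than
#' `cfg$min_component_px` are dropped.
#'
#' @param gfp,cy5 co-registered [channel_image()]s.
#' @param roi optional [roi_polygon()] restricting the quantified region.
#' @param cfg a [segmentation_config()] (only `min_component_px` is used).
#' @param method auto-threshold method passed to [auto_threshold()].
#' @return A `segmentation_result` (see [quantify_fish()]); `crop_box` spans
#'   the full image. The auto-threshold reports for both channels are
#'   attached as attribute `"auto_thresholds"`.
#' @export
bodipy_area <- function(gfp, cy5, roi = NULL, cfg = segmentation_config(),
                        method = "isodata") {
  stopifnot(inherits(gfp, "channel_image"), inherits(cy5, "channel_image"))
  if (!identical(dim(gfp$pixels), dim(cy5$pixels)))
    stopf("registration error: GFP and Cy5 shapes differ")
  d <- dim(gfp$pixels)
  thr_g <- tryCatch(auto_threshold(gfp, method),
                    error = function(e) stopf("GFP channel: %s", conditionMessage(e)))
  thr_c <- tryCatch(auto_threshold(cy5, method),
                    error = function(e) stopf("Cy5 channel: %s", conditionMessage(e)))
  mask <- (gfp$pixels >= thr_g$threshold) & !(cy5$pixels >= thr_c$threshold)
  if (!is.null(roi)) mask <- mask & rasterize_roi(roi, d)
  mask <- remove_small_components(mask, cfg$min_component_px)
  res <- segmentation_result(mask, c(0L, 0L, d[1], d[2]), gfp$pixel_size, cfg,
                             detected = any(mask))
  attr(res, "auto_thresholds") <- list(GFP = thr_g, Cy5 = thr_c)
  res
}
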