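#' Parameters for the synthetic fish-image generator
#'
#' Describes a transparent-fish field of view: elliptical adipose blobs that
#' express the lipid-droplet reporter, a single elongated autofluorescent
#' gut/gallbladder region along the lower image edge that shows up in every
#' fluorescence channel, a constant background and additive noise. Intensity
#' defaults are declared placeholders: the real distribution of adipocyte
#' sizes and gut autofluorescence is not characterised, so values are chosen
#' to give the signal ordering seen in practice (adipose reporter signal well
#' above background; gut autofluorescence strong in GFP, intermediate in
#' tdTomato and Cy5).
#'
#' @param shape image shape `c(rows, cols)` in pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_adipose_blobs number of elliptical adipose blobs to plant.
#' @param blob_axes_range range `c(min, max)` of ellipse semi-axes, pixels.
#' @param adipose_peak reporter intensity over adipose pixels (AU).
#' @param gut_peak_gfp,gut_peak_tdt,gut_peak_cy5 gut autofluorescence added in
#'   each channel (AU).
#' @param adipose_gfp_leak GFP-channel intensity over adipose pixels (AU);
#'   default far below any sensible GFP background threshold.
#' @param noise_sd additive Gaussian noise standard deviation (AU); ignored
#'   for `noise_model = "poisson"`.
#' @param background_level constant background (AU).
#' @param blur_sigma Gaussian blur of the ideal (pre-noise) image, pixels;
#'   0 disables blurring. Ground-truth area is defined on the ideal
#'   rasterized ellipses before blurring.
#' @param noise_model `"gaussian"` (additive) or `"poisson"` (counts at the
#'   ideal intensity).
#' @param gut_overlap_fraction allowed fractional overlap between an adipose
#'   blob and the gut region; 0 (default) forbids overlap via rejection
#'   sampling.
#' @param blobs optional data frame with columns `center_row`, `center_col`,
#'   `axis_a`, `axis_b`, `theta` (0-based pixel coordinates, semi-axes in
#'   pixels) giving explicit blob placements; overrides random placement and
#'   `n_adipose_blobs`.
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return A list of class `image_sim_params`.
#' @export
image_sim_params <- function(shape = c(256L, 256L),
                             pixel_size = 2.5,
                             n_adipose_blobs = 6L,
                             blob_axes_range = c(6, 14),
                             adipose_peak = 900,
                             gut_peak_gfp = 700,
                             gut_peak_tdt = 500,
                             gut_peak_cy5 = 600,
                             adipose_gfp_leak = 20,
                             noise_sd = 10,
                             background_level = 100,
                             blur_sigma = 1,
                             noise_model = c("gaussian", "poisson"),
                             gut_overlap_fraction = 0,
                             blobs = NULL,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 32L))
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  stopifnot(length(blob_axes_range) == 2L, blob_axes_range[1] > 0,
            blob_axes_range[2] >= blob_axes_range[1])
  for (nm in c("adipose_peak", "gut_peak_gfp", "gut_peak_tdt", "gut_peak_cy5",
               "adipose_gfp_leak", "noise_sd", "background_level",
               "blur_sigma", "gut_overlap_fraction"))
    assert_scalar_num(get(nm), nm, min = 0)
  if (n_adipose_blobs < 0) stopf("'n_adipose_blobs' must be >= 0")
  if (!is.null(blobs)) {
    blobs <- as.data.frame(blobs)
    need <- c("center_row", "center_col", "axis_a", "axis_b", "theta")
    if (!all(need %in% names(blobs)))
      stopf("explicit 'blobs' must have columns %s", paste(need, collapse = ", "))
  }
  structure(list(shape = shape, pixel_size = pixel_size,
                 n_adipose_blobs = as.integer(n_adipose_blobs),
                 blob_axes_range = as.numeric(blob_axes_range),
                 adipose_peak = adipose_peak, gut_peak_gfp = gut_peak_gfp,
                 gut_peak_tdt = gut_peak_tdt, gut_peak_cy5 = gut_peak_cy5,
                 adipose_gfp_leak = adipose_gfp_leak, noise_sd = noise_sd,
                 background_level = background_level, blur_sigma = blur_sigma,
                 noise_model = noise_model,
                 gut_overlap_fraction = gut_overlap_fraction,
                 blobs = blobs,
                 seed = as.integer(seed)),
            class = "image_sim_params")
}

# Rasterize a filled ellipse (boundary inclusive) on the 0-based pixel lattice:
# pixel (r, c) is in iff the rotated normalized quadratic form is <= 1.
rasterize_ellipse <- function(shape, center, axes, theta = 0) {
  rr <- rep(0:(shape[1] - 1L), times = shape[2]) - center[1]
  cc <- rep(0:(shape[2] - 1L), each = shape[1]) - center[2]
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  matrix((u / axes[1])^2 + (v / axes[2])^2 <= 1, shape[1], shape[2])
}

# Default gut region: one elongated ellipse along the lower image edge,
# mimicking the intestinal loops' position.
gut_region <- function(shape) {
  rasterize_ellipse(shape,
                    center = c(0.85 * (shape[1] - 1), 0.5 * (shape[2] - 1)),
                    axes = c(0.07 * shape[1], 0.32 * shape[2]),
                    theta = 0)
}

MAX_PLACEMENT_ATTEMPTS <- 200L

# Plant n elliptical blobs in the central field, rejecting placements that
# leave the image or overlap the gut beyond the allowed fraction.
place_blobs <- function(params, gut_mask) {
  shape <- params$shape
  adipose <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(params$blobs)) {
    blobs <- params$blobs
    blobs$peak <- params$adipose_peak
    for (i in seq_len(nrow(blobs)))
      adipose <- adipose | rasterize_ellipse(
        shape, c(blobs$center_row[i], blobs$center_col[i]),
        c(blobs$axis_a[i], blobs$axis_b[i]), blobs$theta[i])
    return(list(mask = adipose, blobs = blobs))
  }
  n <- params$n_adipose_blobs
  blobs <- data.frame(center_row = numeric(0), center_col = numeric(0),
                      axis_a = numeric(0), axis_b = numeric(0),
                      theta = numeric(0), peak = numeric(0))
  if (n == 0L) return(list(mask = adipose, blobs = blobs))
  row_rng <- c(0.25, 0.55) * (shape[1] - 1)
  col_rng <- c(0.30, 0.70) * (shape[2] - 1)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(MAX_PLACEMENT_ATTEMPTS)) {
      ctr <- c(runif(1, row_rng[1], row_rng[2]), runif(1, col_rng[1], col_rng[2]))
      ax <- runif(2, params$blob_axes_range[1], params$blob_axes_range[2])
      th <- runif(1, 0, pi)
      m <- rasterize_ellipse(shape, ctr, ax, th)
      ov <- sum(m & gut_mask) / max(sum(m), 1L)
      if (ov <= params$gut_overlap_fraction) {
        adipose <- adipose | m
        blobs <- rbind(blobs, data.frame(center_row = ctr[1], center_col = ctr[2],
                                         axis_a = ax[1], axis_b = ax[2],
                                         theta = th, peak = params$adipose_peak))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("placement error: could not place adipose blob %d after %d attempts",
            i, MAX_PLACEMENT_ATTEMPTS)
  }
  list(mask = adipose, blobs = blobs)
}

make_channel_stack <- function(params, adipose, gut, weights) {
  shape <- params$shape
  bg <- params$background_level
  build <- function(adipose_amp, gut_amp) {
    ideal <- matrix(bg, shape[1], shape[2]) + adipose_amp * adipose + gut_amp * gut
    ideal <- blur_gaussian(ideal, params$blur_sigma)
    if (params$noise_model == "gaussian") {
      if (params$noise_sd > 0)
        ideal <- ideal + matrix(rnorm(length(ideal), 0, params$noise_sd),
                                shape[1], shape[2])
    } else {
      ideal <- matrix(rpois(length(ideal), pmax(ideal, 0)), shape[1], shape[2])
    }
    pmax(ideal, 0)
  }
  chans <- list()
  for (nm in names(weights)) {
    w <- weights[[nm]]
    chans[[nm]] <- channel_image(build(w[1], w[2]), nm, params$pixel_size)
  }
  chans
}

ground_truth <- function(adipose, gut, blobs) {
  structure(list(adipose_mask = adipose, gut_mask = gut,
                 adipose_area_px = sum(adipose), per_blob_params = blobs),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> adipose_area_px = %d, gut pixels = %d, blobs = %d\n",
              x$adipose_area_px, sum(x$gut_mask), nrow(x$per_blob_params)))
  invisible(x)
}

#' Generate a synthetic reporter-line fish image with ground truth
#'
#' Adipose blobs carry the reporter signal in the tdTomato channel (with only
#' a small leak into GFP); the gut region is autofluorescent in GFP, tdTomato
#' and Cy5. Returns the image and the planted masks so segmentation accuracy
#' can be measured against known truth.
#'
#' @param params an [image_sim_params()].
#' @return `list(image = fish_image, truth = ground_truth)`.
#' @export
generate_fish_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  withr::with_seed(params$seed, {
    gut <- gut_region(params$shape)
    pl <- place_blobs(params, gut)
    chans <- make_channel_stack(params, pl$mask, gut, list(
      GFP = c(params$adipose_gfp_leak, params$gut_peak_gfp),
      tdTomato = c(params$adipose_peak, params$gut_peak_tdt),
      Cy5 = c(0, params$gut_peak_cy5)))
    list(image = fish_image(chans),
         truth = ground_truth(pl$mask, gut, pl$blobs))
  })
}

#' Generate a synthetic dye-stained fish image with ground truth
#'
#' The lipophilic-dye variant: adipose signal appears in the GFP channel only,
#' autofluorescence in both GFP and Cy5, and the tdTomato channel stays at
#' background.
#'
#' @inheritParams generate_fish_image
#' @return `list(image = fish_image, truth = ground_truth)`.
#' @export
generate_bodipy_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  withr::with_seed(params$seed, {
    gut <- gut_region(params$shape)
    pl <- place_blobs(params, gut)
    chans <- make_channel_stack(params, pl$mask, gut, list(
      GFP = c(params$adipose_peak, params$gut_peak_gfp),
      tdTomato = c(0, 0),
      Cy5 = c(0, params$gut_peak_cy5)))
    list(image = fish_image(chans),
         truth = ground_truth(pl$mask, gut, pl$blobs))
  })
}
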