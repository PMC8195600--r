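make_ci <- function(px, ch = "tdTomato", ps = 1) channel_image(px, ch, ps)

test_that("background subtraction gates tdTomato by the GFP threshold", {
  tdt <- make_ci(matrix(0, 10, 10))
  gfp <- make_ci(matrix(500, 10, 10), "GFP")
  expect_true(all(subtract_background(tdt, gfp, 300)$pixels == 0))
  # gfp uniformly above threshold kills everything regardless of tdt
  tdt2 <- make_ci(matrix(runif(100, 0, 1000), 10, 10))
  expect_true(all(subtract_background(tdt2, gfp, 300)$pixels == 0))
  # below threshold leaves tdt untouched
  gfp_lo <- make_ci(matrix(100, 10, 10), "GFP")
  expect_identical(subtract_background(tdt2, gfp_lo, 300)$pixels, tdt2$pixels)
  expect_error(subtract_background(tdt2, make_ci(matrix(1, 5, 5), "GFP"), 300),
               "registration error")
})

test_that("surviving tdTomato pixels equal the planted adipose mask (noiseless)", {
  p <- image_sim_params(noise_sd = 0, blur_sigma = 0, seed = 21)
  g <- generate_fish_image(p)
  bs <- subtract_background(g$image$channels$tdTomato, g$image$channels$GFP, 300)
  # brute-force per-pixel check against the planted masks
  survived <- bs$pixels > p$background_level
  expect_identical(survived, g$truth$adipose_mask)
})

test_that("background subtraction is idempotent and monotone in its threshold", {
  p <- image_sim_params(seed = 31)  # default noise
  g <- generate_fish_image(p)
  tdt <- g$image$channels$tdTomato; gfp <- g$image$channels$GFP
  once <- subtract_background(tdt, gfp, 300)
  twice <- subtract_background(once, gfp, 300)
  expect_identical(once$pixels, twice$pixels)
  # raising the GFP threshold never shrinks the surviving set
  lo <- subtract_background(tdt, gfp, 250)$pixels > 0
  hi <- subtract_background(tdt, gfp, 400)$pixels > 0
  expect_true(all(hi[lo] | !lo[lo]))  # lo-survivors stay survivors under hi
  expect_true(all(which(lo) %in% which(hi)))
})

test_that("detect_crop centers, clamps and weights as specified", {
  px <- matrix(0, 200, 200)
  px[51, 51] <- 100  # 0-based (50, 50)
  box <- detect_crop(make_ci(px), 50, c(21, 21))
  expect_identical(box, c(40L, 40L, 61L, 61L))
  # near the corner the box shifts, never shrinks
  px2 <- matrix(0, 200, 200); px2[3, 3] <- 100  # 0-based (2, 2)
  expect_identical(detect_crop(make_ci(px2), 50, c(21, 21)), c(0L, 0L, 21L, 21L))
  # two equal clusters: centroid midway
  px3 <- matrix(0, 200, 200); px3[31, 31] <- 100; px3[71, 71] <- 100
  expect_identical(detect_crop(make_ci(px3), 50, c(21, 21)), c(40L, 40L, 61L, 61L))
  # nothing detected
  expect_null(detect_crop(make_ci(matrix(0, 50, 50)), 50, c(21, 21)))
  expect_error(detect_crop(make_ci(px), 50, c(300, 21)), "configuration error")
})

test_that("segment_in_crop applies the high threshold and component filter", {
  px <- matrix(0, 128, 128)
  blank <- segment_in_crop(make_ci(px), c(0, 0, 128, 128), 50, 100)
  expect_false(any(blank))
  # planted disc of radius 10 -> 317 px at the high threshold
  p <- image_sim_params(shape = c(128, 128), noise_sd = 0, blur_sigma = 0,
                        blobs = data.frame(center_row = 60, center_col = 64,
                                           axis_a = 10, axis_b = 10, theta = 0))
  g <- generate_fish_image(p)
  bs <- subtract_background(g$image$channels$tdTomato, g$image$channels$GFP, 300)
  m <- segment_in_crop(bs, c(30, 30, 100, 100), 250, 500, min_component_px = 0)
  expect_equal(sum(m), 317)
  # a 40-px speck dies at min_component_px = 50 while a 400-px blob survives
  px4 <- matrix(0, 128, 128)
  px4[10:17, 10:14] <- 1000          # 8 x 5 = 40 px
  px4[60:79, 60:79] <- 1000          # 400 px
  m4 <- segment_in_crop(make_ci(px4), c(0, 0, 128, 128), 250, 500,
                        min_component_px = 50)
  expect_equal(sum(m4), 400)
  expect_false(any(m4[10:17, 10:14]))
})

test_that("component removal uses 8-connectivity", {
  px <- matrix(0, 32, 32)
  # a diagonal chain of single pixels: one 8-connected component of size 5
  for (i in 0:4) px[10 + i, 10 + i] <- 1000
  m <- segment_in_crop(make_ci(px), c(0, 0, 32, 32), 500, 500,
                       min_component_px = 5)
  expect_equal(sum(m), 5)
  m2 <- segment_in_crop(make_ci(px), c(0, 0, 32, 32), 500, 500,
                        min_component_px = 6)
  expect_equal(sum(m2), 0)
})

test_that("quantify_fish composes the pipeline and calibrates area", {
  blank <- fish_image(list(
    GFP = make_ci(matrix(100, 64, 64), "GFP"),
    tdTomato = make_ci(matrix(100, 64, 64))))
  r0 <- quantify_fish(blank, segmentation_config(crop_size = c(32, 32)))
  expect_false(r0$detected)
  expect_equal(r0$area_px, 0)
  # unit arithmetic: 100 px at 2 um/px -> 400 um^2
  px <- matrix(0, 64, 64); px[21:30, 21:30] <- 1000
  img <- fish_image(list(GFP = make_ci(matrix(0, 64, 64), "GFP", 2),
                         tdTomato = make_ci(px, "tdTomato", 2)))
  r1 <- quantify_fish(img, segmentation_config(crop_size = c(32, 32),
                                               min_component_px = 0))
  expect_equal(r1$area_px, 100)
  expect_equal(r1$area_um2, 400)
  expect_error(quantify_fish(fish_image(list(GFP = make_ci(matrix(1, 8, 8), "GFP")))),
               "input error")
})

test_that("gut autofluorescence contributes zero area on noiseless images", {
  p <- image_sim_params(noise_sd = 0, blur_sigma = 0, seed = 13)
  g <- generate_fish_image(p)
  res <- quantify_fish(g$image)
  expect_identical(res$adipose_mask, g$truth$adipose_mask)
  expect_equal(sum(res$adipose_mask & g$truth$gut_mask), 0)
  expect_equal(res$area_px, g$truth$adipose_area_px)
})

test_that("raising the segmentation threshold never increases area", {
  g <- generate_fish_image(image_sim_params(seed = 17))
  areas <- sapply(c(400, 500, 600, 700), function(t)
    quantify_fish(g$image, segmentation_config(tdt_segment_thresh = t))$area_px)
  expect_true(all(diff(areas) <= 0))
})

test_that("area recovery stays within 5% median error at default noise", {
  errs <- sapply(1:15, function(s) {
    g <- generate_fish_image(image_sim_params(seed = s))
    r <- quantify_fish(g$image)
    abs(r$area_px - g$truth$adipose_area_px) / g$truth$adipose_area_px
  })
  expect_lte(median(errs), 0.05)
})
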