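# Channel splitting, grayscale merging, Otsu and the full ROI pipeline.

test_that("split_channels separates and recombines losslessly", {
  img <- flat_image(c(0, 255, 0), nr = 4, nc = 5)
  b <- split_channels(img)
  expect_true(all(b$r == 0) && all(b$g == 255) && all(b$b == 0))
  set.seed(31)
  px <- array(sample(0:255, 4 * 5 * 3, TRUE), dim = c(4, 5, 3))
  b <- split_channels(px)
  rec <- array(c(b$r, b$g, b$b), dim = dim(px))
  expect_identical(rec, px)
  gray <- array(rep(px[, , 1], 3), dim = dim(px))
  b2 <- split_channels(gray)
  expect_identical(b2$r, b2$g)
  expect_error(split_channels(array(0, c(4, 5, 2))), "3-channel")
})

test_that("merge_to_gray implements a rescaled excess-green score", {
  leaf <- list(r = matrix(60), g = matrix(180), b = matrix(60))
  soil <- list(r = matrix(120), g = matrix(100), b = matrix(80))
  expect_gt(merge_to_gray(leaf)[1], merge_to_gray(soil)[1])
  # 2G - R - B = 240 vs 0
  expect_equal(merge_to_gray(leaf)[1], (240 + 510) / 1020 * 255)
  expect_equal(merge_to_gray(soil)[1], (0 + 510) / 1020 * 255)
  # uniform weights reduce to the channel mean
  b <- list(r = matrix(30), g = matrix(60), b = matrix(90))
  expect_equal(merge_to_gray(b, c(1, 1, 1) / 3)[1], 60)
  # all-equal RGB under excess-green -> constant mid-level
  g <- merge_to_gray(list(r = matrix(77, 2, 2), g = matrix(77, 2, 2),
                          b = matrix(77, 2, 2)))
  expect_true(all(abs(g - 127.5) < 1e-9))
  # monotone in G for fixed R, B
  lo <- merge_to_gray(list(r = matrix(50), g = matrix(100), b = matrix(50)))
  hi <- merge_to_gray(list(r = matrix(50), g = matrix(140), b = matrix(50)))
  expect_gt(hi[1], lo[1])
  expect_error(merge_to_gray(list(r = matrix(0, 2, 2), g = matrix(0, 3, 3),
                                  b = matrix(0, 2, 2))), "shape")
})

test_that("otsu_threshold equals exhaustive search and honours the tie-break", {
  h <- rep(0, 256); h[1] <- 10; h[256] <- 10
  expect_equal(otsu_threshold(h), 0)   # all splits tie; smallest t wins
  expect_error(otsu_threshold(rep(c(1, 0), c(1, 255))), "degenerate")
  set.seed(32)
  for (i in 1:200) {
    h <- rep(0, 256)
    occ <- sample(0:255, sample(2:40, 1))
    h[occ + 1] <- rpois(length(occ), 40) + 1
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
  # bimodal sampled histogram: threshold separates the two modes (the
  # between-class variance is nearly flat across the gap, so the exact
  # argmax with smallest-t tie-breaking sits toward the gap's left edge)
  x <- c(rnorm(5e4, 50, 10), rnorm(5e4, 200, 10))
  h <- tabulate(pmin(pmax(round(x), 0), 255) + 1L, 256)
  t <- otsu_threshold(h)
  expect_identical(t, oracle_otsu(h))
  expect_true(t > 80 && t < 170)
})

test_that("segmentation recovers the truth mask on noise-free renders", {
  cfg <- trial_config(n_varieties = 1, plots_unstressed = 1, plots_treated = 1,
                      exclude_from_second_plot = 0, days = c(0L),
                      views = "vertical", seed = 33,
                      pixel_noise_sd = 0, lobe_color_sd = 0, growth_noise_sd = 0)
  tr <- generate_trial(cfg)
  id <- names(tr$images)[1]
  sg <- segment(tr$images[[id]])
  expect_gte(mask_jaccard(sg$roi, tr$truth$masks[[id]]), 0.95)
})

test_that("an all-background image yields zero components, not an error", {
  img <- flat_image(c(40, 38, 42), nr = 30, nc = 30)
  expect_warning(sg <- segment(img), "empty")
  expect_equal(length(sg$components), 0)
  expect_false(any(sg$roi))
})

test_that("two disjoint rendered blobs give two components; min_size is monotone", {
  px <- array(rep(c(40, 38, 42), each = 900), dim = c(30, 30, 3))
  for (k in 1:3) {
    px[5:10, 5:10, k] <- c(60, 150, 50)[k]
    px[20:24, 20:24, k] <- c(60, 150, 50)[k]
  }
  img <- plant_image(px)
  sg <- segment(img, params = segment_params(min_size = 5, opening_radius = 0))
  expect_equal(length(sg$components), 2)
  expect_equal(sort(unname(sg$components)), c(25, 36))
  expect_equal(sg$largest_component_index,
               unname(which.max(sg$components)))
  # shrinking min_size never decreases the component count
  n_prev <- -1L
  for (ms in c(40, 30, 20, 10, 1)) {
    sgm <- suppressWarnings(segment(img, params = segment_params(min_size = ms)))
    if (n_prev >= 0) expect_gte(length(sgm$components), n_prev)
    n_prev <- length(sgm$components)
  }
})

test_that("exclusion masks remove clutter without touching foreground", {
  tr <- quick_trial(seed = 34, days = c(0L))
  id <- names(tr$images)[1]
  img <- tr$images[[id]]
  excl <- exclude_obstacles(img, default_obstacle_rules(img$view))
  truth <- tr$truth$masks[[id]]
  expect_lt(sum(excl & truth) / sum(truth), 0.01)
  sg <- segment(img, excl)
  expect_gte(mask_jaccard(sg$roi, truth), 0.9)
})

test_that("the per-band binarize-then-merge variant still finds the plant", {
  tr <- quick_trial(seed = 35, days = c(0L))
  id <- names(tr$images)[1]
  sg <- segment(tr$images[[id]],
                params = segment_params(band_mode = "binary_merge"))
  expect_gt(length(sg$components), 0)
})
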