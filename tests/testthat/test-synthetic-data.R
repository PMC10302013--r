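# Growth model, renderer and trial generator: determinism, closed forms,
# effect monotonicity and ground-truth consistency.

test_that("unstressed growth follows the closed form and zero effects erase treatment", {
  vp <- variety_params(growth_rate = 0.1)
  st <- simulate_growth(vp, stress_model(), FALSE, 7, noise_sd = 0)
  expect_equal(st$true_area_mm2, 2000 * 1.1^14)   # day0 = -7, 14 growth days
  # zero-effect stress: treated state identical to unstressed, all days
  s0 <- stress_model(area_shrink_per_day = 0, yellowing_per_day = 0)
  for (d in c(-7, 0, 7, 14, 21, 28)) {
    set.seed(91); a <- simulate_growth(vp, s0, TRUE, d, noise_sd = 0.05)
    set.seed(91); b <- simulate_growth(vp, s0, FALSE, d, noise_sd = 0.05)
    expect_identical(a[setdiff(names(a), "treated")],
                     b[setdiff(names(b), "treated")])
  }
  expect_error(simulate_growth(vp, stress_model(), FALSE, 99), "range")
  expect_error(simulate_growth(vp, stress_model(), FALSE, -20), "range")
})

test_that("simulate_growth is deterministic under a fixed seed and treated areas dip then recover", {
  vp <- variety_params()
  set.seed(92); a <- simulate_growth(vp, stress_model(), TRUE, 14, noise_sd = 0.05)
  set.seed(92); b <- simulate_growth(vp, stress_model(), TRUE, 14, noise_sd = 0.05)
  expect_identical(a, b)
  st <- stress_model(area_shrink_per_day = 0.05, recovery_rate = 0.04)
  un <- vapply(c(0, 14, 28), function(d)
    simulate_growth(vp, st, FALSE, d, noise_sd = 0)$true_area_mm2, 0)
  tr <- vapply(c(0, 14, 28), function(d)
    simulate_growth(vp, st, TRUE, d, noise_sd = 0)$true_area_mm2, 0)
  expect_equal(tr[1], un[1])                    # identical before treatment
  expect_lt(tr[2] / un[2], 0.6)                 # (1 - .05)^14 deficit at +14
  expect_gt(tr[3] / un[3], tr[2] / un[2])       # deficit closes in recovery
  expect_lt(tr[3] / un[3], 1)                   # ...but not fully by default
})

test_that("expected treated area at day +14 is non-increasing in the shrink rate", {
  vp <- variety_params()
  grid <- c(0, 0.02, 0.05, 0.08)
  means <- vapply(grid, function(s) {
    st <- stress_model(area_shrink_per_day = s)
    set.seed(93)
    mean(vapply(1:200, function(i)
      simulate_growth(vp, st, TRUE, 14, noise_sd = 0.06)$true_area_mm2, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("height and node counts correlate with area by construction", {
  set.seed(94)
  vars <- make_varieties(30)
  st <- lapply(vars, function(v) simulate_growth(v, stress_model(), FALSE, 14,
                                                 noise_sd = 0.05))
  area <- vapply(st, `[[`, 0, "true_area_mm2")
  height <- vapply(st, `[[`, 0, "true_height_mm")
  expect_gt(pearson_correlation(area, height), 0.5)
  expect_true(all(vapply(st, `[[`, 0, "node_count_total") >=
                    vapply(st, `[[`, 0, "node_count_main")))
})

test_that("rendered truth masks hit the target pixel area", {
  cfg <- trial_config(seed = 95, pixel_noise_sd = 0, lobe_color_sd = 0,
                      growth_noise_sd = 0)
  vp <- variety_params()
  st <- simulate_growth(vp, stress_model(), FALSE, 0, noise_sd = 0)
  set.seed(95)
  rp <- render_plant(st, "vertical", cfg)
  target <- st$true_area_mm2 * cfg$px_per_mm^2
  expect_lt(abs(sum(rp$mask) - target) / target, 0.05)
  expect_true(all(dim(rp$image$pixels)[1:2] == cfg$image_size))
  # truth mask marks exactly the leaf pixels: leaf colour where masked
  g <- rp$image$pixels[, , 2]
  expect_true(all(g[rp$mask] > 90))
})

test_that("renders are bit-identical under a fixed seed and empty for zero area", {
  cfg <- trial_config(seed = 96)
  vp <- variety_params()
  st <- simulate_growth(vp, stress_model(), FALSE, 0, noise_sd = 0)
  set.seed(96); a <- render_plant(st, "horizontal", cfg)
  set.seed(96); b <- render_plant(st, "horizontal", cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  st0 <- st; st0$true_area_mm2 <- 0
  cfg0 <- trial_config(seed = 96, pixel_noise_sd = 0)
  rp <- render_plant(st0, "vertical", cfg0)
  expect_false(any(rp$mask))
  sg <- suppressWarnings(segment(rp$image, exclude_obstacles(rp$image)))
  expect_equal(length(sg$components), 0)
  # oversized plant: render error naming the plant
  stbig <- st; stbig$true_area_mm2 <- 5e5
  expect_error(render_plant(stbig, "vertical", cfg, plant_id = "P999"), "P999")
})

test_that("generate_trial counts, manifests and determinism", {
  tr <- quick_trial(seed = 97, days = c(0L, 14L), n_varieties = 1)
  # 1 variety x 2 plots x 2 days x 1 view = 4 images
  expect_equal(length(tr$images), 4)
  expect_equal(nrow(tr$manifest), 4)
  expect_true(all(tr$manifest$image_id %in% names(tr$images)))
  expect_true(all(names(tr$truth$masks) == tr$manifest$image_id))
  tr2 <- quick_trial(seed = 97, days = c(0L, 14L), n_varieties = 1)
  expect_identical(tr$manifest, tr2$manifest)
  expect_identical(tr$truth$states, tr2$truth$states)
  expect_identical(tr$images[[1]]$pixels, tr2$images[[1]]$pixels)
  expect_error(generate_trial(trial_config(n_varieties = 3, seed = 1),
                              varieties = make_varieties(2)),
               "configuration error")
})

test_that("the default design yields 180 individuals and full day x view coverage", {
  cfg <- trial_config(seed = 98)
  tr <- generate_trial(cfg, render = FALSE)
  expect_equal(nrow(tr$plants), 180)
  expect_equal(cfg$n_individuals, 180)
  expect_equal(sum(tr$plants$treatment == "unstressed"), 2 * 28 - 16)
  expect_equal(sum(tr$plants$treatment == "drought"), 5 * 28)
  expect_equal(nrow(tr$manifest), 180 * 6 * 2)
  expect_equal(nrow(tr$hand_measurements), 180 * 6)
})

test_that("ground truth stays within 10% of the simulated area with noise on", {
  tr <- cached_default_trial()
  st <- tr$truth$states
  key <- paste(st$plant_id, st$day)
  for (id in tr$manifest$image_id) {
    row <- tr$manifest[tr$manifest$image_id == id, ]
    a_true <- st$true_area_mm2[match(paste(row$plant_id, row$day), key)]
    a_mask <- sum(tr$truth$masks[[id]]) / tr$config$px_per_mm^2
    expect_lt(abs(a_mask - a_true) / a_true, 0.10)
  }
})

test_that("dropping the pre-treatment timepoint works for stage V3", {
  cfg <- trial_config(n_varieties = 1, plots_unstressed = 1, plots_treated = 1,
                      exclude_from_second_plot = 0, stage = "V3",
                      days = c(-7L, 0L, 14L), views = "vertical",
                      seed = 99, drop_pre_treatment = TRUE)
  tr <- generate_trial(cfg, render = FALSE)
  expect_false(any(tr$manifest$day < 0))
})
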