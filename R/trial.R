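# Synthetic drought-trial simulation: per-variety growth curves, a
# 14-day water-deficit treatment followed by a 14-day recovery, and
# hand-measured covariates (height, node counts) coupled to shoot area
# through a shared variety vigour factor.

#' Trial configuration
#'
#' Defaults emulate a greenhouse screen of 28 varieties grown in 7
#' randomized plots (2 unstressed, 5 drought-treated) with 16 varieties
#' excluded from the second unstressed plot, giving 180 individuals,
#' imaged at days -7, 0, +7, +14, +21, +28 relative to treatment start
#' from two camera angles.
#'
#' @param n_varieties number of varieties.
#' @param plots_unstressed,plots_treated replicate plots per treatment arm.
#' @param exclude_from_second_plot varieties dropped from the second
#'   unstressed plot (space-limited trials); 0 disables.
#' @param stage vegetative stage at treatment onset: "V2", "V3" or "V4".
#' @param days imaging days relative to treatment start, strictly increasing.
#' @param views camera angles, subset of `c("vertical", "horizontal")`.
#' @param image_size canvas (rows, cols) in pixels.
#' @param px_per_mm image scale.
#' @param seed integer root seed; all trial randomness flows from it.
#' @param growth_noise_sd lognormal sd of day-to-day biological noise on
#'   area and height (0 disables).
#' @param pixel_noise_sd per-pixel Gaussian channel noise, 8-bit levels.
#' @param lobe_color_sd per-lobe Gaussian colour jitter, 8-bit levels.
#' @param measure_sd sd of the hand height measurement error, mm.
#' @param drop_pre_treatment if `TRUE` and `stage == "V3"`, the
#'   pre-treatment timepoints are dropped (emulating missing data from
#'   facility errors).
#' @return A `trial_config` list.
#' @export
trial_config <- function(n_varieties = 28L,
                         plots_unstressed = 2L,
                         plots_treated = 5L,
                         exclude_from_second_plot = 16L,
                         stage = c("V2", "V3", "V4"),
                         days = c(-7L, 0L, 7L, 14L, 21L, 28L),
                         views = c("vertical", "horizontal"),
                         image_size = c(160L, 160L),
                         px_per_mm = 0.5,
                         seed = 1L,
                         growth_noise_sd = 0.06,
                         pixel_noise_sd = 5,
                         lobe_color_sd = 8,
                         measure_sd = 5,
                         drop_pre_treatment = FALSE) {
  stage <- match.arg(stage)
  views <- match.arg(views, c("vertical", "horizontal"), several.ok = TRUE)
  stopifnot(n_varieties > 0, plots_unstressed > 0, plots_treated > 0,
            length(days) >= 1, all(diff(days) > 0),
            length(image_size) == 2, all(image_size > 0), px_per_mm > 0,
            growth_noise_sd >= 0, pixel_noise_sd >= 0, exclude_from_second_plot >= 0)
  if (is.null(seed)) stop("trial_config requires an explicit integer seed")
  cfg <- list(n_varieties = as.integer(n_varieties),
              plots_unstressed = as.integer(plots_unstressed),
              plots_treated = as.integer(plots_treated),
              exclude_from_second_plot = as.integer(exclude_from_second_plot),
              stage = stage, days = as.integer(days), views = views,
              image_size = as.integer(image_size), px_per_mm = px_per_mm,
              seed = as.integer(seed),
              growth_noise_sd = growth_noise_sd,
              pixel_noise_sd = pixel_noise_sd,
              lobe_color_sd = lobe_color_sd,
              measure_sd = measure_sd,
              drop_pre_treatment = isTRUE(drop_pre_treatment))
  n_plots <- cfg$plots_unstressed + cfg$plots_treated
  excl <- if (cfg$plots_unstressed >= 2L) min(cfg$exclude_from_second_plot, cfg$n_varieties) else 0L
  cfg$n_individuals <- cfg$n_varieties * n_plots - excl
  class(cfg) <- "trial_config"
  cfg
}

#' Per-variety growth parameters
#'
#' @param base_area_mm2 projected shoot area at the first imaging day, mm^2.
#' @param growth_rate daily relative area growth (fraction/day).
#' @param leaf_count_mean mean number of rendered leaf lobes.
#' @param green_hue mean green-channel level of healthy leaves (0-255).
#' @param height_rate height growth, mm/day.
#' @return A `variety_params` list.
#' @export
variety_params <- function(base_area_mm2 = 2000, growth_rate = 0.04,
                           leaf_count_mean = 6, green_hue = 130,
                           height_rate = 8) {
  stopifnot(base_area_mm2 > 0, growth_rate > 0, leaf_count_mean > 0,
            green_hue >= 0, green_hue <= 255, height_rate > 0)
  structure(list(base_area_mm2 = base_area_mm2, growth_rate = growth_rate,
                 leaf_count_mean = leaf_count_mean, green_hue = green_hue,
                 height_rate = height_rate),
            class = "variety_params")
}

#' Draw a panel of varieties around the defaults
#'
#' A shared lognormal vigour factor scales both the baseline area and the
#' height rate, which is what couples image area to hand-measured height
#' across varieties.
#'
#' @param n number of varieties.
#' @param vigour_sd sd of the log vigour factor.
#' @return List of [variety_params()] objects named `V01`, `V02`, ...
#' @export
make_varieties <- function(n, vigour_sd = 0.15) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vig <- exp(stats::rnorm(1, 0, vigour_sd))
    out[[i]] <- variety_params(
      base_area_mm2 = 2000 * vig,
      growth_rate = 0.04 * exp(stats::rnorm(1, 0, 0.08)),
      leaf_count_mean = sample(4:8, 1),
      green_hue = min(255, max(0, stats::rnorm(1, 130, 6))),
      height_rate = 8 * vig * exp(stats::rnorm(1, 0, 0.05)))
  }
  names(out) <- sprintf("V%02d", seq_len(n))
  out
}

#' Drought-stress model
#'
#' During the treatment window the expected area of treated plants falls
#' behind the unstressed trajectory by `area_shrink_per_day` per day, and
#' the leaf colour drifts along the green-red axis toward yellow by
#' `yellowing_per_day` levels per day. During recovery the area deficit
#' closes at `recovery_rate` per day (never overshooting) and the colour
#' shift decays exponentially. A model with zero shrink and zero yellowing
#' is observationally identical to no treatment.
#'
#' @param area_shrink_per_day fraction in \[0, 1\].
#' @param yellowing_per_day channel levels/day on the green-red axis.
#' @param recovery_rate fraction/day by which the area deficit closes.
#' @param treatment_days,recovery_days window lengths, days.
#' @param color_recovery_decay exponential decay rate of the colour shift
#'   during recovery (/day); slow by default because chlorotic mature
#'   tissue does not re-green -- recovery dilutes it with new growth.
#' @param wilt_coupling dimensionless canopy-compaction per unit relative
#'   area loss: wilted plants droop into a more compact silhouette, and
#'   regrown plants keep part of that habit (decaying at
#'   `color_recovery_decay`). Proportional to the accumulated shrink, so
#'   a zero-shrink model stays observationally identical to no treatment.
#' @return A `stress_model` list.
#' @export
stress_model <- function(area_shrink_per_day = 0.05, yellowing_per_day = 3,
                         recovery_rate = 0.04, treatment_days = 14L,
                         recovery_days = 14L, color_recovery_decay = 0.03,
                         wilt_coupling = 0.8) {
  stopifnot(area_shrink_per_day >= 0, area_shrink_per_day <= 1,
            recovery_rate >= 0, recovery_rate <= 1,
            treatment_days >= 0, recovery_days >= 0, yellowing_per_day >= 0,
            wilt_coupling >= 0)
  structure(list(area_shrink_per_day = area_shrink_per_day,
                 yellowing_per_day = yellowing_per_day,
                 recovery_rate = recovery_rate,
                 treatment_days = as.integer(treatment_days),
                 recovery_days = as.integer(recovery_days),
                 color_recovery_decay = color_recovery_decay,
                 wilt_coupling = wilt_coupling),
            class = "stress_model")
}

# log-area deficit of a treated plant at `day` (0 at/before treatment start)
.stress_deficit <- function(stress, day) {
  s_d <- min(max(day, 0), stress$treatment_days)
  r_d <- min(max(day - stress$treatment_days, 0), stress$recovery_days)
  d <- s_d * log(1 - stress$area_shrink_per_day)
  if (r_d > 0) d <- min(0, d + r_d * log(1 + stress$recovery_rate))
  d
}

# green-red colour shift (8-bit levels) of a treated plant at `day`
.color_shift <- function(stress, day) {
  s_d <- min(max(day, 0), stress$treatment_days)
  shift <- stress$yellowing_per_day * s_d
  t_rec <- max(day - stress$treatment_days, 0)
  if (t_rec > 0) shift <- shift * exp(-stress$color_recovery_decay * t_rec)
  shift
}

# canopy-compaction (wilt) fraction of a treated plant at `day`:
# proportional to the accumulated relative area loss, fading by dilution
# with new growth at the colour-recovery rate
.wilt_fraction <- function(stress, day) {
  s_d <- min(max(day, 0), stress$treatment_days)
  w <- stress$wilt_coupling * (1 - (1 - stress$area_shrink_per_day)^s_d)
  t_rec <- max(day - stress$treatment_days, 0)
  if (t_rec > 0) w <- w * exp(-stress$color_recovery_decay * t_rec)
  min(w, 0.95)
}

#' Simulate the true state of one plant on one day
#'
#' Unstressed plants grow multiplicatively at the variety growth rate from
#' the trial start (`day0`). Treated plants accumulate a log-area deficit
#' of `log(1 - area_shrink_per_day)` per treatment day, which closes at
#' `log(1 + recovery_rate)` per recovery day (clamped at zero). Height
#' grows linearly at the variety rate and carries half of the area
#' log-deficit; node counts are Poisson around a stage-dependent mean and
#' stall during treatment. Draws from the current RNG stream; seed the
#' stream for reproducibility.
#'
#' @param variety a [variety_params()].
#' @param stress a [stress_model()].
#' @param treated logical.
#' @param day observation day relative to treatment start.
#' @param stage vegetative stage label ("V2", "V3", "V4").
#' @param day0 first observed day (growth reference).
#' @param noise_sd lognormal sd of biological noise on area and height.
#' @return A `plant_state` list.
#' @export
simulate_growth <- function(variety, stress, treated, day, stage = "V2",
                            day0 = -7, noise_sd = 0) {
  day_max <- stress$treatment_days + stress$recovery_days
  if (day < day0 || day > day_max) {
    stop(sprintf("day %s outside the configured range [%s, %s]",
                 day, day0, day_max))
  }
  deficit <- if (treated) .stress_deficit(stress, day) else 0
  shift <- if (treated) .color_shift(stress, day) else 0
  wilt <- if (treated) .wilt_fraction(stress, day) else 0
  gdays <- day - day0

  area <- variety$base_area_mm2 * (1 + variety$growth_rate)^gdays * exp(deficit)
  if (noise_sd > 0) area <- area * exp(stats::rnorm(1, 0, noise_sd))

  height <- (80 + variety$height_rate * gdays) * exp(0.5 * deficit)
  if (noise_sd > 0) height <- height * exp(stats::rnorm(1, 0, noise_sd))

  stage_base <- c(V2 = 2, V3 = 3, V4 = 4)[[stage]]
  stalled <- if (treated && stress$area_shrink_per_day > 0) {
    min(max(day, 0), stress$treatment_days)
  } else 0
  mean_main <- stage_base + 0.25 * max(gdays - stalled, 0)
  node_main <- stats::rpois(1, mean_main)
  node_total <- node_main + stats::rpois(1, 0.6 * mean_main)

  # chlorosis: pale-yellowing of leaf tissue -- red rises, green rises
  # slightly, blue falls (yellow = R+G against B), lightness increases
  col <- c(r = 55 + shift,
           g = variety$green_hue + 0.15 * shift,
           b = 45 - 0.3 * shift)
  col <- pmin(pmax(col, 0), 255)

  structure(list(day = day, true_area_mm2 = area, true_height_mm = height,
                 node_count_main = node_main, node_count_total = node_total,
                 mean_leaf_color = col, color_shift = shift, wilt = wilt,
                 treated = treated, stage = stage),
            class = "plant_state")
}
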