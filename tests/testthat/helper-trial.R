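# Shared small trials, built once per test session and cached.

.trial_cache <- new.env(parent = emptyenv())

# scaled default trial: 8 varieties x 7 plots = 56 plants, two days, both
# views (224 images) -- the workhorse for segmentation-recovery and the
# geometric containment invariants
cached_default_trial <- function() {
  if (is.null(.trial_cache$default)) {
    cfg <- trial_config(n_varieties = 8, exclude_from_second_plot = 0,
                        days = c(0L, 14L), views = c("vertical", "horizontal"),
                        seed = 2024)
    .trial_cache$default <- generate_trial(cfg)
  }
  .trial_cache$default
}

cached_default_traits <- function() {
  if (is.null(.trial_cache$traits)) {
    .trial_cache$traits <- suppressWarnings(suppressMessages(
      trial_trait_table(cached_default_trial())))
  }
  .trial_cache$traits
}

# small single-view trial for quick tests
quick_trial <- function(seed = 7, days = c(-7L, 0L, 14L), n_varieties = 2,
                        views = "vertical", ...) {
  generate_trial(trial_config(n_varieties = n_varieties, plots_unstressed = 1,
                              plots_treated = 1, exclude_from_second_plot = 0,
                              days = days, views = views, seed = seed, ...))
}

# trait table built directly from simulated states (no rendering): used
# for statistical calibration over many replicate trials
state_trait_long <- function(config, stress, varieties = NULL) {
  tr <- generate_trial(config, varieties = varieties, stress = stress,
                       render = FALSE)
  st <- tr$truth$states
  do.call(rbind, lapply(
    c("true_area_mm2", "true_height_mm", "node_count_main"),
    function(tn) data.frame(
      plant_id = st$plant_id, variety = st$variety, treatment = st$treatment,
      stage = st$stage, day = st$day, view = "state", trait_name = tn,
      value = st[[tn]], stringsAsFactors = FALSE)))
}
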