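# Trial-level generation: plants x days x views, with manifest,
# ground-truth tables/masks and hand measurements.

#' Generate a synthetic drought trial
#'
#' Assigns varieties to randomized plots (plot treatment labels are
#' shuffled from the seed), simulates every plant's state on every
#' imaging day, and (optionally) renders every (plant, day, view) image
#' with its ground-truth mask. The whole dataset is a pure function of
#' `(config, varieties, stress)`: the root seed lives in the config.
#'
#' @param config a [trial_config()].
#' @param varieties list of [variety_params()], one per variety; drawn
#'   with [make_varieties()] when missing.
#' @param stress a [stress_model()].
#' @param render if `FALSE`, skip image rendering and return states,
#'   manifest and hand measurements only (used for statistical
#'   calibration runs that need many replicate trials).
#' @return A `shoot_trial` list: `config`, `stress`, `varieties`, `plants`
#'   (data frame), `manifest`, `truth` (`states` data frame + `masks`
#'   list), `images` (named list of [plant_image]), `hand_measurements`.
#' @export
generate_trial <- function(config = trial_config(), varieties = NULL,
                           stress = stress_model(), render = TRUE) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  if (is.null(varieties)) varieties <- make_varieties(config$n_varieties)
  if (length(varieties) != config$n_varieties) {
    stop(sprintf("configuration error: %d varieties supplied for n_varieties = %d",
                 length(varieties), config$n_varieties))
  }
  if (is.null(names(varieties))) names(varieties) <- sprintf("V%02d", seq_along(varieties))

  n_plots <- config$plots_unstressed + config$plots_treated
  plot_treatment <- sample(rep(c("unstressed", "drought"),
                               c(config$plots_unstressed, config$plots_treated)))
  unstressed_plots <- which(plot_treatment == "unstressed")

  # plant roster: every (variety, plot), minus the varieties excluded from
  # the second unstressed plot in space-limited designs
  plants <- expand.grid(variety = names(varieties), plot = seq_len(n_plots),
                        stringsAsFactors = FALSE)
  excl <- config$exclude_from_second_plot
  if (excl > 0L && length(unstressed_plots) >= 2L) {
    second <- unstressed_plots[2L]
    drop_vars <- utils::tail(names(varieties), min(excl, config$n_varieties))
    plants <- plants[!(plants$plot == second & plants$variety %in% drop_vars), ]
  }
  plants$plant_id <- sprintf("P%03d", seq_len(nrow(plants)))
  plants$treatment <- plot_treatment[plants$plot]
  plants$stage <- config$stage
  rownames(plants) <- NULL

  days <- config$days
  if (config$drop_pre_treatment && config$stage == "V3") days <- days[days >= 0]

  # persistent per-(plant, view) lobe layouts
  layouts <- list()
  for (i in seq_len(nrow(plants))) {
    vp <- varieties[[plants$variety[i]]]
    for (v in config$views) {
      layouts[[paste(plants$plant_id[i], v, sep = ".")]] <-
        make_lobe_layout(vp$leaf_count_mean, v, config$lobe_color_sd)
    }
  }

  states <- list(); hand <- list(); manifest <- list()
  images <- list(); masks <- list()
  row <- 0L
  for (i in seq_len(nrow(plants))) {
    pid <- plants$plant_id[i]
    vp <- varieties[[plants$variety[i]]]
    treated <- plants$treatment[i] == "drought"
    for (d in days) {
      st <- simulate_growth(vp, stress, treated, d, stage = config$stage,
                            day0 = config$days[1], noise_sd = config$growth_noise_sd)
      states[[length(states) + 1L]] <- data.frame(
        plant_id = pid, variety = plants$variety[i], plot = plants$plot[i],
        treatment = plants$treatment[i], stage = config$stage, day = d,
        true_area_mm2 = st$true_area_mm2, true_height_mm = st$true_height_mm,
        node_count_main = st$node_count_main,
        node_count_total = st$node_count_total,
        color_shift = st$color_shift, stringsAsFactors = FALSE)
      hand[[length(hand) + 1L]] <- data.frame(
        plant_id = pid, day = d,
        height_mm = st$true_height_mm + stats::rnorm(1, 0, config$measure_sd),
        node_count_main = st$node_count_main,
        node_count_total = st$node_count_total, stringsAsFactors = FALSE)
      for (v in config$views) {
        row <- row + 1L
        image_id <- paste(pid, d, v, sep = "_")
        manifest[[row]] <- data.frame(
          image_id = image_id, plant_id = pid, variety = plants$variety[i],
          plot = plants$plot[i], treatment = plants$treatment[i],
          stage = config$stage, day = d, view = v,
          image_path = paste0(image_id, ".png"), stringsAsFactors = FALSE)
        if (render) {
          rp <- render_plant(st, v, config, plant_id = pid,
                             layout = layouts[[paste(pid, v, sep = ".")]])
          rp$image$variety <- plants$variety[i]
          images[[image_id]] <- rp$image
          masks[[image_id]] <- rp$mask
        }
      }
    }
  }

  structure(list(config = config, stress = stress, varieties = varieties,
                 plants = plants,
                 manifest = do.call(rbind, manifest),
                 truth = list(states = do.call(rbind, states), masks = masks),
                 images = images,
                 hand_measurements = do.call(rbind, hand)),
            class = "shoot_trial")
}

#' @export
print.shoot_trial <- function(x, ...) {
  cat(sprintf("<shoot_trial: %d plants, days %s, views %s, %d images>\n",
              nrow(x$plants), paste(unique(x$truth$states$day), collapse = "/"),
              paste(x$config$views, collapse = "+"), length(x$images)))
  invisible(x)
}

#' Write a trial to disk as PNG images plus CSV tables
#'
#' Images are 8-bit RGB PNGs, truth masks single-channel 0/255 PNGs, and
#' the manifest / hand-measurement tables CSVs with headers.
#'
#' @param trial a `shoot_trial`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (id in names(trial$images)) {
    png::writePNG(aperm(trial$images[[id]]$pixels, c(1, 2, 3)) / 255,
                  file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(matrix(as.numeric(trial$truth$masks[[id]]),
                         nrow(trial$truth$masks[[id]])),
                  file.path(dir, "masks", paste0(id, ".png")))
  }
  utils::write.csv(trial$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(trial$hand_measurements, file.path(dir, "hand_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$truth$states, file.path(dir, "truth_states.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a plant image back from PNG
#'
#' @param path PNG file path.
#' @param ... metadata fields passed to [plant_image()].
#' @return A [plant_image].
#' @export
read_plant_png <- function(path, ...) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  plant_image(a[, , 1:3] * 255, ...)
}
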