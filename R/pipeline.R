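# End-to-end orchestration: simulate -> preprocess -> segment -> extract
# -> filter -> screen -> embed, as one reproducible, configured run.
#
# Stage boundaries follow the four-process scheme of phenotyping
# facilities (data acquisition / preprocessing / data processing / data
# analysis); intermediate artifacts are plain data frames (and plain
# files when an output directory is given) so any stage can be inspected
# or replaced. All randomness flows from one root seed, split per stage
# by fixed offsets: simulation uses `seed`, embeddings `seed + 1000`.

#' Default pipeline configuration
#'
#' @param seed root seed (required; every stochastic stage derives from it).
#' @param trial named list of [trial_config()] overrides.
#' @param stress named list of [stress_model()] overrides.
#' @param segmentation named list of [segment_params()] overrides.
#' @param color_mode `"lab8"` or `"rgb"`.
#' @param stats list with `taus` (outlier quantiles), `alpha_hand`,
#'   `alpha_image`.
#' @param embedding list with `perplexity`, `max_iter`, `views`,
#'   `timepoints` (days to embed; `NULL` = all).
#' @param out_dir optional directory for CSV/PNG artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, trial = list(), stress = list(),
                            segmentation = list(),
                            color_mode = c("lab8", "rgb"),
                            stats = list(taus = c(0.05, 0.95),
                                         alpha_hand = 0.05, alpha_image = 0.005),
                            embedding = list(perplexity = 30, max_iter = 600,
                                             timepoints = NULL),
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed)) {
    stop("validation error: pipeline_config requires a root `seed`")
  }
  color_mode <- match.arg(color_mode)
  stopifnot(is.list(trial), is.list(stress), is.list(segmentation))
  trial$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed),
              trial = do.call(trial_config, trial),
              stress = do.call(stress_model, stress),
              segmentation = do.call(segment_params, segmentation),
              color_mode = color_mode, stats = stats,
              embedding = embedding, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("validation error: config is missing `seed`")
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  trial_fields <- unclass(config$trial)
  trial_fields$n_individuals <- NULL   # derived, recomputed on read
  y <- list(seed = config$seed,
            trial = trial_fields, stress = unclass(config$stress),
            segmentation = config$segmentation, color_mode = config$color_mode,
            stats = config$stats, embedding = config$embedding)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full phenotyping pipeline on a synthetic trial
#'
#' Executes, in order: trial simulation (data acquisition), obstacle
#' exclusion (preprocessing), segmentation + trait extraction (data
#' processing), quantile-regression outlier filtering, Kruskal-Wallis
#' screening by treatment and by variety, and per-timepoint embeddings
#' (data analysis). Each stage's outputs are returned (and written as CSV
#' when `out_dir` is set) together with a run manifest of row counts and
#' warnings.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_run` list: `trial`, `traits` (wide), `jaccard`,
#'   `filtered` (long), `outlier_report`, `screening` (image-trait
#'   screening table), `screening_hand`, `embeddings`, `validation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("expected a pipeline_config")
  warnings_log <- character(0)
  note <- function(stage, w) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, conditionMessage(w)))
    invokeRestart("muffleWarning")
  }
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   version = as.character(utils::packageVersion("shootpheno")))

  # --- stage 1: data acquisition (simulation) ----------------------------
  trial <- generate_trial(config$trial, stress = config$stress)
  manifest$n_plants <- nrow(trial$plants)
  manifest$n_images <- length(trial$images)

  # --- stages 2-3: preprocessing + data processing -----------------------
  traits <- withCallingHandlers(
    trial_trait_table(trial, params = config$segmentation,
                      color_mode = config$color_mode),
    warning = function(w) note("extract", w))
  jac <- attr(traits, "jaccard")
  manifest$n_trait_rows <- nrow(traits)
  manifest$median_jaccard <- stats::median(jac, na.rm = TRUE)

  # --- stage 4: data analysis --------------------------------------------
  long <- traits_to_long(traits)
  filt <- withCallingHandlers(
    quantile_outlier_filter(long, taus = config$stats$taus),
    warning = function(w) note("filter", w))
  manifest$n_outliers_removed <- sum(filt$report$flags$removed)

  screening <- withCallingHandlers(
    build_screening_tables(filt$table, grouping = c("treatment", "variety"),
                           alpha = config$stats$alpha_image),
    warning = function(w) note("screen", w))

  hand <- trial$hand_measurements
  hand_long <- do.call(rbind, lapply(
    c("height_mm", "node_count_main", "node_count_total"),
    function(tn) data.frame(
      plant_id = hand$plant_id,
      variety = trial$plants$variety[match(hand$plant_id, trial$plants$plant_id)],
      treatment = trial$plants$treatment[match(hand$plant_id, trial$plants$plant_id)],
      stage = config$trial$stage, day = hand$day, view = "hand",
      trait_name = tn, value = hand[[tn]], stringsAsFactors = FALSE)))
  screening_hand <- withCallingHandlers(
    build_screening_tables(hand_long, grouping = "treatment",
                           alpha = config$stats$alpha_hand),
    warning = function(w) note("screen_hand", w))

  emb_days <- config$embedding$timepoints
  if (is.null(emb_days)) emb_days <- sort(unique(traits$day))
  embeddings <- list()
  eseed <- config$seed + 1000L
  for (d in emb_days) {
    for (v in config$trial$views) {
      fm <- withCallingHandlers(
        suppressMessages(feature_matrix(traits, "all13", day = d, view = v)),
        warning = function(w) note("embed", w))
      if (nrow(fm) < 4) next
      key <- sprintf("day%+d_%s", d, v)
      pca <- pca_embed(fm)
      ts <- if (config$embedding$perplexity < nrow(fm) / 3) {
        tsne_embed(fm, perplexity = config$embedding$perplexity,
                   seed = eseed, max_iter = config$embedding$max_iter)
      } else NULL
      embeddings[[key]] <- list(
        day = d, view = v, pca = pca, tsne = ts,
        timepoint = timepoint_class(d, config$stress),
        silhouette_pca = cluster_separation(pca),
        silhouette_tsne = if (is.null(ts)) NA_real_ else cluster_separation(ts))
    }
  }

  validation <- validate_against_truth(traits, trial)
  manifest$warnings <- warnings_log
  manifest$finished <- format(Sys.time())

  run <- structure(list(trial = trial, traits = traits, jaccard = jac,
                        filtered = filt$table, outlier_report = filt$report,
                        screening = screening, screening_hand = screening_hand,
                        embeddings = embeddings, validation = validation,
                        manifest = manifest, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

.write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(run$filtered, file.path(dir, "traits_filtered.csv"), row.names = FALSE)
  utils::write.csv(run$screening, file.path(dir, "screening_image.csv"), row.names = FALSE)
  utils::write.csv(run$screening_hand, file.path(dir, "screening_hand.csv"), row.names = FALSE)
  utils::write.csv(run$outlier_report$flags, file.path(dir, "outlier_flags.csv"), row.names = FALSE)
  emb <- do.call(rbind, lapply(names(run$embeddings), function(k) {
    e <- run$embeddings[[k]]
    if (is.null(e$tsne)) return(NULL)
    data.frame(key = k, day = e$day, view = e$view,
               plant_id = attr(e$tsne$coordinates, "plant_id") %||%
                 seq_len(nrow(e$tsne$coordinates)),
               tsne1 = e$tsne$coordinates[, 1], tsne2 = e$tsne$coordinates[, 2],
               treatment = e$tsne$labels, stringsAsFactors = FALSE)
  }))
  if (!is.null(emb)) utils::write.csv(emb, file.path(dir, "embeddings.csv"), row.names = FALSE)
  write_pipeline_config(run$config, file.path(dir, "config_resolved.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate image-derived traits against simulated ground truth
#'
#' Pearson correlations between the image-based area and the simulated
#' true area, hand-measured height and node counts per view, plus a
#' segmentation Jaccard summary. Ids present on one side only raise a
#' reconciliation error listing the orphans.
#'
#' @param traits wide trait table.
#' @param trial the generating `shoot_trial`.
#' @return A `validation_report` data frame plus a `jaccard` summary
#'   attribute.
#' @export
validate_against_truth <- function(traits, trial) {
  truth <- trial$truth$states
  key_t <- paste(traits$plant_id, traits$day)
  key_s <- paste(truth$plant_id, truth$day)
  orphans <- setdiff(unique(key_t), unique(key_s))
  if (length(orphans) > 0) {
    stop(sprintf("reconciliation error: %d trait row key(s) missing from truth: %s",
                 length(orphans),
                 paste(utils::head(orphans, 5), collapse = ", ")))
  }
  hand <- trial$hand_measurements
  key_h <- paste(hand$plant_id, hand$day)
  rows <- list()
  for (v in unique(traits$view)) {
    sub <- traits[traits$view == v, ]
    k <- paste(sub$plant_id, sub$day)
    m <- match(k, key_s); mh <- match(k, key_h)
    rows[[v]] <- data.frame(
      view = v, stage = trial$config$stage, n = nrow(sub),
      r_true_area = pearson_correlation(sub$area, truth$true_area_mm2[m]),
      r_height = pearson_correlation(sub$area, hand$height_mm[mh]),
      r_node_main = pearson_correlation(sub$area, hand$node_count_main[mh]),
      r_node_total = pearson_correlation(sub$area, hand$node_count_total[mh]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  jac <- attr(traits, "jaccard")
  attr(out, "jaccard") <- if (is.null(jac)) NULL else
    c(median = stats::median(jac, na.rm = TRUE), min = min(jac, na.rm = TRUE))
  class(out) <- c("validation_report", class(out))
  out
}
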