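# Rendering of synthetic plant images: shoots as unions of overlapping
# elliptical leaf lobes over background, pot and support-strut clutter,
# with a pixel-exact ground-truth foreground mask.

#' Construct a plant image
#'
#' @param pixels H x W x 3 numeric array, 8-bit channel levels.
#' @param view `"vertical"` or `"horizontal"`.
#' @param plant_id,variety,treatment,stage,day metadata labels.
#' @param px_per_mm image scale, pixels per millimetre.
#' @return A `plant_image` object.
#' @export
plant_image <- function(pixels, view = "vertical", plant_id = "plant",
                        variety = NA, treatment = NA, stage = NA, day = NA,
                        px_per_mm = 1) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L, px_per_mm > 0)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("channel levels must lie in [0, 255]")
  }
  structure(list(pixels = pixels, view = view, plant_id = plant_id,
                 variety = variety, treatment = treatment, stage = stage,
                 day = day, px_per_mm = px_per_mm),
            class = "plant_image")
}

#' @export
print.plant_image <- function(x, ...) {
  cat(sprintf("<plant_image %s  %dx%d  view=%s day=%s px/mm=%.3g>\n",
              x$plant_id, dim(x$pixels)[1], dim(x$pixels)[2],
              x$view, as.character(x$day), x$px_per_mm))
  invisible(x)
}

# palette shared by the renderer and the default obstacle rules
.scene_colors <- list(background = c(40, 38, 42),
                      pot = c(115, 82, 60),
                      strut = c(228, 228, 222))

#' Draw a persistent leaf-lobe layout for one plant
#'
#' The layout (lobe positions, axes, orientations and colour jitters, in
#' unit coordinates) is drawn once per plant and reused across days so a
#' plant keeps its shape while growing; only the overall scale follows
#' the simulated area. Consumes the current RNG stream.
#'
#' @param n_lobes number of elliptical lobes (clamped to 3..9).
#' @param view camera angle; side views spread lobes upward from a stem.
#' @param lobe_color_sd per-lobe colour jitter sd, levels.
#' @return A `lobe_layout` list.
#' @export
make_lobe_layout <- function(n_lobes = 6, view = "vertical",
                             lobe_color_sd = 8) {
  n <- max(3L, min(9L, as.integer(round(n_lobes))))
  ang <- stats::runif(n, 0, 2 * pi)
  if (view == "horizontal") {
    # side view: lobes mostly above the stem (smaller row = up)
    ang <- pi + stats::runif(n, 0.1, pi - 0.1)  # sin(ang) <= 0 -> dy up
  } else {
    ang <- sort(ang)
  }
  structure(list(
    n = n,
    angle = ang,
    dist = stats::runif(n, 0.25, 0.85),
    a = stats::runif(n, 0.45, 0.75),   # radial semi-axis, unit scale
    b = stats::runif(n, 0.25, 0.45),   # tangential semi-axis
    tilt = stats::rnorm(n, 0, 0.25),   # orientation jitter about radial
    color_jitter = matrix(stats::rnorm(3 * n, 0, lobe_color_sd), ncol = 3),
    patch_w = stats::runif(n, -1, 1)  # per-lobe chlorosis patchiness:
                                      # some lobes stay green, some reach
                                      # twice the mean shift

  ), class = "lobe_layout")
}

# rasterize one ellipse onto a logical mask (pixel centers)
.add_ellipse <- function(mask, cy, cx, a, b, theta) {
  nr <- nrow(mask); nc <- ncol(mask)
  ext <- max(a, b)
  rs <- max(1, floor(cy - ext)):min(nr, ceiling(cy + ext))
  cs <- max(1, floor(cx - ext)):min(nc, ceiling(cx + ext))
  if (length(rs) == 0 || length(cs) == 0) return(list(mask = mask, idx = NULL))
  dy <- matrix(rep(rs - cy, times = length(cs)), nrow = length(rs))
  dx <- matrix(rep(cs - cx, each = length(rs)), nrow = length(rs))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  hit <- u * u + v * v <= 1
  sub <- mask[rs, cs, drop = FALSE]
  mask[rs, cs] <- sub | hit
  # linear indices of the hit pixels in the full mask
  hi <- which(hit, arr.ind = TRUE)
  idx <- (cs[hi[, 2]] - 1L) * nr + rs[hi[, 1]]
  list(mask = mask, idx = idx)
}

# rasterize the lobe union at a given scale; returns mask + per-lobe indices
.rasterize_lobes <- function(layout, scale, center, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  lobe_idx <- vector("list", layout$n)
  for (i in seq_len(layout$n)) {
    cy <- center[1] + scale * layout$dist[i] * sin(layout$angle[i])
    cx <- center[2] + scale * layout$dist[i] * cos(layout$angle[i])
    res <- .add_ellipse(mask, cy, cx,
                        a = scale * layout$a[i], b = scale * layout$b[i],
                        theta = layout$angle[i] + layout$tilt[i])
    mask <- res$mask
    lobe_idx[[i]] <- res$idx
  }
  list(mask = mask, lobe_idx = lobe_idx)
}

#' Render one plant image with its ground-truth mask
#'
#' The shoot is drawn as the union of the layout's elliptical lobes,
#' scaled so that the foreground pixel count matches
#' `true_area_mm2 * px_per_mm^2` (two secant corrections on the scale; the
#' residual mismatch is rasterization jitter of a few percent). Background,
#' a pot (annulus in vertical view, bottom block in horizontal view) and a
#' near-white support strut are drawn first; leaves are drawn on top, so
#' the truth mask marks exactly the visible leaf pixels.
#'
#' @param state a `plant_state` from [simulate_growth()].
#' @param view `"vertical"` or `"horizontal"`.
#' @param config a [trial_config()] (canvas size, scale, noise levels).
#' @param plant_id label used in messages and metadata.
#' @param layout optional persistent [make_lobe_layout()]; drawn from the
#'   RNG when missing.
#' @return List with `image` (a [plant_image]) and `mask` (logical truth
#'   matrix marking leaf pixels).
#' @export
render_plant <- function(state, view = c("vertical", "horizontal"),
                         config = trial_config(), plant_id = "plant",
                         layout = NULL) {
  view <- match.arg(view)
  shape <- config$image_size
  ppm <- config$px_per_mm
  if (is.null(layout)) layout <- make_lobe_layout(6, view, config$lobe_color_sd)
  # wilt compaction: lobes droop toward the center and broaden, giving a
  # denser silhouette at the same projected area
  w <- if (is.null(state$wilt)) 0 else state$wilt
  if (w > 0) {
    layout$dist <- layout$dist * (1 - 0.5 * w)
    layout$b <- layout$b * (1 + 0.25 * w)
  }
  target_px <- state$true_area_mm2 * ppm^2

  center <- if (view == "vertical") shape / 2 else c(0.45 * shape[1], 0.5 * shape[2])

  # --- scale search -------------------------------------------------------
  mask <- matrix(FALSE, shape[1], shape[2])
  lobes <- list(mask = mask, lobe_idx = vector("list", layout$n))
  if (target_px >= 0.5) {
    est_unit <- 0.70 * sum(pi * layout$a * layout$b)
    s <- sqrt(target_px / est_unit)
    max_reach <- max(layout$dist + pmax(layout$a, layout$b))
    fit_limit <- 0.49 * min(shape)
    if (s * max_reach > fit_limit) {
      stop(sprintf("plant '%s' does not fit the canvas (needs %.0f px reach, limit %.0f)",
                   plant_id, s * max_reach, fit_limit))
    }
    for (it in 1:3) {
      lobes <- .rasterize_lobes(layout, s, center, shape)
      cnt <- sum(lobes$mask)
      if (cnt == 0) { s <- s * 1.5; next }
      if (abs(cnt - target_px) / target_px < 0.01) break
      s <- s * sqrt(target_px / cnt)
      if (s * max_reach > fit_limit) {
        stop(sprintf("plant '%s' does not fit the canvas (needs %.0f px reach, limit %.0f)",
                     plant_id, s * max_reach, fit_limit))
      }
    }
    mask <- lobes$mask
  }

  # --- scene --------------------------------------------------------------
  nr <- shape[1]; nc <- shape[2]
  px <- array(0, dim = c(nr, nc, 3))
  for (k in 1:3) px[, , k] <- .scene_colors$background[k]

  if (view == "vertical") {
    rr <- row(px[, , 1]) - center[1]; cc <- col(px[, , 1]) - center[2]
    rad <- sqrt(rr^2 + cc^2)
    ring <- rad >= 0.82 * min(shape) / 2 & rad <= 0.96 * min(shape) / 2
    for (k in 1:3) { b <- px[, , k]; b[ring] <- .scene_colors$pot[k]; px[, , k] <- b }
    strut_rows <- pmax(1, round(center[1]) + (-1:1))
    for (k in 1:3) px[strut_rows, , k] <- .scene_colors$strut[k]
  } else {
    pot_rows <- max(1, round(0.86 * nr)):nr
    pot_cols <- round(0.28 * nc):round(0.72 * nc)
    for (k in 1:3) px[pot_rows, pot_cols, k] <- .scene_colors$pot[k]
    strut_cols <- pmax(1, round(center[2]) + (-1:1))
    strut_rows <- round(0.12 * nr):round(0.86 * nr)
    for (k in 1:3) px[strut_rows, strut_cols, k] <- .scene_colors$strut[k]
  }

  # leaves on top: later lobes overwrite earlier ones in overlaps
  base_col <- state$mean_leaf_color
  shift <- state$color_shift
  for (i in seq_len(layout$n)) {
    idx <- lobes$lobe_idx[[i]]
    if (is.null(idx) || length(idx) == 0) next
    lc <- base_col + layout$color_jitter[i, ]
    p <- layout$patch_w[i] * shift                      # patchy chlorosis
    lc[1] <- lc[1] + p
    lc[2] <- lc[2] + 0.15 * p
    lc[3] <- lc[3] - 0.3 * p
    lc <- pmin(pmax(lc, 0), 255)
    plane <- nr * nc
    px[idx] <- lc[1]; px[idx + plane] <- lc[2]; px[idx + 2 * plane] <- lc[3]
  }

  if (config$pixel_noise_sd > 0) {
    px <- px + array(stats::rnorm(length(px), 0, config$pixel_noise_sd), dim = dim(px))
  }
  px <- pmin(pmax(px, 0), 255)

  img <- plant_image(px, view = view, plant_id = plant_id,
                     treatment = if (isTRUE(state$treated)) "drought" else "unstressed",
                     stage = state$stage, day = state$day, px_per_mm = ppm)
  list(image = img, mask = mask)
}

#' Default obstacle-exclusion rules for the synthetic scenes
#'
#' Colour boxes matching the renderer's pot and strut palettes (with a
#' margin for pixel noise) plus, for side views, the fixed pot zone at the
#' bottom of the frame; the leaf colour box is declared as protected
#' foreground.
#'
#' @param view camera angle the rules apply to.
#' @return An `obstacle_rules` list understood by [exclude_obstacles()].
#' @export
default_obstacle_rules <- function(view = "vertical") {
  rules <- list(
    color_boxes = list(
      pot = list(min = .scene_colors$pot - 22, max = .scene_colors$pot + 22),
      strut = list(min = .scene_colors$strut - 25, max = c(255, 255, 255))),
    zones = list(),
    foreground_box = list(min = c(0, 90, 0), max = c(150, 220, 110)))
  if (view == "horizontal") {
    rules$zones <- list(pot_zone = list(rows = c(0.86, 1), cols = c(0, 1)))
  }
  class(rules) <- "obstacle_rules"
  rules
}
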