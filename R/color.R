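# Colour traits: channel conversion and within-ROI channel variances.
#
# Two channel semantics are first-class:
#  * "rgb"  - raw R, G, B bands;
#  * "lab8" - opponent axes (lightness; green-red; blue-yellow) affinely
#    mapped onto 0-255 with neutral gray near level 128. On the green-red
#    axis levels below neutral are green-biased and above are red-biased;
#    on the blue-yellow axis below is blue and above yellow. This is the
#    default because the band descriptions "0 = green, 255 = red about a
#    neutral near 126" describe an opponent space rather than raw RGB.

#' Convert an RGB image into three analysis channels
#'
#' @param image a [plant_image] (or H x W x 3 array, levels 0-255).
#' @param mode `"lab8"` (default; opponent axes via CIE Lab, D65) or
#'   `"rgb"` (raw bands, identical to [split_channels()]).
#' @return List of three H x W matrices with levels in \[0, 255\]:
#'   `ch1` (brightness / R), `ch2` (green-red / G), `ch3` (blue-yellow / B).
#' @export
convert_channels <- function(image, mode = c("lab8", "rgb")) {
  mode <- match.arg(mode)
  bands <- split_channels(image)
  if (mode == "rgb") {
    return(list(ch1 = bands$r, ch2 = bands$g, ch3 = bands$b, mode = "rgb"))
  }
  d <- dim(bands$r)
  rgb01 <- cbind(as.vector(bands$r), as.vector(bands$g), as.vector(bands$b)) / 255
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  clamp <- function(x) pmin(pmax(x, 0), 255)
  list(ch1 = matrix(clamp(lab[, 1] * 2.55), d[1], d[2]),
       ch2 = matrix(clamp(lab[, 2] + 128), d[1], d[2]),
       ch3 = matrix(clamp(lab[, 3] + 128), d[1], d[2]),
       mode = "lab8")
}

#' Population variance of a channel over the ROI
#'
#' Only ROI pixels contribute; anything outside the ROI (background,
#' excluded obstacles) is ignored entirely. The population estimator
#' (divide by n) is used: ROIs hold thousands of pixels and the choice
#' makes small-ROI tests exact.
#'
#' @param channel numeric matrix of levels.
#' @param roi logical matrix of the same shape.
#' @return Variance in squared levels; `NA_real_` for an empty ROI.
#' @export
channel_variance <- function(channel, roi) {
  stopifnot(identical(dim(channel), dim(roi)))
  v <- channel[roi]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  mean((v - mean(v))^2)
}

#' The three colour-variance traits of a segmented image
#'
#' @param image a [plant_image].
#' @param roi logical ROI matrix (from [segment()]).
#' @param mode channel semantics, see [convert_channels()].
#' @return Named numeric vector `mean_color_red_variance`,
#'   `mean_color_green_variance`, `mean_color_blue_variance` (the
#'   conventional trait names; under `lab8` they are the brightness,
#'   green-red and blue-yellow axis variances).
#' @export
color_trait_variances <- function(image, roi, mode = c("lab8", "rgb")) {
  mode <- match.arg(mode)
  px <- image$pixels
  if (!any(roi)) {
    return(c(mean_color_red_variance = NA_real_,
             mean_color_green_variance = NA_real_,
             mean_color_blue_variance = NA_real_))
  }
  # convert only the ROI pixels (the rest never contributes)
  idx <- which(roi)
  plane <- dim(px)[1] * dim(px)[2]
  rgb01 <- cbind(px[idx], px[idx + plane], px[idx + 2 * plane]) / 255
  if (mode == "rgb") {
    ch <- rgb01 * 255
  } else {
    lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
    ch <- cbind(pmin(pmax(lab[, 1] * 2.55, 0), 255),
                pmin(pmax(lab[, 2] + 128, 0), 255),
                pmin(pmax(lab[, 3] + 128, 0), 255))
  }
  pv <- function(v) mean((v - mean(v))^2)
  c(mean_color_red_variance = pv(ch[, 1]),
    mean_color_green_variance = pv(ch[, 2]),
    mean_color_blue_variance = pv(ch[, 3]))
}

#' Mean level of the green-red axis over the ROI
#'
#' Diagnostic used to verify that drought shifts leaf colour toward
#' red/yellow: higher values mean more red-biased foliage.
#'
#' @inheritParams color_trait_variances
#' @return Mean `ch2` level over the ROI (`NA` when empty).
#' @export
green_red_level <- function(image, roi, mode = c("lab8", "rgb")) {
  mode <- match.arg(mode)
  if (!any(roi)) return(NA_real_)
  px <- image$pixels
  idx <- which(roi)
  plane <- dim(px)[1] * dim(px)[2]
  rgb01 <- cbind(px[idx], px[idx + plane], px[idx + 2 * plane]) / 255
  if (mode == "rgb") return(mean(rgb01[, 2] * 255))
  lab <- grDevices::convertColor(rgb01, from = "sRGB", to = "Lab")
  mean(pmin(pmax(lab[, 2] + 128, 0), 255))
}
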