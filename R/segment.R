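# Shoot segmentation: channel separation, band merging, Otsu thresholding,
# noise removal and connected-component ROI construction.

#' Split an RGB image into its three channel bands
#'
#' @param image a [plant_image] (or bare H x W x 3 array, levels 0-255).
#' @return A list with matrices `r`, `g`, `b`.
#' @export
split_channels <- function(image) {
  px <- if (inherits(image, "plant_image")) image$pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("expected a 3-channel RGB image")
  }
  d <- dim(px)
  list(r = matrix(px[, , 1], d[1], d[2]),
       g = matrix(px[, , 2], d[1], d[2]),
       b = matrix(px[, , 3], d[1], d[2]))
}

#' Merge channel bands into one grayscale image
#'
#' The default weights (-1, 2, -1) compute the excess-green score
#' 2G - R - B, the standard vegetation index for separating green canopy
#' from soil and hardware; the score is affinely rescaled so that the
#' achievable range of the weighted combination maps onto \[0, 255\].
#' Uniform weights (1/3, 1/3, 1/3) therefore reduce to the plain channel
#' mean. The merged level is monotone increasing in G for fixed R and B
#' whenever the green weight is positive.
#'
#' @param bands list with `r`, `g`, `b` matrices (see [split_channels()]).
#' @param weights numeric length-3 channel weights; their absolute values
#'   must sum to a positive number.
#' @return Grayscale matrix with levels in \[0, 255\].
#' @export
merge_to_gray <- function(bands, weights = c(-1, 2, -1)) {
  stopifnot(length(weights) == 3L)
  if (sum(abs(weights)) <= 0) stop("weights must not be all zero")
  dims <- lapply(bands[c("r", "g", "b")], dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("channel bands must have identical shapes")
  }
  combo <- weights[1] * bands$r + weights[2] * bands$g + weights[3] * bands$b
  lo <- 255 * sum(pmin(weights, 0))
  hi <- 255 * sum(pmax(weights, 0))
  (combo - lo) / (hi - lo) * 255
}

#' Otsu threshold of a 256-level histogram
#'
#' Finds the split level t in 0..254 maximizing the between-class variance
#' w0 * w1 * (mu0 - mu1)^2 of the classes \{<= t\} and \{> t\}; ties are
#' broken by the smallest t.
#'
#' @param hist integer/numeric vector of length 256, counts per level 0-255.
#' @return The threshold level (integer in 0..254).
#' @export
otsu_threshold <- function(hist) {
  stopifnot(length(hist) == 256L)
  if (sum(hist > 0) < 2L) stop("histogram is degenerate: fewer than two occupied levels")
  levels <- 0:255
  n <- sum(hist)
  w0 <- cumsum(hist)[1:255]
  w1 <- n - w0
  s0 <- cumsum(hist * levels)[1:255]
  total <- sum(hist * levels)
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  as.integer(which.max(bcv) - 1L)  # which.max takes the first (smallest t) on ties
}

#' Histogram of a grayscale image over the 256 8-bit levels
#'
#' Levels are clamped to \[0, 255\] and binned by rounding.
#'
#' @param gray numeric matrix.
#' @return Integer vector of length 256.
#' @export
gray_histogram <- function(gray) {
  lv <- pmin(pmax(round(gray), 0), 255)
  tabulate(as.integer(lv) + 1L, nbins = 256L)
}

#' Default segmentation parameters
#'
#' @param min_size smallest retained component, pixels.
#' @param opening_radius disk radius of the noise-removal opening, pixels.
#' @param band_mode `"excess_green"` (merge raw bands by the excess-green
#'   score, then one Otsu pass; default) or `"binary_merge"` (threshold
#'   each band separately by Otsu, merge the binaries into a grayscale
#'   vote, keep majority; retained for comparison with per-band
#'   binarization workflows).
#' @param weights channel weights for the grayscale merge.
#' @export
segment_params <- function(min_size = 25L, opening_radius = 1L,
                           band_mode = c("excess_green", "binary_merge"),
                           weights = c(-1, 2, -1)) {
  band_mode <- match.arg(band_mode)
  list(min_size = as.integer(min_size),
       opening_radius = as.integer(opening_radius),
       band_mode = band_mode, weights = weights)
}

#' Segment the plant region of interest
#'
#' Pipeline: grayscale merge -> Otsu threshold -> above-threshold binary
#' mask (plants are the green-dominant, high-score class) -> zero out
#' excluded pixels -> morphological opening -> drop components below
#' `min_size` -> 8-connected component labelling.
#'
#' An image from which no plant can be recovered (all background, or a
#' constant merged image) yields a zero-component result with a warning
#' rather than an error: drought-killed plants may genuinely vanish.
#'
#' @param image a [plant_image].
#' @param exclusion optional logical matrix of pixels to ignore
#'   (see [exclude_obstacles()]).
#' @param params list from [segment_params()].
#' @return A `segmentation_result`: list with `roi` (logical matrix),
#'   `labels` (integer matrix), `components` (integer vector of pixel
#'   counts), `otsu_level`, `largest_component_index`, `px_per_mm`.
#' @export
segment <- function(image, exclusion = NULL, params = segment_params()) {
  bands <- split_channels(image)
  empty_result <- function(shape, level = NA_integer_) {
    structure(list(roi = matrix(FALSE, shape[1], shape[2]),
                   labels = matrix(0L, shape[1], shape[2]),
                   components = integer(0), otsu_level = level,
                   largest_component_index = NA_integer_,
                   px_per_mm = image$px_per_mm),
              class = "segmentation_result")
  }
  shape <- dim(bands$r)

  if (params$band_mode == "excess_green") {
    gray <- merge_to_gray(bands, params$weights)
    h <- gray_histogram(gray)
    if (sum(h > 0) < 2L) {
      warning("constant merged image: empty segmentation result")
      return(empty_result(shape))
    }
    level <- otsu_threshold(h)
    mask <- round(gray) > level
  } else {
    votes <- matrix(0L, shape[1], shape[2])
    used <- 0L
    for (b in list(bands$r, bands$g, bands$b)) {
      h <- gray_histogram(b)
      if (sum(h > 0) < 2L) next
      t <- otsu_threshold(h)
      votes <- votes + (round(b) > t)
      used <- used + 1L
    }
    if (used == 0L) {
      warning("constant image in every band: empty segmentation result")
      return(empty_result(shape))
    }
    # merged grayscale vote; majority of the thresholded bands is foreground
    level <- as.integer(used %/% 2L)
    mask <- votes > used / 2
  }

  if (!is.null(exclusion)) {
    stopifnot(identical(dim(exclusion), dim(mask)))
    mask <- mask & !exclusion
  }
  if (params$opening_radius > 0L) mask <- open_mask(mask, params$opening_radius)

  labels <- label_components(mask, connectivity = 8)
  sizes <- component_sizes(labels)
  keep <- which(sizes >= params$min_size)
  if (length(keep) == 0L) {
    if (any(mask)) warning("all components below min_size: empty segmentation result")
    res <- empty_result(shape, level)
    return(res)
  }
  mask2 <- labels %in% keep
  dim(mask2) <- shape
  labels2 <- label_components(mask2, connectivity = 8)
  sizes2 <- component_sizes(labels2)
  structure(list(roi = mask2, labels = labels2, components = sizes2,
                 otsu_level = level,
                 largest_component_index = as.integer(which.max(sizes2)),
                 px_per_mm = image$px_per_mm),
            class = "segmentation_result")
}

#' Jaccard index between two masks
#' @param a,b logical matrices of identical shape.
#' @return Intersection over union; 1 when both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
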