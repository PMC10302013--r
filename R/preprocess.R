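# Preprocessing: cropping/standardization, obstacle exclusion and scale
# normalization so pixel counts are comparable across images.
#
# Coordinate convention (used everywhere): row-major, top-left origin,
# half-open windows [row0, row1) x [col0, col1) in pixel units.

# bilinear resize of one channel matrix to (nr, nc)
.resize_bilinear <- function(m, nr, nc) {
  sr <- nrow(m) / nr; sc <- ncol(m) / nc
  # map output pixel centers into input coordinates
  yi <- (seq_len(nr) - 0.5) * sr + 0.5  # output center k-0.5 -> input pixel-center units
  xi <- (seq_len(nc) - 0.5) * sc + 0.5
  y0 <- pmin(pmax(floor(yi), 1), nrow(m)); y1 <- pmin(y0 + 1, nrow(m))
  x0 <- pmin(pmax(floor(xi), 1), ncol(m)); x1 <- pmin(x0 + 1, ncol(m))
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) + d * WY * WX
}

# nearest-neighbour resize (masks: preserves binarity)
.resize_nearest <- function(m, nr, nc) {
  ri <- pmin(pmax(ceiling((seq_len(nr) - 0.5) * nrow(m) / nr), 1), nrow(m))
  ci <- pmin(pmax(ceiling((seq_len(nc) - 0.5) * ncol(m) / nc), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Resize an image array or mask
#'
#' Bilinear resampling for image channels, nearest-neighbour for logical
#' masks (preserving binarity).
#'
#' @param x H x W x 3 array, numeric matrix or logical matrix.
#' @param nr,nc target dimensions.
#' @return Resized object of the same kind.
#' @export
resize_image <- function(x, nr, nc) {
  if (is.logical(x)) {
    out <- .resize_nearest(x * 1L, nr, nc) > 0
    return(out)
  }
  if (is.matrix(x)) return(.resize_bilinear(x, nr, nc))
  out <- array(0, dim = c(nr, nc, dim(x)[3]))
  for (k in seq_len(dim(x)[3])) out[, , k] <- .resize_bilinear(x[, , k], nr, nc)
  out
}

#' Crop specification
#'
#' @param row0,row1,col0,col1 half-open window bounds in pixels
#'   (top-left origin, 1-based: rows `row0..row1-1` are kept).
#' @param target_size output (rows, cols); defaults to the window size.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(row0, row1, col0, col1, target_size = NULL) {
  stopifnot(row1 > row0, col1 > col0)
  if (is.null(target_size)) target_size <- c(row1 - row0, col1 - col0)
  stopifnot(length(target_size) == 2, all(target_size > 0))
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1),
                 target_size = as.integer(target_size)),
            class = "crop_spec")
}

#' Crop an image window and standardize its size
#'
#' Extracts the half-open window and resamples it (bilinear) to the
#' target size; `px_per_mm` is rescaled by the resize factor so physical
#' areas stay comparable. A window equal to the target size is returned
#' pixel-exact without resampling.
#'
#' @param image a [plant_image].
#' @param spec a [crop_spec()].
#' @return A [plant_image] of exactly `spec$target_size`.
#' @export
crop_and_standardize <- function(image, spec) {
  d <- dim(image$pixels)
  if (spec$row0 < 1 || spec$col0 < 1 || spec$row1 > d[1] + 1 || spec$col1 > d[2] + 1) {
    stop("crop window lies outside the image bounds")
  }
  rows <- spec$row0:(spec$row1 - 1L); cols <- spec$col0:(spec$col1 - 1L)
  sub <- image$pixels[rows, cols, , drop = FALSE]
  win <- c(length(rows), length(cols))
  tgt <- spec$target_size
  fr <- tgt[1] / win[1]; fc <- tgt[2] / win[2]
  if (abs(fr - fc) / max(fr, fc) > 1e-6) {
    warning("anisotropic resize: px_per_mm rescaled by the mean factor")
  }
  out <- if (all(tgt == win)) sub else resize_image(sub, tgt[1], tgt[2])
  out <- pmin(pmax(out, 0), 255)
  img <- image
  img$pixels <- out
  img$px_per_mm <- image$px_per_mm * (fr + fc) / 2
  img
}

#' Mark obstacle pixels to exclude from segmentation
#'
#' Rules are data, not code: a set of per-channel colour boxes (min/max
#' levels) plus fixed spatial zones (fractions of the frame). Pixels whose
#' colour falls inside the protected `foreground_box` are never marked,
#' whatever the other rules say.
#'
#' @param image a [plant_image].
#' @param rules list with `color_boxes` (each `list(min, max)` length-3),
#'   `zones` (each `list(rows = c(lo, hi), cols = c(lo, hi))` in 0-1
#'   fractions) and optional `foreground_box`; see
#'   [default_obstacle_rules()]. An empty rule set yields an empty mask.
#' @return Logical exclusion matrix (TRUE = ignore in segmentation).
#' @export
exclude_obstacles <- function(image, rules = default_obstacle_rules(image$view)) {
  px <- image$pixels
  nr <- dim(px)[1]; nc <- dim(px)[2]
  excl <- matrix(FALSE, nr, nc)
  fg <- rules$foreground_box
  for (box in rules$color_boxes) {
    if (!is.null(fg) && all(box$min <= fg$min) && all(box$max >= fg$max)) {
      stop("configuration error: foreground colour box lies inside an exclusion box")
    }
    hit <- px[, , 1] >= box$min[1] & px[, , 1] <= box$max[1] &
           px[, , 2] >= box$min[2] & px[, , 2] <= box$max[2] &
           px[, , 3] >= box$min[3] & px[, , 3] <= box$max[3]
    excl <- excl | hit
  }
  for (z in rules$zones) {
    rs <- max(1, floor(z$rows[1] * nr) + 1):min(nr, ceiling(z$rows[2] * nr))
    cs <- max(1, floor(z$cols[1] * nc) + 1):min(nc, ceiling(z$cols[2] * nc))
    excl[rs, cs] <- TRUE
  }
  if (!is.null(fg)) {
    is_fg <- px[, , 1] >= fg$min[1] & px[, , 1] <= fg$max[1] &
             px[, , 2] >= fg$min[2] & px[, , 2] <= fg$max[2] &
             px[, , 3] >= fg$min[3] & px[, , 3] <= fg$max[3]
    excl <- excl & !is_fg
  }
  excl
}

#' Normalize an image to a common physical scale
#'
#' Resamples so that the output `px_per_mm` equals the target (exactly,
#' up to the integer output size); physical areas in mm^2 are conserved
#' within resampling tolerance. An image already at the target scale is
#' returned unchanged.
#'
#' @param image a [plant_image] with a known positive `px_per_mm`.
#' @param target_px_per_mm desired scale.
#' @return A [plant_image] with `px_per_mm = target_px_per_mm`.
#' @export
normalize_scale <- function(image, target_px_per_mm) {
  if (is.null(image$px_per_mm) || !is.finite(image$px_per_mm) || image$px_per_mm <= 0) {
    stop("source scale unknown: set px_per_mm on the image before normalizing")
  }
  if (target_px_per_mm <= 0) stop("target_px_per_mm must be positive")
  f <- target_px_per_mm / image$px_per_mm
  if (abs(f - 1) < 1e-9) return(image)
  d <- dim(image$pixels)
  nr <- max(1L, round(d[1] * f)); nc <- max(1L, round(d[2] * f))
  img <- image
  img$pixels <- pmin(pmax(resize_image(image$pixels, nr, nc), 0), 255)
  img$px_per_mm <- target_px_per_mm
  img
}
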