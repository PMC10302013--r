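# Binary-mask raster operations.
#
# Masks are logical matrices (rows = image rows, columns = image columns).
# Connectivity conventions, stated once and shared with the trait code:
# connected components are 8-connected; a boundary pixel is a mask pixel
# with at least one 4-neighbour outside the mask (the image border counts
# as outside).

# shift a matrix by (dr, dc), padding with `fill`
.shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

.neigh8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
.neigh4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

#' Label connected components of a binary mask
#'
#' Run-length union-find: vertical runs of foreground pixels are the
#' union-find nodes; runs in adjacent columns are merged when their row
#' intervals touch (with a one-row tolerance under 8-connectivity, where
#' diagonal contact joins components). Linear in the number of pixels.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape: 0 for background, 1..k for
#'   components labelled in order of their smallest linear pixel index.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (!any(mask)) return(out)

  # vertical runs, column-major order: starts/ends alternate within columns
  above <- rbind(FALSE, mask[-nr, , drop = FALSE])
  below <- rbind(mask[-1, , drop = FALSE], FALSE)
  s_idx <- which(mask & !above)   # run starts (linear, column-major)
  e_idx <- which(mask & !below)   # run ends, paired with starts in order
  s_row <- ((s_idx - 1L) %% nr) + 1L
  e_row <- ((e_idx - 1L) %% nr) + 1L
  col <- ((s_idx - 1L) %/% nr) + 1L
  m <- length(s_idx)

  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tol <- if (connectivity == 8) 1L else 0L
  runs_by_col <- split(seq_len(m), col)
  cols_present <- as.integer(names(runs_by_col))
  for (ci in seq_along(cols_present)[-1]) {
    if (cols_present[ci] - cols_present[ci - 1L] != 1L) next
    left <- runs_by_col[[ci - 1L]]; right <- runs_by_col[[ci]]
    for (i in right) {
      hit <- left[e_row[left] >= s_row[i] - tol & s_row[left] <= e_row[i] + tol]
      for (j in hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(m), find, 0L)
  # order components by the smallest linear pixel index they contain
  comp_min <- tapply(s_idx, root, min)
  relabel <- integer(max(root))
  relabel[as.integer(names(comp_min))] <- as.integer(rank(comp_min))
  run_lab <- relabel[root]
  lens <- e_row - s_row + 1L
  out[sequence(lens, from = s_idx)] <- rep.int(run_lab, lens)
  out
}

#' Component sizes from a label matrix
#' @param labels integer label matrix from [label_components()].
#' @return Named integer vector of pixel counts, names are labels.
#' @export
component_sizes <- function(labels) {
  v <- labels[labels > 0L]
  if (length(v) == 0L) return(integer(0))
  tab <- tabulate(v)
  stats::setNames(as.integer(tab), seq_along(tab))
}

# binary erosion/dilation with a disk structuring element of radius r
.disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Morphological erosion, dilation and opening (disk structuring element)
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels; radius 1 is the 4-neighbourhood
#'   cross plus center.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, radius = 1) {
  off <- .disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- out & .shift_mat(mask, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius = 1) {
  off <- .disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- out | .shift_mat(mask, off$dr[i], off$dc[i], fill = FALSE)
  }
  out
}

#' @rdname erode_mask
#' @export
open_mask <- function(mask, radius = 1) {
  dilate_mask(erode_mask(mask, radius), radius)
}

#' Boundary pixels of a mask
#'
#' A mask pixel is a boundary pixel when at least one of its 4-neighbours
#' lies outside the mask; pixels on the image border always qualify.
#'
#' @param mask logical matrix.
#' @return Logical matrix marking boundary pixels.
#' @export
boundary_mask <- function(mask) {
  inside <- mask
  for (i in seq_len(nrow(.neigh4))) {
    inside <- inside & .shift_mat(mask, .neigh4[i, 1], .neigh4[i, 2], fill = FALSE)
  }
  mask & !inside
}

#' Pixel-center coordinates of mask pixels
#'
#' @param mask logical matrix.
#' @return An n x 2 matrix of (x = column, y = row) pixel centers.
#' @export
mask_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  point_set(x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]))
}

#' Boundary points of a mask as a point set
#' @inheritParams mask_points
#' @return An n x 2 point matrix of boundary pixel centers.
#' @export
boundary_points <- function(mask) {
  mask_points(boundary_mask(mask))
}

# Moore-neighbour order, clockwise starting east: E SE S SW W NW N NE
.moore <- cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
                dc = c(1, 1, 0, -1, -1, -1, 0, 1))

# trace the outer contour of one 8-connected component; returns the ordered
# pixel path (closed: last step returns to start)
.trace_contour <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  # start at the topmost-leftmost pixel, entering from the west
  o <- order(idx[, 1], idx[, 2])
  start <- idx[o[1L], ]
  if (nrow(idx) == 1L) return(rbind(start))
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  path <- matrix(NA_integer_, nrow = 4L * nrow(idx) + 8L, ncol = 2L)
  cur <- start
  # backtrack direction: we "came from" the west, so searching starts there
  dir_from <- 5L  # index of W in .moore
  path[1L, ] <- cur
  np <- 1L
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- ((dir_from - 1L + s) %% 8L) + 1L
      r2 <- cur[1] + .moore[d, 1]; c2 <- cur[2] + .moore[d, 2]
      if (inside(r2, c2)) {
        if (np == 1L) first_move <- d
        # Jacob's stopping criterion: back at start making the same first move
        if (np > 1L && cur[1] == start[1] && cur[2] == start[2] && d == first_move) {
          return(path[seq_len(np), , drop = FALSE])
        }
        cur <- c(r2, c2)
        np <- np + 1L
        if (np > nrow(path)) path <- rbind(path, path)  # safety growth
        path[np, ] <- cur
        # next search starts from the backtrack of the move taken
        dir_from <- ((d + 4L - 1L + 1L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(path[seq_len(np), , drop = FALSE])  # isolated pixel run
    if (np > 4L * nrow(idx) + 8L) return(path[seq_len(np), , drop = FALSE])
  }
}

#' Contour perimeter by Moore-neighbour boundary tracing
#'
#' Traces the outer contour of every 8-connected component and sums
#' Euclidean step lengths (1 for axial moves, sqrt(2) for diagonal moves).
#' A single-pixel component contributes 0 under the pixel-center
#' convention. Interior holes are not traced.
#'
#' @param mask logical matrix.
#' @param labels optional precomputed label matrix.
#' @return Total contour length in pixels.
#' @export
trace_perimeter <- function(mask, labels = NULL) {
  if (is.null(labels)) labels <- label_components(mask, connectivity = 8)
  k <- max(labels)
  if (k == 0L) return(0)
  total <- 0
  for (lbl in seq_len(k)) {
    comp <- labels == lbl
    path <- .trace_contour(comp)
    if (is.null(path) || nrow(path) < 2L) next
    steps <- diff(path)
    total <- total + sum(sqrt(rowSums(steps^2)))
  }
  total
}
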