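# Exact 2-D computational geometry on pixel-center point sets.
#
# Convention used throughout the package: a point set is an n x 2 numeric
# matrix with columns (x, y); mask pixels are represented by their centers,
# x = column index, y = row index. A single pixel therefore has caliper
# length 0, not 1.

#' Build a point-set matrix
#'
#' @param x,y numeric vectors of equal length (or `x` an n x 2 matrix).
#' @return An n x 2 numeric matrix with columns `x`, `y`.
#' @export
point_set <- function(x, y = NULL) {
  if (is.null(y)) {
    p <- as.matrix(x)
    if (ncol(p) != 2L) stop("point set must have two columns (x, y)")
  } else {
    p <- cbind(x, y)
  }
  storage.mode(p) <- "double"
  if (anyNA(p) || any(!is.finite(p))) stop("point coordinates must be finite")
  colnames(p) <- c("x", "y")
  p
}

# cross product (b - a) x (c - a); > 0 when c lies left of a->b
.cross <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

#' Convex hull by the monotone chain algorithm
#'
#' Returns the hull vertices in counter-clockwise order with collinear
#' points on hull edges excluded. Degenerate inputs (a single point, all
#' points collinear) return the extreme points; such hulls have zero area.
#'
#' @param pts an n x 2 point matrix (see [point_set()]).
#' @return An h x 2 matrix of hull vertices, counter-clockwise.
#' @export
convex_hull <- function(pts) {
  pts <- point_set(pts)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 0L) stop("convex hull of an empty point set")
  if (n <= 2L) return(pts)
  ord <- order(pts[, 1], pts[, 2])
  p <- pts[ord, , drop = FALSE]
  build <- function(idx) {
    st <- integer(0)
    for (i in idx) {
      while (length(st) >= 2L) {
        k <- length(st)
        if (.cross(p[st[k - 1L], ], p[st[k], ], p[i, ]) <= 0) {
          st <- st[-k]
        } else break
      }
      st <- c(st, i)
    }
    st
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  p[hull, , drop = FALSE]
}

#' Polygon area by the shoelace formula
#'
#' @param poly vertex matrix (ordered, closed implicitly).
#' @return Signed area is taken absolute; degenerate polygons return 0.
#' @export
polygon_area <- function(poly) {
  if (nrow(poly) < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter
#'
#' @param poly vertex matrix (ordered).
#' @return Sum of Euclidean edge lengths, closing the polygon.
#' @export
polygon_perimeter <- function(poly) {
  if (nrow(poly) < 2L) return(0)
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

#' Feret (caliper) length: maximum pairwise distance
#'
#' Computed exactly on the convex hull vertices (the diameter of a point
#' set is attained between hull vertices).
#'
#' @param pts an n x 2 point matrix.
#' @return Maximum Euclidean distance between any two points; `NA_real_`
#'   for fewer than two distinct points (undefined, recorded as missing).
#' @export
caliper_length <- function(pts) {
  pts <- point_set(pts)
  h <- convex_hull(pts)
  if (nrow(h) < 2L) return(NA_real_)
  dx <- outer(h[, 1], h[, 1], "-")
  dy <- outer(h[, 2], h[, 2], "-")
  sqrt(max(dx * dx + dy * dy))
}

#' Minimum-area enclosing rectangle
#'
#' Rotating-caliper sweep over hull edge directions: some optimal
#' rectangle has a side collinear with a hull edge, so only hull edge
#' angles need be examined.
#'
#' @param pts an n x 2 point matrix.
#' @return A list with `area`, `corners` (4 x 2, in rectangle order),
#'   `angle` (radians of the supporting edge direction), `width`, `height`.
#'   Degenerate sets (<3 distinct points or collinear) give `area = 0`.
#' @export
min_area_rectangle <- function(pts) {
  pts <- point_set(pts)
  h <- convex_hull(pts)
  nh <- nrow(h)
  if (nh < 2L) {
    return(list(area = 0, corners = h[rep(1L, 4L), , drop = FALSE],
                angle = 0, width = 0, height = 0))
  }
  edges <- rbind(h[-1, , drop = FALSE], h[1, , drop = FALSE]) - h
  angles <- atan2(edges[, 2], edges[, 1])
  best <- NULL
  for (th in angles) {
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    pu <- h %*% u; pv <- h %*% v
    w <- max(pu) - min(pu); hgt <- max(pv) - min(pv)
    a <- w * hgt
    if (is.null(best) || a < best$area - 1e-12) {
      c1 <- min(pu); c2 <- max(pu); d1 <- min(pv); d2 <- max(pv)
      corners <- rbind(c1 * u + d1 * v, c2 * u + d1 * v,
                       c2 * u + d2 * v, c1 * u + d2 * v)
      colnames(corners) <- c("x", "y")
      best <- list(area = a, corners = corners, angle = th,
                   width = w, height = hgt)
    }
  }
  best
}

# smallest circle through one, two or three points
.circle2 <- function(a, b) {
  ctr <- (a + b) / 2
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

.circle3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: fall back to the widest pair
    cands <- list(.circle2(a, b), .circle2(a, c), .circle2(b, c))
    return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

.in_circle <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius + tol
}

#' Minimum enclosing circle (Welzl's algorithm)
#'
#' Randomized incremental construction over a deterministic permutation
#' (a small multiplicative congruential shuffle, so results never touch
#' R's global RNG stream). The minimum enclosing circle is unique, so the
#' permutation affects runtime only. Points are reduced to hull vertices
#' first; the object and its hull share the same enclosing circle.
#'
#' @param pts an n x 2 point matrix.
#' @return A list with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- point_set(pts)
  p <- convex_hull(pts)
  n <- nrow(p)
  if (n == 1L) return(list(center = p[1, ], radius = 0))
  # deterministic pseudo-shuffle (LCG), independent of the global RNG
  idx <- seq_len(n)
  state <- 48271
  for (i in n:2) {
    state <- (state * 16807) %% 2147483647
    j <- (state %% i) + 1L
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  p <- p[idx, , drop = FALSE]

  circ <- .circle2(p[1, ], p[2, ])
  if (n >= 3L) {
    for (i in 3:n) {
      if (.in_circle(circ, p[i, ])) next
      # p[i] lies on the boundary of the new circle
      circ <- .circle2(p[1, ], p[i, ])
      for (j in seq_len(i - 1L)[-1L]) {
        if (.in_circle(circ, p[j, ])) next
        circ <- .circle2(p[i, ], p[j, ])
        for (k in seq_len(j - 1L)) {
          if (.in_circle(circ, p[k, ])) next
          circ <- .circle3(p[i, ], p[j, ], p[k, ])
        }
      }
    }
  }
  circ
}

#' Pixel centers inside or on a convex polygon
#'
#' Rasterizes a convex polygon over integer pixel centers and counts the
#' covered pixels (used for the pixel-count reading of the hull-area trait).
#'
#' @param poly convex polygon, counter-clockwise vertex matrix.
#' @return Number of integer-coordinate pixel centers inside or on `poly`.
#' @export
count_pixels_in_convex_polygon <- function(poly, tol = 1e-9) {
  nv <- nrow(poly)
  if (nv == 0L) return(0L)
  xs <- seq(floor(min(poly[, 1])), ceiling(max(poly[, 1])))
  ys <- seq(floor(min(poly[, 2])), ceiling(max(poly[, 2])))
  if (nv == 1L) {
    return(sum(abs(xs - poly[1, 1]) < tol) * sum(abs(ys - poly[1, 2]) < tol))
  }
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  keep <- rep(TRUE, length(gx))
  for (i in seq_len(nv)) {
    a <- poly[i, ]; b <- poly[if (i == nv) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    if (nv == 2L) keep <- keep & abs(cr) < tol else keep <- keep & cr >= -tol
    if (!any(keep)) return(0L)
  }
  if (nv == 2L) {
    # segment: also require projection within the endpoints
    d <- poly[2, ] - poly[1, ]
    t <- ((gx - poly[1, 1]) * d[1] + (gy - poly[1, 2]) * d[2]) / sum(d^2)
    keep <- keep & t >= -tol & t <= 1 + tol
  }
  sum(keep)
}
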