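# Independent brute-force oracles for the geometric operators and the
# rank statistics. These deliberately share no code with the package:
# naive enumeration only.

# maximum pairwise distance, O(n^2) over all points
oracle_caliper <- function(pts) {
  if (nrow(pts) < 2) return(NA_real_)
  max(stats::dist(pts))
}

# O(n^3) hull edge test: (i, j) is a hull edge iff every other point lies
# on one side of (or on) the line i -> j; returns the set of hull vertices
oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  verts <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
            (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      if (all(cr >= -1e-9) || all(cr <= 1e-9)) {
        verts[i] <- TRUE; verts[j] <- TRUE
      }
    }
  }
  which(verts)
}

# every point inside or on the (counter-clockwise) polygon, within tol
oracle_all_inside <- function(pts, poly, tol = 1e-9) {
  nv <- nrow(poly)
  ok <- rep(TRUE, nrow(pts))
  for (i in seq_len(nv)) {
    a <- poly[i, ]; b <- poly[if (i == nv) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    ok <- ok & cr >= -tol
  }
  all(ok)
}

# minimum-area rectangle by a 0.1-degree brute-force angle sweep
oracle_rect_area <- function(pts, step_deg = 0.1) {
  best <- Inf
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- pts[, 1] * cos(th) + pts[, 2] * sin(th)
    v <- -pts[, 1] * sin(th) + pts[, 2] * cos(th)
    a <- (max(u) - min(u)) * (max(v) - min(v))
    if (a < best) best <- a
  }
  best
}

# circle through two (diametral) or three points -- independent rewrite
.orc_circ2 <- function(a, b) {
  ctr <- (a + b) / 2
  c(ctr, sqrt(sum((a - ctr)^2)))
}
.orc_circ3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

# minimum enclosing circle by enumerating all pair- and triple-defined
# candidate circles; intended for small point sets
oracle_mec_radius <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n == 1) return(0)
  best <- Inf
  contains_all <- function(circ) {
    all(sqrt((pts[, 1] - circ[1])^2 + (pts[, 2] - circ[2])^2) <= circ[3] + tol)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    circ <- .orc_circ2(pts[i, ], pts[j, ])
    if (circ[3] < best && contains_all(circ)) best <- circ[3]
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      circ <- .orc_circ3(pts[i, ], pts[j, ], pts[k, ])
      if (!is.null(circ) && circ[3] < best && contains_all(circ)) best <- circ[3]
    }
  }
  best
}

# exhaustive Otsu: naive per-split class statistics
oracle_otsu <- function(h) {
  lv <- 0:255
  n <- sum(h)
  best_t <- -1; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * lv[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):256] * lv[(t + 2):256]) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis H statistic
oracle_kw_perm_p <- function(groups, B = 2000) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  hstat <- function(xx) {
    r <- rank(xx)
    R <- tapply(r, g, sum)
    N <- length(xx)
    H <- 12 / (N * (N + 1)) * sum(R^2 / lengths(groups)) - 3 * (N + 1)
    ties <- table(xx)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  h0 <- hstat(x)
  cnt <- 0
  for (b in seq_len(B)) if (hstat(sample(x)) >= h0 - 1e-12) cnt <- cnt + 1
  (cnt + 1) / (B + 1)
}

# digital disk mask of radius r (pixel centers within r of the center)
make_disk_mask <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - ctr)^2 + (cc - ctr)^2 <= r^2
}

make_block_mask <- function(h, w, nr = h + 4, nc = w + 4, r0 = 3, c0 = 3) {
  m <- matrix(FALSE, nr, nc)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

# wrap a bare mask as a segmentation result (for trait functions)
seg_from_mask <- function(mask, px_per_mm = 1) {
  labels <- label_components(mask, 8)
  sizes <- component_sizes(labels)
  structure(list(roi = mask, labels = labels, components = sizes,
                 otsu_level = NA_integer_,
                 largest_component_index = if (length(sizes)) which.max(sizes) else NA_integer_,
                 px_per_mm = px_per_mm),
            class = "segmentation_result")
}

# uniform flat image as a plant_image
flat_image <- function(col = c(40, 40, 40), nr = 20, nc = 20, ...) {
  px <- array(rep(col, each = nr * nc), dim = c(nr, nc, 3))
  plant_image(px, ...)
}
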