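# Mask rasters and the thirteen-trait extraction.

test_that("connected-component labelling matches a propagation oracle", {
  slow_label <- function(mask, connectivity = 8) {
    nb <- if (connectivity == 8) {
      cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    lab <- matrix(Inf, nrow(mask), ncol(mask)); lab[mask] <- which(mask)
    sh <- function(m, dr, dc) {
      nr <- nrow(m); nc <- ncol(m); o <- matrix(Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
      o[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]; o
    }
    repeat {
      new <- lab
      for (i in seq_len(nrow(nb))) new <- pmin(new, sh(lab, nb[i, 1], nb[i, 2]))
      new[!mask] <- Inf
      if (identical(new, lab)) break
      lab <- new
    }
    out <- matrix(0L, nrow(mask), ncol(mask))
    if (any(mask)) {
      v <- lab[mask]
      out[mask] <- as.integer(factor(v, levels = sort(unique(v))))
    }
    out
  }
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(runif(625) < runif(1, 0.2, 0.7), 25, 25)
    expect_identical(label_components(m, 8), slow_label(m, 8))
    expect_identical(label_components(m, 4), slow_label(m, 4))
  }
  expect_identical(label_components(matrix(FALSE, 3, 3)), matrix(0L, 3, 3))
})

test_that("boundary pixels follow the 4-neighbour convention", {
  b <- make_block_mask(3, 3)
  expect_equal(sum(boundary_mask(b)), 8)      # only the center is interior
  line <- make_block_mask(1, 20)
  expect_equal(sum(boundary_mask(line)), 20)  # 1-px line: all boundary
  # image border counts as outside
  edge <- matrix(TRUE, 3, 3)
  expect_equal(sum(boundary_mask(edge)), 8)
  disk <- make_disk_mask(50)
  expect_lt(abs(sum(boundary_mask(disk)) - 2 * pi * 50) / (2 * pi * 50), 0.15)
})

test_that("Moore-traced perimeter is exact on blocks and close on disks", {
  expect_equal(trace_perimeter(make_block_mask(10, 10)), 36)
  expect_equal(trace_perimeter(make_block_mask(1, 1)), 0)   # single pixel
  two <- matrix(FALSE, 4, 4); two[2, 2:3] <- TRUE
  expect_equal(trace_perimeter(two), 2)
  disk <- make_disk_mask(50)
  expect_lt(abs(trace_perimeter(disk) - 2 * pi * 50) / (2 * pi * 50), 0.10)
  # two components: perimeters add
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE; m[10:13, 10:13] <- TRUE
  expect_equal(trace_perimeter(m), 2 * 12)
})

test_that("area traits count pixels under both scope conventions", {
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:3] <- TRUE          # 4 px
  m[6:8, 6:8] <- TRUE          # 9 px
  seg <- seg_from_mask(m)
  expect_equal(area_trait(seg), 13)
  expect_equal(object_sum_area_trait(seg), 13)
  expect_equal(area_trait(seg, scope = "largest"), 9)
  expect_equal(area_trait(seg_from_mask(matrix(FALSE, 4, 4))), 0)
  disk <- make_disk_mask(50)
  expect_lt(abs(area_trait(seg_from_mask(disk)) - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("circumference traits support perimeter and literal readings", {
  seg <- seg_from_mask(make_block_mask(10, 10))
  expect_equal(circumference_trait(seg, "perimeter"), 36)
  mec_d <- 2 * min_enclosing_circle(boundary_points(seg$roi))$radius
  expect_equal(circumference_trait(seg, "literal"), pi * mec_d)
  expect_equal(convex_hull_circumference_trait(seg, "literal"),
               circumference_trait(seg, "literal"))
  expect_equal(convex_hull_circumference_trait(seg, "perimeter"), 36)
  # hull perimeter never exceeds the traced object perimeter
  set.seed(21)
  for (i in 1:8) {
    m <- dilate_mask(matrix(runif(400) < 0.1, 20, 20), 1)
    if (!any(m)) next
    seg <- seg_from_mask(m)
    expect_lte(convex_hull_circumference_trait(seg, "perimeter"),
               circumference_trait(seg, "perimeter") + 1e-9)
  }
})

test_that("roundness behaves like a disk/line discriminator", {
  dsk <- seg_from_mask(make_disk_mask(50))
  tr <- extract_traits(flat_image(nr = nrow(dsk$roi), nc = ncol(dsk$roi)), dsk)
  expect_equal(tr$roundness, 1, tolerance = 0.05)
  line <- seg_from_mask(make_block_mask(1, 100, nr = 5, nc = 104))
  trl <- extract_traits(flat_image(nr = 5, nc = 104), line)
  expect_equal(trl$roundness, 4 * 100 / (pi * 99^2), tolerance = 1e-9)
  expect_gt(tr$roundness, 0); expect_lte(tr$roundness, 1.1)
})

test_that("boundary-point roundness matches direct formulas and scales as 1/size", {
  b3 <- seg_from_mask(make_block_mask(3, 3))
  tr3 <- extract_traits(flat_image(nr = 7, nc = 7), b3)
  expect_equal(tr3$boundary_point_roundness, 8 / (pi * 2), tolerance = 1e-9)
  dsk <- seg_from_mask(make_disk_mask(50))
  trd <- extract_traits(flat_image(nr = nrow(dsk$roi), nc = ncol(dsk$roi)), dsk)
  expect_equal(trd$boundary_point_roundness, 2 / 50, tolerance = 0.2)
  small <- seg_from_mask(make_disk_mask(25))
  trs <- extract_traits(flat_image(nr = nrow(small$roi), nc = ncol(small$roi)), small)
  expect_equal(trs$boundary_point_roundness / trd$boundary_point_roundness, 2,
               tolerance = 0.15)
})

test_that("empty and degenerate ROIs yield zero areas and missing shape traits", {
  seg <- seg_from_mask(matrix(FALSE, 6, 6))
  tr <- extract_traits(flat_image(nr = 6, nc = 6), seg)
  expect_equal(tr$area, 0)
  expect_equal(tr$object_sum_area, 0)
  expect_true(is.na(tr$caliper_length))
  expect_true(is.na(tr$roundness))
  expect_true(is.na(tr$mean_color_red_variance))
  # single pixel: caliper degenerate -> roundness missing, not zero
  one <- seg_from_mask(make_block_mask(1, 1), 1)
  tro <- extract_traits(flat_image(nr = 5, nc = 5), one)
  expect_true(is.na(tro$roundness))
})

test_that("similarity scaling: lengths scale ~k, areas ~k^2", {
  small <- seg_from_mask(make_disk_mask(25))
  big <- seg_from_mask(make_disk_mask(50))
  ts <- extract_traits(flat_image(nr = nrow(small$roi), nc = ncol(small$roi)), small)
  tb <- extract_traits(flat_image(nr = nrow(big$roi), nc = ncol(big$roi)), big)
  expect_equal(tb$area / ts$area, 4, tolerance = 0.05)
  expect_equal(tb$caliper_length / ts$caliper_length, 2, tolerance = 0.05)
  expect_equal(tb$convex_hull_area / ts$convex_hull_area, 4, tolerance = 0.05)
  expect_equal(tb$circumference / ts$circumference, 2, tolerance = 0.05)
})

test_that("rotation robustness: caliper, MEC diameter and hull area stable under 45 degrees", {
  # rasterize a smooth asymmetric blob at 0 and 45 degrees
  blob <- function(theta) {
    n <- 181; ctr <- 91
    rr <- matrix(seq_len(n), n, n) - ctr
    cc <- t(matrix(seq_len(n), n, n)) - ctr
    x <- cc * cos(theta) + rr * sin(theta)
    y <- -cc * sin(theta) + rr * cos(theta)
    (x / 60)^2 + (y / 35)^2 <= 1
  }
  a <- seg_from_mask(blob(0)); b <- seg_from_mask(blob(pi / 4))
  fa <- extract_traits(flat_image(nr = 181, nc = 181), a)
  fb <- extract_traits(flat_image(nr = 181, nc = 181), b)
  for (col in c("caliper_length", "min_enclosing_circle_diameter", "convex_hull_area")) {
    expect_lt(abs(fa[[col]] - fb[[col]]) / fa[[col]], 0.03)
  }
})
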