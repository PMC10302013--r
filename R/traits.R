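# The thirteen image-based traits, grouped as area / boundary / colour.
#
# Geometry runs on pixel centers of the retained ROI (whole-plant union of
# components by default; the largest component alone in "largest" scope).
# Undefined traits (empty ROI, degenerate point sets) are recorded as NA,
# never 0 - zeros would corrupt downstream rank tests.

#' Names of the thirteen traits
#' @param category optional subset: "area", "boundary" or "color".
#' @return Character vector of trait column names.
#' @export
trait_names <- function(category = NULL) {
  cats <- list(
    area = c("area", "caliper_length", "convex_hull_area",
             "min_area_rectangle_area", "object_sum_area"),
    boundary = c("boundary_point_roundness", "circumference",
                 "convex_hull_circumference", "min_enclosing_circle_diameter",
                 "roundness"),
    color = c("mean_color_red_variance", "mean_color_green_variance",
              "mean_color_blue_variance"))
  if (is.null(category)) return(unlist(cats, use.names = FALSE))
  cats[[match.arg(category, names(cats))]]
}

#' Projected area: pixel count of the retained ROI
#'
#' @param result a `segmentation_result`.
#' @param scope `"union"` (whole plant, default) or `"largest"` (largest
#'   component only).
#' @return Pixel count (0 for an empty ROI).
#' @export
area_trait <- function(result, scope = c("union", "largest")) {
  scope <- match.arg(scope)
  if (length(result$components) == 0L) return(0L)
  if (scope == "largest") return(max(result$components))
  sum(result$components)
}

#' Sum of all component pixel counts
#'
#' Equals [area_trait()] under the union convention; kept as a separate
#' trait so the largest-component variant still reports the whole plant.
#'
#' @param result a `segmentation_result`.
#' @return Pixel count.
#' @export
object_sum_area_trait <- function(result) {
  sum(result$components)
}

# ROI mask for the configured scope
.scope_mask <- function(result, scope) {
  if (scope == "largest" && length(result$components) > 0L) {
    return(result$labels == result$largest_component_index)
  }
  result$roi
}

#' Circumference trait
#'
#' Mode `"perimeter"` (default) is the total Moore-traced contour length
#' of the ROI; mode `"literal"` reads the trait name literally as the
#' circumference of the minimum enclosing circle, `pi * MEC diameter`.
#'
#' @param result a `segmentation_result`.
#' @param mode `"perimeter"` or `"literal"`.
#' @param scope component scope, see [area_trait()].
#' @return Length in pixels (`NA` for an empty ROI).
#' @export
circumference_trait <- function(result, mode = c("perimeter", "literal"),
                                scope = c("union", "largest")) {
  mode <- match.arg(mode); scope <- match.arg(scope)
  mask <- .scope_mask(result, scope)
  if (!any(mask)) return(NA_real_)
  if (mode == "literal") {
    mec <- min_enclosing_circle(boundary_points(mask))
    return(pi * 2 * mec$radius)
  }
  labels <- if (scope == "union") result$labels else NULL
  trace_perimeter(mask, labels)
}

#' Convex-hull circumference trait
#'
#' Mode `"perimeter"` (default) is the hull polygon perimeter; mode
#' `"literal"` is `pi *` the diameter of the hull's minimum enclosing
#' circle, which coincides with the literal [circumference_trait()]
#' because an object and its hull share the same enclosing circle.
#'
#' @inheritParams circumference_trait
#' @return Length in pixels (`NA` for an empty ROI).
#' @export
convex_hull_circumference_trait <- function(result, mode = c("perimeter", "literal"),
                                            scope = c("union", "largest")) {
  mode <- match.arg(mode); scope <- match.arg(scope)
  mask <- .scope_mask(result, scope)
  if (!any(mask)) return(NA_real_)
  pts <- boundary_points(mask)
  if (mode == "literal") {
    mec <- min_enclosing_circle(pts)
    return(pi * 2 * mec$radius)
  }
  polygon_perimeter(convex_hull(pts))
}

#' Extract the full trait record of one segmented image
#'
#' Computes the five area traits, five boundary traits and three colour
#' variances, plus identifying metadata, for a single (plant, day, view)
#' image. Geometry uses the pixel-center convention throughout.
#'
#' @param image a [plant_image].
#' @param result its `segmentation_result` (from [segment()]).
#' @param color_mode channel semantics for the colour variances.
#' @param circumference_mode `"perimeter"` or `"literal"`.
#' @param scope `"union"` (default) or `"largest"`.
#' @return One-row data frame: metadata columns then the 13 traits.
#' @export
extract_traits <- function(image, result,
                           color_mode = c("lab8", "rgb"),
                           circumference_mode = c("perimeter", "literal"),
                           scope = c("union", "largest")) {
  color_mode <- match.arg(color_mode)
  circumference_mode <- match.arg(circumference_mode)
  scope <- match.arg(scope)

  meta <- data.frame(plant_id = image$plant_id, variety = image$variety,
                     treatment = image$treatment, stage = image$stage,
                     day = image$day, view = image$view,
                     stringsAsFactors = FALSE)
  empty <- c(stats::setNames(rep(NA_real_, 10), trait_names()[1:10]),
             mean_color_red_variance = NA_real_,
             mean_color_green_variance = NA_real_,
             mean_color_blue_variance = NA_real_)

  mask <- .scope_mask(result, scope)
  if (!any(mask)) {
    empty["area"] <- 0; empty["object_sum_area"] <- 0
    return(cbind(meta, as.data.frame(as.list(empty))))
  }

  bpts <- boundary_points(mask)
  hull <- convex_hull(bpts)
  cal <- caliper_length(bpts)
  mec <- min_enclosing_circle(bpts)
  rect <- min_area_rectangle(bpts)
  area_px <- if (scope == "largest") max(result$components) else sum(result$components)
  nb <- nrow(bpts)

  vals <- c(
    area = as.numeric(area_px),
    caliper_length = cal,
    convex_hull_area = as.numeric(count_pixels_in_convex_polygon(hull)),
    min_area_rectangle_area = rect$area,
    object_sum_area = as.numeric(sum(result$components)),
    boundary_point_roundness = if (is.na(cal) || cal <= 0) NA_real_ else
      nb / (pi * (cal / 2)^2),
    circumference = circumference_trait(result, circumference_mode, scope),
    convex_hull_circumference =
      convex_hull_circumference_trait(result, circumference_mode, scope),
    min_enclosing_circle_diameter = 2 * mec$radius,
    roundness = if (is.na(cal) || cal <= 0) NA_real_ else
      4 * area_px / (pi * cal^2))
  colv <- color_trait_variances(image, mask, color_mode)
  cbind(meta, as.data.frame(as.list(c(vals, colv))))
}

#' Trait table for a whole trial
#'
#' Segments every image of a trial and extracts its trait record; the
#' result is one row per (plant, day, view) with the 13 trait columns.
#'
#' @param trial a `shoot_trial` with rendered images.
#' @param params segmentation parameters ([segment_params()]).
#' @param exclusion_rules `NULL`, or a function `(view) ->` rules passed
#'   to [exclude_obstacles()]; defaults to the generator-matched rules.
#' @param ... passed on to [extract_traits()].
#' @return Data frame of trait records; attribute `"jaccard"` holds the
#'   per-image segmentation Jaccard index against the truth masks.
#' @export
trial_trait_table <- function(trial, params = segment_params(),
                              exclusion_rules = default_obstacle_rules, ...) {
  rows <- vector("list", length(trial$images))
  jac <- numeric(length(trial$images))
  for (i in seq_along(trial$images)) {
    id <- names(trial$images)[i]
    img <- trial$images[[id]]
    excl <- if (is.null(exclusion_rules)) NULL else
      exclude_obstacles(img, exclusion_rules(img$view))
    seg <- withCallingHandlers(segment(img, excl, params),
                               warning = function(w) invokeRestart("muffleWarning"))
    rows[[i]] <- extract_traits(img, seg, ...)
    truth <- trial$truth$masks[[id]]
    jac[i] <- if (is.null(truth)) NA_real_ else mask_jaccard(seg$roi, truth)
  }
  out <- do.call(rbind, rows)
  attr(out, "jaccard") <- stats::setNames(jac, names(trial$images))
  out
}

#' Reshape a wide trait table to long format
#'
#' @param traits wide trait table from [trial_trait_table()].
#' @return Long data frame with columns (plant_id, variety, treatment,
#'   stage, day, view, trait_name, value).
#' @export
traits_to_long <- function(traits) {
  tn <- intersect(trait_names(), names(traits))
  out <- do.call(rbind, lapply(tn, function(t) {
    data.frame(plant_id = traits$plant_id, variety = traits$variety,
               treatment = traits$treatment, stage = traits$stage,
               day = traits$day, view = traits$view,
               trait_name = t, value = traits[[t]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
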