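#' Rectangle annotation (major vascular bundle)
#' @param cx,cy centre coordinates (px).
#' @param width,height side lengths (px, > 0).
#' @return object of class `rect_annotation`.
#' @export
rect_annotation <- function(cx, cy, width, height) {
  stopifnot(width > 0, height > 0)
  structure(list(centre = c(cx, cy), width = width, height = height),
            class = "rect_annotation")
}

#' Oval annotation (minor vascular bundle)
#' @param cx,cy centre coordinates (px).
#' @param a,b semi-axes (px, > 0).
#' @param angle orientation in radians (default 0).
#' @return object of class `oval_annotation`.
#' @export
oval_annotation <- function(cx, cy, a, b, angle = 0) {
  stopifnot(a > 0, b > 0)
  structure(list(centre = c(cx, cy), semi_axes = c(a, b), angle = angle),
            class = "oval_annotation")
}

#' Baseline between the two major-bundle rectangle centres
#'
#' The segment joining the centres of the two rectangles fitted to the
#' major vascular bundles; its length normalizes every minor-bundle
#' distribution feature.
#'
#' @param rA,rB [rect_annotation()] objects with distinct centres.
#' @return list of class `vb_baseline` with `p1`, `p2`, `length`.
#' @export
baseline_from_rects <- function(rA, rB) {
  stopifnot(inherits(rA, "rect_annotation"), inherits(rB, "rect_annotation"))
  len <- sqrt(sum((rA$centre - rB$centre)^2))
  if (len <= .Machine$double.eps) {
    stop("degenerate baseline: rectangle centres coincide")
  }
  structure(list(p1 = rA$centre, p2 = rB$centre, length = len),
            class = "vb_baseline")
}

#' Sum of perpendicular distances to the baseline, over baseline length
#'
#' `Ratio`: the absolute perpendicular distances from each minor-bundle
#' centre to the (infinite) line through the baseline are summed and
#' divided by the baseline length. Distances are unsigned and feet are
#' not clipped to the segment.
#'
#' @param centres 2-column matrix of centres (0 or more rows).
#' @param b a [baseline_from_rects()] baseline.
#' @return dimensionless ratio (0 for an empty centre set).
#' @export
mnvb_ratio <- function(centres, b) {
  stopifnot(inherits(b, "vb_baseline"))
  p <- as.matrix(centres)
  if (!nrow(p)) return(0)
  d <- b$p2 - b$p1
  # |cross product| / |d| = distance to the infinite line
  num <- abs((p[, 1] - b$p1[1]) * d[2] - (p[, 2] - b$p1[2]) * d[1])
  sum(num / b$length) / b$length
}

#' Sum of distances to the baseline midpoint, over baseline length
#'
#' `Ratio2`: Euclidean distances from each minor-bundle centre to the
#' midpoint of the baseline, summed and divided by the baseline length.
#'
#' @inheritParams mnvb_ratio
#' @return dimensionless ratio (0 for an empty centre set).
#' @export
mnvb_ratio2 <- function(centres, b) {
  stopifnot(inherits(b, "vb_baseline"))
  p <- as.matrix(centres)
  if (!nrow(p)) return(0)
  mid <- (b$p1 + b$p2) / 2
  sum(sqrt((p[, 1] - mid[1])^2 + (p[, 2] - mid[2])^2)) / b$length
}

#' Shortest tour through the minor-bundle centres, over baseline length
#'
#' @inheritParams mnvb_ratio
#' @param time_budget heuristic budget in seconds, see
#'   [shortest_tour_length()].
#' @return dimensionless ratio (0 for fewer than 2 centres).
#' @export
salesman_ratio <- function(centres, b, time_budget = 300) {
  stopifnot(inherits(b, "vb_baseline"))
  shortest_tour_length(centres, time_budget)$length / b$length
}

#' Scene annotation: two rectangles, oval centres, optional contours
#'
#' @param mjvb_rects list of exactly two [rect_annotation()].
#' @param mnvb_ovals list of [oval_annotation()] (possibly empty).
#' @param mjvb_contours list of 0--2 [vb_contour()] outlines of the
#'   major bundles (used for shape features when present).
#' @param label optional cultivar name.
#' @param scene_id optional identifier.
#' @return object of class `scene_annotation`. Warns when an oval
#'   centre's projection falls outside the baseline span.
#' @export
scene_annotation <- function(mjvb_rects, mnvb_ovals = list(),
                             mjvb_contours = list(), label = NA_character_,
                             scene_id = NA_character_) {
  if (length(mjvb_rects) != 2L) {
    stop("a scene needs exactly two major-bundle rectangles, got ",
         length(mjvb_rects))
  }
  stopifnot(all(vapply(mjvb_rects, inherits, logical(1), "rect_annotation")),
            all(vapply(mnvb_ovals, inherits, logical(1), "oval_annotation")),
            length(mjvb_contours) <= 2L)
  b <- baseline_from_rects(mjvb_rects[[1]], mjvb_rects[[2]])
  if (length(mnvb_ovals)) {
    d <- (b$p2 - b$p1) / b$length
    tproj <- vapply(mnvb_ovals, function(o) {
      sum((o$centre - b$p1) * d)
    }, numeric(1))
    if (any(tproj < 0 | tproj > b$length)) {
      warning("some oval centres lie outside the span between the ",
              "rectangle centres")
    }
  }
  structure(list(mjvb_rects = mjvb_rects, mnvb_ovals = mnvb_ovals,
                 mjvb_contours = mjvb_contours, label = label,
                 scene_id = scene_id),
            class = "scene_annotation")
}

#' Minor-bundle distribution features of a scene
#'
#' The four distribution descriptors: the count of minor bundles
#' between the two major bundles, and the three baseline-normalized
#' ratios ([mnvb_ratio()], [mnvb_ratio2()], [salesman_ratio()]). All
#' are invariant under rigid motion and uniform scaling of the scene.
#'
#' @param scene a [scene_annotation()].
#' @param time_budget heuristic tour budget in seconds.
#' @return list with `number`, `ratio`, `ratio2`, `salesman_ratio`.
#' @export
mnvb_features <- function(scene, time_budget = 300) {
  stopifnot(inherits(scene, "scene_annotation"))
  b <- baseline_from_rects(scene$mjvb_rects[[1]], scene$mjvb_rects[[2]])
  centres <- do.call(rbind, lapply(scene$mnvb_ovals, `[[`, "centre"))
  if (is.null(centres)) centres <- matrix(numeric(0), 0, 2)
  list(
    number = nrow(centres),
    ratio = mnvb_ratio(centres, b),
    ratio2 = mnvb_ratio2(centres, b),
    salesman_ratio = salesman_ratio(centres, b, time_budget)
  )
}

#' Canonical feature names, in classifier input order
#' @return character vector of the nine feature names.
#' @export
feature_names <- function() {
  c("number", "ratio", "ratio2", "salesman_ratio", "form_factor",
    "aspect_ratio", "rectangularity", "eccentricity", "residual")
}

#' Assemble the nine-descriptor feature vector of one scene
#'
#' Combines the four distribution features with the five shape
#' features. When shape features from both major bundles are supplied
#' they are averaged by default (`combine = "mean"`); `"first"` keeps
#' only the first bundle.
#'
#' @param mn output of [mnvb_features()].
#' @param mj_list list of 1--2 [mjvb_features()] outputs.
#' @param label optional cultivar name.
#' @param combine `"mean"` (default) or `"first"`.
#' @return one-row data.frame with the nine features (canonical order)
#'   and a `label` column.
#' @export
assemble_feature_vector <- function(mn, mj_list, label = NA_character_,
                                    combine = c("mean", "first")) {
  combine <- match.arg(combine)
  if (!length(mj_list)) stop("at least one set of shape features is required")
  if (length(mj_list) > 2L) stop("at most two major bundles per scene")
  shape_names <- c("form_factor", "aspect_ratio", "rectangularity",
                   "eccentricity", "residual")
  mj <- if (combine == "first" || length(mj_list) == 1L) {
    mj_list[[1]]
  } else {
    as.list(colMeans(do.call(rbind, lapply(mj_list, function(m) {
      unlist(m[shape_names])
    }))))
  }
  out <- data.frame(
    number = mn$number, ratio = mn$ratio, ratio2 = mn$ratio2,
    salesman_ratio = mn$salesman_ratio,
    form_factor = mj$form_factor, aspect_ratio = mj$aspect_ratio,
    rectangularity = mj$rectangularity, eccentricity = mj$eccentricity,
    residual = mj$residual,
    label = label, stringsAsFactors = FALSE
  )
  out[, c(feature_names(), "label")]
}

#' Extract the full feature vector of one annotated scene
#'
#' Runs [mnvb_features()] on the annotation geometry and
#' [mjvb_features()] on each stored major-bundle contour, then
#' assembles the canonical nine-feature row.
#'
#' @param scene a [scene_annotation()] with at least one contour.
#' @param time_budget heuristic tour budget in seconds.
#' @param combine how to combine two bundles' shape features, see
#'   [assemble_feature_vector()].
#' @return one-row data.frame (nine features + label).
#' @export
scene_features <- function(scene, time_budget = 300,
                           combine = c("mean", "first")) {
  stopifnot(inherits(scene, "scene_annotation"))
  if (!length(scene$mjvb_contours)) {
    stop("scene ", scene$scene_id,
         " carries no major-bundle contour; run the preprocessing chain ",
         "or supply contours in the annotation")
  }
  mn <- mnvb_features(scene, time_budget)
  mj <- lapply(scene$mjvb_contours, mjvb_features)
  out <- assemble_feature_vector(mn, mj, scene$label, combine)
  cbind(scene_id = scene$scene_id, out, stringsAsFactors = FALSE)
}
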