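#' Write scene annotations to CSV
#'
#' One row per annotated object; columns `scene_id`, `role`
#' (`mjvb_rect` or `mnvb_oval`), `cx`, `cy`, `width`, `height`,
#' `angle_deg`, `label`. For ovals, `width`/`height` are the full axes
#' (2a, 2b). Contours are stored separately, see [write_contour_csv()].
#'
#' @param scenes list of [scene_annotation()].
#' @param path output CSV path.
#' @export
write_annotations <- function(scenes, path) {
  rows <- lapply(scenes, function(sc) {
    r <- lapply(seq_along(sc$mjvb_rects), function(i) {
      rr <- sc$mjvb_rects[[i]]
      data.frame(scene_id = sc$scene_id, role = "mjvb_rect",
                 cx = rr$centre[1], cy = rr$centre[2],
                 width = rr$width, height = rr$height, angle_deg = 0,
                 label = sc$label, stringsAsFactors = FALSE)
    })
    o <- lapply(sc$mnvb_ovals, function(ov) {
      data.frame(scene_id = sc$scene_id, role = "mnvb_oval",
                 cx = ov$centre[1], cy = ov$centre[2],
                 width = 2 * ov$semi_axes[1], height = 2 * ov$semi_axes[2],
                 angle_deg = ov$angle * 180 / pi,
                 label = sc$label, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(r, o))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read scene annotations from CSV
#'
#' Inverse of [write_annotations()]. Each scene must carry exactly two
#' `mjvb_rect` rows; a malformed scene aborts with its identifier.
#'
#' @param path annotation CSV path.
#' @param contours_dir optional directory of per-scene contour CSVs
#'   (`<scene_id>_1.csv`, `<scene_id>_2.csv`), attached when present.
#' @return list of [scene_annotation()].
#' @export
read_annotations <- function(path, contours_dir = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scene_id", "role", "cx", "cy", "width", "height")
  if (!all(need %in% names(df))) {
    stop("annotation CSV lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$scene_id), function(g) {
    id <- g$scene_id[1]
    rects <- g[g$role == "mjvb_rect", , drop = FALSE]
    if (nrow(rects) != 2L) {
      stop("scene ", id, " has ", nrow(rects),
           " major-bundle rectangle(s); exactly 2 required")
    }
    ovals <- g[g$role == "mnvb_oval", , drop = FALSE]
    contours <- list()
    if (!is.null(contours_dir)) {
      for (k in 1:2) {
        f <- file.path(contours_dir, sprintf("%s_%d.csv", id, k))
        if (file.exists(f)) {
          contours[[length(contours) + 1L]] <- read_contour_csv(f)
        }
      }
    }
    scene_annotation(
      mjvb_rects = lapply(seq_len(2), function(i) {
        rect_annotation(rects$cx[i], rects$cy[i],
                        rects$width[i], rects$height[i])
      }),
      mnvb_ovals = lapply(seq_len(nrow(ovals)), function(i) {
        ang <- if ("angle_deg" %in% names(ovals)) {
          ovals$angle_deg[i] * pi / 180
        } else 0
        oval_annotation(ovals$cx[i], ovals$cy[i],
                        ovals$width[i] / 2, ovals$height[i] / 2, ang)
      }),
      mjvb_contours = contours,
      label = if ("label" %in% names(g)) g$label[1] else NA_character_,
      scene_id = id
    )
  })
}

#' Write a contour as CSV (`point_index`, `x`, `y`)
#' @param c a [vb_contour()].
#' @param path output path.
#' @export
write_contour_csv <- function(c, path) {
  stopifnot(inherits(c, "vb_contour"))
  p <- unclass(c)
  utils::write.csv(
    data.frame(point_index = seq_len(nrow(p)), x = p[, 1], y = p[, 2]),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a contour from CSV
#' @param path CSV with columns `point_index`, `x`, `y`.
#' @return a [vb_contour()].
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path)
  vb_contour(as.matrix(df[order(df$point_index), c("x", "y")]))
}

#' Extract features for all scenes of an annotation file
#'
#' @param scenes list of [scene_annotation()] (with contours attached).
#' @param time_budget heuristic tour budget in seconds.
#' @return feature table: one row per scene, `scene_id`, nine features,
#'   `label`.
#' @export
extract_features <- function(scenes, time_budget = 300) {
  do.call(rbind, lapply(scenes, scene_features, time_budget = time_budget))
}

#' Write / read a feature table CSV
#' @param features feature table as returned by [extract_features()].
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing)) {
    stop("feature CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}
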