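#' Class specification for the synthetic scene generator
#'
#' Describes one cultivar-like class: how many minor bundles lie
#' between the two major bundles, how far they scatter from the
#' baseline, and the size/shape statistics of the major bundles. The
#' generator renders what the real preparation shows after DAPI-filter
#' fluorescence imaging: two bright elongated major-bundle blobs
#' flanking a row of small minor-bundle blobs scattered about the
#' line joining the major-bundle centres.
#'
#' @param name class (cultivar) name.
#' @param mnvb_count_range integer vector of admissible minor-bundle
#'   counts (e.g. `6:8`).
#' @param scatter_sd sd of minor-bundle centre offsets perpendicular to
#'   the baseline (px).
#' @param spacing_jitter sd of along-baseline position jitter (px).
#' @param baseline_length distance between the two major-bundle
#'   centres (px).
#' @param mjvb_axes major-bundle ellipse semi-axes `c(a, b)` (px).
#' @param axis_jitter relative sd of per-scene semi-axis variation.
#' @param boundary_noise_sd radial boundary noise of the major-bundle
#'   contour (px).
#' @param spike_density expected number of hair-like spikes per
#'   contour (Poisson).
#' @param spike_height spike height (px).
#' @param fg_intensity blue-channel foreground intensity (0--255).
#' @param bg_noise_sd background Gaussian noise sd (intensity units).
#' @return list of class `class_spec`.
#' @export
class_spec <- function(name, mnvb_count_range, scatter_sd, spacing_jitter,
                       baseline_length, mjvb_axes, axis_jitter = 0.05,
                       boundary_noise_sd = 0.8, spike_density = 1,
                       spike_height = 6, fg_intensity = 220,
                       bg_noise_sd = 5) {
  stopifnot(length(mnvb_count_range) >= 1, all(mnvb_count_range >= 0),
            scatter_sd >= 0, spacing_jitter >= 0, baseline_length > 0,
            length(mjvb_axes) == 2, all(mjvb_axes > 0),
            boundary_noise_sd >= 0, spike_density >= 0, bg_noise_sd >= 0)
  structure(list(name = name,
                 mnvb_count_range = as.integer(mnvb_count_range),
                 scatter_sd = scatter_sd, spacing_jitter = spacing_jitter,
                 baseline_length = baseline_length, mjvb_axes = mjvb_axes,
                 axis_jitter = axis_jitter,
                 boundary_noise_sd = boundary_noise_sd,
                 spike_density = spike_density, spike_height = spike_height,
                 fg_intensity = fg_intensity, bg_noise_sd = bg_noise_sd),
            class = "class_spec")
}

#' Default five-class specification set
#'
#' Five well-separated classes named after the five date-palm cultivars
#' of the original study. The separation (distinct minor-bundle count
#' ranges, scatter levels and major-bundle elongations) is chosen for
#' testability -- real inter-cultivar effect sizes are unknown because
#' no image data are deposited. One class carries more than twelve
#' minor bundles so the heuristic branch of the tour computation is
#' exercised, as happens for the Hewlat al Jouf cultivar.
#'
#' @return named list of five [class_spec()] objects.
#' @export
default_class_specs <- function() {
  list(
    hewlat_al_jouf = class_spec("hewlat_al_jouf", 13:16,
      scatter_sd = 6, spacing_jitter = 5, baseline_length = 620,
      mjvb_axes = c(60, 40), spike_density = 2, spike_height = 8),
    khlas = class_spec("khlas", 6:8,
      scatter_sd = 14, spacing_jitter = 6, baseline_length = 500,
      mjvb_axes = c(75, 30), spike_density = 1, spike_height = 6),
    nabot_soltan = class_spec("nabot_soltan", 9:11,
      scatter_sd = 3, spacing_jitter = 4, baseline_length = 650,
      mjvb_axes = c(50, 47), spike_density = 0, spike_height = 0),
    shishi = class_spec("shishi", 4:5,
      scatter_sd = 22, spacing_jitter = 8, baseline_length = 440,
      mjvb_axes = c(80, 24), spike_density = 3, spike_height = 10),
    um_raheem = class_spec("um_raheem", 11:12,
      scatter_sd = 16, spacing_jitter = 5, baseline_length = 700,
      mjvb_axes = c(55, 34), spike_density = 1, spike_height = 6)
  )
}

# noisy ellipse polygon (optionally with outward hair spikes)
.noisy_ellipse_contour <- function(centre, a, b, angle, n_points,
                                   noise_sd, n_spikes, spike_height) {
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  r_noise <- if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else
    numeric(n_points)
  ex <- (a + r_noise) * cos(t)
  ey <- (b + r_noise) * sin(t)
  if (n_spikes > 0) {
    idx <- sample.int(n_points, min(n_spikes, n_points))
    scale_x <- 1 + spike_height / a
    scale_y <- 1 + spike_height / b
    ex[idx] <- ex[idx] * scale_x
    ey[idx] <- ey[idx] * scale_y
  }
  x <- centre[1] + ex * cos(angle) - ey * sin(angle)
  y <- centre[2] + ex * sin(angle) + ey * cos(angle)
  vb_contour(cbind(x, y))
}

# fill pixels whose centres fall inside a polygon (even-odd rule)
.fill_polygon <- function(canvas, poly, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  cols <- max(1L, floor(xr[1])):min(w, ceiling(xr[2]))
  rows <- max(1L, floor(yr[1])):min(h, ceiling(yr[2]))
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  canvas[cbind(rep(rows, times = length(cols))[inside],
               rep(cols, each = length(rows))[inside])] <- value
  canvas
}

#' Generate one synthetic cross-section scene
#'
#' Draws the scene geometry from the class specification (all
#' randomness from `seed`): two major-bundle ellipse contours with
#' boundary noise and optional hair spikes, `N` minor-bundle centres
#' jittered about the baseline, and the exactly matching ground-truth
#' annotation (rectangles fitting the noise-free ellipse extents, oval
#' centres, contours, class label). When `render = TRUE` an RGB raster
#' is produced with the signal concentrated in the blue channel.
#'
#' @param spec a [class_spec()].
#' @param seed integer seed (fully determines the scene).
#' @param width,height canvas size in px (default 1024 x 512).
#' @param render render the raster image (default TRUE; feature
#'   extraction needs only the annotation).
#' @param scene_id identifier stored in the annotation.
#' @return list of class `synthetic_scene` with `image` (a
#'   [raster_image()] or NULL), `truth` (a [scene_annotation()]) and
#'   `class_name`.
#' @export
generate_scene <- function(spec, seed, width = 1024, height = 512,
                           render = TRUE, scene_id = NULL) {
  stopifnot(inherits(spec, "class_spec"))
  set.seed(seed)
  if (is.null(scene_id)) scene_id <- sprintf("%s_%d", spec$name, seed)
  cx <- width / 2; cy <- height / 2
  L <- spec$baseline_length
  centres_mj <- list(c(cx - L / 2, cy), c(cx + L / 2, cy))

  contours <- list()
  rects <- list()
  for (k in 1:2) {
    a <- spec$mjvb_axes[1] * (1 + stats::rnorm(1, 0, spec$axis_jitter))
    b <- spec$mjvb_axes[2] * (1 + stats::rnorm(1, 0, spec$axis_jitter))
    ang <- pi / 2 + stats::rnorm(1, 0, 0.05)  # elongation across the blade
    n_spikes <- stats::rpois(1, spec$spike_density)
    contours[[k]] <- .noisy_ellipse_contour(
      centres_mj[[k]], a, b, ang, 256, spec$boundary_noise_sd,
      n_spikes, spec$spike_height)
    half_w <- sqrt(a^2 * cos(ang)^2 + b^2 * sin(ang)^2)
    half_h <- sqrt(a^2 * sin(ang)^2 + b^2 * cos(ang)^2)
    rects[[k]] <- rect_annotation(centres_mj[[k]][1], centres_mj[[k]][2],
                                  2 * half_w, 2 * half_h)
  }

  n_mn <- if (length(spec$mnvb_count_range) == 1L) {
    spec$mnvb_count_range
  } else {
    sample(spec$mnvb_count_range, 1)
  }
  margin <- max(spec$mjvb_axes) + 20
  ovals <- list()
  if (n_mn > 0) {
    t0 <- seq(margin, L - margin, length.out = n_mn)
    t_pos <- pmin(pmax(t0 + stats::rnorm(n_mn, 0, spec$spacing_jitter),
                       margin), L - margin)
    off <- stats::rnorm(n_mn, 0, spec$scatter_sd)
    for (i in seq_len(n_mn)) {
      oa <- 5 * (1 + stats::rnorm(1, 0, 0.1))
      ob <- 4 * (1 + stats::rnorm(1, 0, 0.1))
      ovals[[i]] <- oval_annotation(centres_mj[[1]][1] + t_pos[i],
                                    cy + off[i], oa, ob)
    }
  }

  all_pts <- rbind(do.call(rbind, lapply(contours, unclass)),
                   do.call(rbind, lapply(ovals, `[[`, "centre")))
  if (min(all_pts) < 0 || max(all_pts[, 1]) > width ||
      max(all_pts[, 2]) > height) {
    stop("scene geometry exceeds the canvas; use a larger width/height")
  }

  truth <- scene_annotation(rects, ovals, contours,
                            label = spec$name, scene_id = scene_id)

  img <- NULL
  if (render) {
    blue <- matrix(0, height, width)
    for (k in 1:2) {
      blue <- .fill_polygon(blue, unclass(contours[[k]]),
                            spec$fg_intensity)
    }
    for (ov in ovals) {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      poly <- cbind(ov$centre[1] + ov$semi_axes[1] * cos(th),
                    ov$centre[2] + ov$semi_axes[2] * sin(th))
      blue <- .fill_polygon(blue, poly, spec$fg_intensity * 0.8)
    }
    if (spec$bg_noise_sd > 0) {
      blue <- blue + matrix(stats::rnorm(height * width, 0,
                                         spec$bg_noise_sd), height, width)
    }
    blue <- pmin(255, pmax(0, blue))
    a <- array(0, dim = c(height, width, 3))
    a[, , 1] <- round(blue * 0.10)
    a[, , 2] <- round(blue * 0.15)
    a[, , 3] <- blue
    img <- raster_image(a)
  }
  structure(list(image = img, truth = truth, class_name = spec$name),
            class = "synthetic_scene")
}

#' Generate a labelled cohort and its feature table
#'
#' Generates `counts[k]` scenes of class `specs[[k]]` and runs the
#' feature-extraction pipeline on each scene's ground-truth annotation
#' (minor-bundle features from the annotated centres, shape features
#' from the true major-bundle contours). All per-scene seeds derive
#' deterministically from the root `seed`. The default class counts
#' (14, 22, 17, 20, 12 -- 85 scenes) reproduce the per-cultivar sample
#' sizes of the original cohort.
#'
#' @param specs list of [class_spec()] (default [default_class_specs()]).
#' @param counts scenes per class (same length as `specs`).
#' @param seed root seed.
#' @param time_budget heuristic tour budget per scene in seconds
#'   (default 1; synthetic instances are small enough that the 2-opt
#'   local optimum is reached well within it).
#' @param render render raster images too (default FALSE; much faster).
#' @param width,height canvas size passed to [generate_scene()].
#' @return list with `scenes` (list of `synthetic_scene`) and
#'   `features` (data.frame: scene_id, nine features, label).
#' @export
generate_cohort <- function(specs = default_class_specs(),
                            counts = c(14, 22, 17, 20, 12), seed = 1,
                            time_budget = 1, render = FALSE,
                            width = 1024, height = 512) {
  stopifnot(length(specs) == length(counts), all(counts >= 1))
  total <- sum(counts)
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, total)
  scenes <- vector("list", total)
  idx <- 0L
  for (k in seq_along(specs)) {
    for (r in seq_len(counts[k])) {
      idx <- idx + 1L
      scenes[[idx]] <- generate_scene(
        specs[[k]], scene_seeds[idx], width = width, height = height,
        render = render,
        scene_id = sprintf("%s_%03d", specs[[k]]$name, r))
    }
  }
  features <- do.call(rbind, lapply(scenes, function(sc) {
    scene_features(sc$truth, time_budget = time_budget)
  }))
  rownames(features) <- NULL
  list(scenes = scenes, features = features)
}
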