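#' Preprocess a fluorescence image into a smoothed bundle contour
#'
#' The full preprocessing chain for major-bundle shape measurement:
#' extract the blue channel, optional linear brightness/contrast
#' adjustment, threshold to a binary mask (Otsu by default), remove
#' small particles, trace the outer boundary of the largest component,
#' and smooth it with a periodic cubic B-spline.
#'
#' @param img a 3-channel [raster_image()] (or 1-channel, in which case
#'   channel extraction is skipped).
#' @param channel colour channel to analyse (default `"blue"`).
#' @param method threshold method, `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold level when `method = "fixed"`.
#' @param gain,offset optional linear intensity adjustment (identity
#'   by default).
#' @param min_area particle-removal area threshold in px (default 64).
#' @param n_segments,n_samples B-spline smoothing parameters, see
#'   [smooth_contour_bspline()].
#' @param debug_dir when set, intermediate masks are written there as
#'   PGM images.
#' @return a smoothed [vb_contour()].
#' @export
preprocess_image <- function(img, channel = "blue",
                             method = c("otsu", "fixed"), threshold = NULL,
                             gain = 1, offset = 0, min_area = 64,
                             n_segments = 18, n_samples = 512,
                             debug_dir = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(img, "raster_image"))
  g <- if (img$channels == 3L) extract_channel(img, channel) else img
  g <- adjust_intensity(g, gain, offset)
  mask <- binarize(g, method, threshold)
  mask <- remove_small_particles(mask, min_area)
  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    write_mask_pnm(mask, file.path(debug_dir, "mask.pgm"))
  }
  raw <- trace_contour(mask)
  smooth_contour_bspline(raw, n_segments, n_samples)
}

# ---- logging -------------------------------------------------------------

.log_level <- function() {
  lv <- getOption("vbmorph.log_level", "info")
  match(lv, c("debug", "info", "warn", "error"))
}

.log <- function(level, ...) {
  if (match(level, c("debug", "info", "warn", "error")) >= .log_level()) {
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  }
}

# FNV-1a hash of a string, reported as 8 hex digits (config provenance);
# multiplication is split so intermediates stay exact in doubles
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> extract -> train -> cross-validate -> variable
#' importance, writing `features.csv`, `model.json`, `cv_report.csv`,
#' `importance.csv` and a JSON run manifest (seed, parameters, config
#' hash) into `out_dir`. Fully deterministic under a fixed seed.
#'
#' @param out_dir output directory (created if absent).
#' @param seed root seed.
#' @param counts scenes per class (default the original cohort sizes
#'   14, 22, 17, 20, 12).
#' @param n_runs cross-validation runs (default 10).
#' @param train_probability training-group probability (default 0.7).
#' @param hidden hidden-layer width (default 10).
#' @param n_permutations importance permutations (default 100).
#' @param tsp_budget heuristic tour budget per scene, seconds.
#' @param render also write rendered scene images (PPM; default FALSE).
#' @return (invisibly) list with the feature table, model, CV report
#'   and importance table.
#' @export
run_pipeline <- function(out_dir, seed = 1, counts = c(14, 22, 17, 20, 12),
                         n_runs = 10, train_probability = 0.7, hidden = 10,
                         n_permutations = 100, tsp_budget = 1,
                         render = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(seed = seed, counts = counts, n_runs = n_runs,
              train_probability = train_probability, hidden = hidden,
              n_permutations = n_permutations, tsp_budget = tsp_budget)
  cfg_hash <- .fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  t0 <- Sys.time()

  .log("info", "simulate: ", sum(counts), " scenes, seed ", seed)
  cohort <- generate_cohort(counts = counts, seed = seed,
                            time_budget = tsp_budget, render = render)
  feats <- cohort$features
  write_features(feats, file.path(out_dir, "features.csv"))
  write_annotations(lapply(cohort$scenes, `[[`, "truth"),
                    file.path(out_dir, "annotations.csv"))
  if (render) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (sc in cohort$scenes) {
      write_pnm(sc$image,
                file.path(img_dir, paste0(sc$truth$scene_id, ".ppm")),
                ascii = FALSE)
    }
  }

  X <- feats[, feature_names()]
  .log("info", "train: hidden ", hidden)
  model <- mlp_train(X, feats$label, hidden = hidden, seed = seed)
  write_mlp_json(model, file.path(out_dir, "model.json"))

  .log("info", "crossval: ", n_runs, " runs")
  report <- repeated_cv(X, feats$label, n_runs = n_runs,
                        train_probability = train_probability,
                        hidden = hidden, seed = seed)
  runs <- report$runs
  utils::write.csv(runs, file.path(out_dir, "cv_report.csv"),
                   row.names = FALSE)

  .log("info", "importance: ", n_permutations, " permutations")
  imp <- variable_importance(model, X, feats$label,
                             n_permutations = n_permutations, seed = seed)
  utils::write.csv(imp, file.path(out_dir, "importance.csv"),
                   row.names = FALSE)

  manifest <- c(cfg, list(
    config_hash = cfg_hash,
    n_scenes = nrow(feats),
    mean_test_accuracy = report$mean_test,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = c("features.csv", "annotations.csv", "model.json",
                "cv_report.csv", "importance.csv")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log("info", "done: mean testing accuracy ", report$mean_test, "%")
  invisible(list(features = feats, model = model, report = report,
                 importance = imp))
}
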