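#' Binary mask container
#'
#' @param values matrix of 0/1 values (height x width).
#' @return object of class `binary_mask` with `width`, `height`, `values`.
#' @export
binary_mask <- function(values) {
  stopifnot(is.matrix(values))
  v <- values
  storage.mode(v) <- "integer"
  if (anyNA(v) || !all(v %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  structure(list(width = ncol(v), height = nrow(v), values = v),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              x$width, x$height, sum(x$values)))
  invisible(x)
}

#' Otsu threshold of an 8-bit intensity sample
#'
#' Exhaustive sweep over levels 1..255 maximizing the between-class
#' variance of the two groups `x < t` and `x >= t`.
#'
#' @param x integer intensities in \[0, 255\].
#' @return the selected threshold level (pixels >= level are foreground).
#' @export
otsu_threshold <- function(x) {
  h <- tabulate(as.integer(x) + 1L, nbins = 256L)
  n <- sum(h)
  if (n == 0L) stop("empty intensity sample")
  lev <- 0:255
  csum <- cumsum(h)            # count of pixels with value <= lev
  cmean <- cumsum(h * lev)     # intensity sum with value <= lev
  total <- cmean[256]
  best_t <- 1L
  best_v <- -1
  for (t in 1:255) {
    n0 <- csum[t]              # pixels < t  (values 0..t-1)
    n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- cmean[t] / n0
    mu1 <- (total - cmean[t]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

#' Threshold a grayscale image to a binary mask
#'
#' A pixel becomes foreground (1) iff its intensity is greater than or
#' equal to the threshold. The default picks the threshold by Otsu's
#' method; a fixed manual level mirrors the original manual workflow.
#'
#' @param img single-channel [raster_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold intensity level, required when `method = "fixed"`.
#' @return a [binary_mask()] of identical dimensions.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(img, "raster_image"))
  if (img$channels != 1L) stop("binarize requires a single-channel image")
  v <- matrix(img$values[, , 1], img$height, img$width)
  t <- switch(method,
    fixed = {
      if (is.null(threshold)) {
        stop("method = \"fixed\" requires a `threshold`")
      }
      threshold
    },
    otsu = otsu_threshold(v)
  )
  binary_mask((v >= t) * 1L)
}

# 8-connected component labelling by vectorized frontier expansion.
# Returns an integer matrix of labels (0 = background), labels in
# arbitrary order.
label_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  h <- mask$height; w <- mask$width
  fg <- mask$values == 1L
  labels <- matrix(0L, h, w)
  todo <- which(fg)
  if (!length(todo)) return(labels)
  # neighbour offsets in column-major linear indices, guarded at borders
  row_of <- function(idx) ((idx - 1L) %% h) + 1L
  col_of <- function(idx) ((idx - 1L) %/% h) + 1L
  lab <- 0L
  unvisited <- fg
  repeat {
    seed <- which(unvisited)
    if (!length(seed)) break
    lab <- lab + 1L
    frontier <- seed[1L]
    unvisited[frontier] <- FALSE
    labels[frontier] <- lab
    while (length(frontier)) {
      r <- row_of(frontier); cc <- col_of(frontier)
      nb <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        ok <- r + dr >= 1L & r + dr <= h & cc + dc >= 1L & cc + dc <= w
        if (any(ok)) {
          nb <- c(nb, (cc[ok] + dc - 1L) * h + (r[ok] + dr))
        }
      }
      nb <- unique(nb[unvisited[nb]])
      if (length(nb)) {
        unvisited[nb] <- FALSE
        labels[nb] <- lab
      }
      frontier <- nb
    }
  }
  labels
}

#' Remove small foreground particles
#'
#' Deletes every 8-connected foreground component whose pixel area is
#' strictly below `min_area`; larger components are untouched. This is
#' the documented, testable replacement for the proprietary "particle
#' remove" debris filter of the original acquisition software.
#'
#' @param mask a [binary_mask()].
#' @param min_area minimum component area in pixels (kept iff
#'   `area >= min_area`). Default 64.
#' @return filtered [binary_mask()], same dimensions.
#' @export
remove_small_particles <- function(mask, min_area = 64) {
  stopifnot(inherits(mask, "binary_mask"), min_area >= 1)
  labels <- label_components(mask)
  if (!any(labels > 0L)) return(mask)
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_area)
  binary_mask(matrix(as.integer(labels %in% keep),
                     mask$height, mask$width))
}
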