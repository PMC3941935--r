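#' Closed contour container
#'
#' An ordered, closed sequence of sub-pixel 2D points in image
#' coordinates (origin top-left, x rightward, y downward). The closing
#' edge from the last point back to the first is implicit.
#'
#' @param points numeric matrix with two columns (x, y), at least 3 rows.
#'   A duplicated final point is dropped.
#' @return object of class `vb_contour` (a matrix with columns x, y).
#' @export
vb_contour <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("contour points must have two columns (x, y)")
  if (nrow(p) > 1L && isTRUE(all(p[1, ] == p[nrow(p), ]))) {
    p <- p[-nrow(p), , drop = FALSE]
  }
  if (nrow(p) < 3L) stop("a contour needs at least 3 points")
  colnames(p) <- c("x", "y")
  structure(p, class = c("vb_contour", "matrix"))
}

#' Signed polygon area (shoelace formula)
#' @param c a [vb_contour()] or 2-column matrix.
#' @return signed area; positive for the package's canonical orientation.
#' @export
polygon_area <- function(c) {
  p <- unclass(c)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Closed polygon perimeter
#' @param c a [vb_contour()] or 2-column matrix.
#' @return total arc length including the closing edge.
#' @export
polygon_perimeter <- function(c) {
  p <- unclass(c)
  d <- rbind(diff(p), p[1, ] - p[nrow(p), ])
  sum(sqrt(rowSums(d^2)))
}

#' Trace the outer boundary of the largest foreground component
#'
#' Pixel (row i, col j) is treated as the unit square
#' \[j-1, j\] x \[i-1, i\]; the boundary polygon runs along pixel edges
#' with the component interior on its left, which makes the shoelace
#' area of the returned polygon equal the component's pixel count (for
#' hole-free components). Components are 8-connected; at diagonal
#' "pinch" vertices the trace crosses into the diagonal neighbour.
#'
#' @param mask a [binary_mask()] with at least one foreground pixel.
#' @return a [vb_contour()] of grid vertices, positively oriented.
#' @export
trace_contour <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  labels <- label_components(mask)
  if (!any(labels > 0L)) stop("mask contains no foreground object")
  areas <- tabulate(labels[labels > 0L])
  big <- which.max(areas)
  fg <- labels == big
  h <- nrow(fg); w <- ncol(fg)

  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  bg_n <- !pad[1:h, 2:(w + 1L)]
  bg_s <- !pad[3:(h + 2L), 2:(w + 1L)]
  bg_w <- !pad[2:(h + 1L), 1:w]
  bg_e <- !pad[2:(h + 1L), 3:(w + 2L)]

  edges <- NULL
  add_edges <- function(which_mat, x1, y1, x2, y2) {
    idx <- which(core & which_mat, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    i <- idx[, 1]; j <- idx[, 2]
    cbind(x1(i, j), y1(i, j), x2(i, j), y2(i, j))
  }
  edges <- rbind(
    # bg to the north: left-to-right along the pixel's top edge
    add_edges(bg_n, function(i, j) j - 1, function(i, j) i - 1,
                    function(i, j) j,     function(i, j) i - 1),
    # bg to the east: downward along the right edge
    add_edges(bg_e, function(i, j) j,     function(i, j) i - 1,
                    function(i, j) j,     function(i, j) i),
    # bg to the south: right-to-left along the bottom edge
    add_edges(bg_s, function(i, j) j,     function(i, j) i,
                    function(i, j) j - 1, function(i, j) i),
    # bg to the west: upward along the left edge
    add_edges(bg_w, function(i, j) j - 1, function(i, j) i,
                    function(i, j) j - 1, function(i, j) i - 1)
  )

  key <- function(x, y) y * (w + 2) + x + 1
  start_key <- key(edges[, 1], edges[, 2])
  by_start <- split(seq_len(nrow(edges)), start_key)
  used <- logical(nrow(edges))

  # turn preference: right, straight, left (interior stays on the left;
  # the right-most turn carries the trace across 8-connected pinches)
  turn_rank <- function(din, dout) {
    right <- c(din[2], -din[1])
    if (all(dout == right)) return(0)
    if (all(dout == din)) return(1)
    2
  }

  loops <- list()
  order_by_key <- order(start_key)
  for (e0 in order_by_key) {
    if (used[e0]) next
    loop <- matrix(NA_real_, nrow(edges) + 1L, 2L)
    n_in_loop <- 0L
    e <- e0
    start_v <- edges[e0, 1:2]
    repeat {
      used[e] <- TRUE
      n_in_loop <- n_in_loop + 1L
      loop[n_in_loop, ] <- edges[e, 1:2]
      v <- edges[e, 3:4]
      cand <- by_start[[as.character(key(v[1], v[2]))]]
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        if (!all(v == start_v)) stop("boundary walk failed to close")
        break
      }
      if (length(cand) > 1L) {
        din <- edges[e, 3:4] - edges[e, 1:2]
        ranks <- vapply(cand, function(k) {
          turn_rank(din, edges[k, 3:4] - edges[k, 1:2])
        }, numeric(1))
        cand <- cand[which.min(ranks)]
      }
      e <- cand[1L]
    }
    loops[[length(loops) + 1L]] <- loop[seq_len(n_in_loop), , drop = FALSE]
  }

  # outer boundary encloses any holes: it has the largest |area|
  areas_l <- vapply(loops, function(p) abs(polygon_area(p)), numeric(1))
  vb_contour(loops[[which.max(areas_l)]])
}

# uniform periodic cubic B-spline basis weights at local parameter s in [0,1)
.bspline_weights <- function(s) {
  cbind((1 - s)^3 / 6,
        (3 * s^3 - 6 * s^2 + 4) / 6,
        (-3 * s^3 + 3 * s^2 + 3 * s + 1) / 6,
        s^3 / 6)
}

# design matrix mapping m periodic control points to points at params u
.bspline_design <- function(u, m) {
  k <- floor(u)
  s <- u - k
  B <- .bspline_weights(s)
  N <- matrix(0, length(u), m)
  for (r in 0:3) {
    ctrl <- ((k + r - 1) %% m) + 1
    N[cbind(seq_along(u), ctrl)] <- N[cbind(seq_along(u), ctrl)] + B[, r + 1]
  }
  N
}

#' Smooth a closed contour with a periodic cubic B-spline
#'
#' Least-squares fit of a periodic uniform cubic B-spline with
#' `n_segments` control points to the input polygon (chord-length
#' parameterization), resampled at `n_samples` uniformly spaced
#' parameters. Few control points relative to the contour length
#' suppress hair-like excursions (short high-curvature spikes), which is
#' the purpose of the smoothing step before shape measurement.
#'
#' @param c a [vb_contour()].
#' @param n_segments number of spline segments / control points
#'   (default 18, within the working range 15--20).
#' @param n_samples number of output points (default 512; must be at
#'   least `3 * n_segments`).
#' @return a smoothed [vb_contour()] with exactly `n_samples` points.
#' @export
smooth_contour_bspline <- function(c, n_segments = 18, n_samples = 512) {
  stopifnot(inherits(c, "vb_contour"))
  if (n_samples < 3 * n_segments) {
    stop("n_samples must be at least 3 * n_segments")
  }
  p <- unclass(c)
  # drop consecutive duplicates (zero chords break the parameterization)
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < n_segments) {
    stop("contour has fewer points (", nrow(p), ") than control points (",
         n_segments, ")")
  }
  seg <- sqrt(rowSums(rbind(diff(p), p[1, ] - p[nrow(p), ])^2))
  s_cum <- c(0, cumsum(seg))
  total <- s_cum[length(s_cum)]
  u <- n_segments * s_cum[-length(s_cum)] / total
  N <- .bspline_design(u, n_segments)
  ctrl <- qr.solve(qr(N), p)
  # robust reweighting: isolated hair-like excursions get residuals far
  # above the robust scale of the bulk and are down-weighted (Cauchy
  # weights), so a short spike barely deflects the fitted curve
  for (it in 1:3) {
    r <- sqrt(rowSums((N %*% ctrl - p)^2))
    s <- max(stats::median(r) * 1.4826, 1e-6)
    w <- 1 / (1 + (r / (3 * s))^2)
    ctrl <- qr.solve(qr(N * w), p * w)
  }
  u_out <- n_segments * (seq_len(n_samples) - 1) / n_samples
  vb_contour(.bspline_design(u_out, n_segments) %*% ctrl)
}
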