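#' Basic geometry of a closed contour
#'
#' Area by the shoelace formula, perimeter as closed polyline arc
#' length, and length/width as the longer/shorter side of the
#' minimum-area oriented bounding rectangle (rotating calipers over the
#' convex hull).
#'
#' @param c a [vb_contour()] (simple polygon, >= 3 points).
#' @return list with `area` (px^2), `perimeter` (px), `length` (px),
#'   `width` (px), `length >= width`.
#' @export
contour_geometry <- function(c) {
  stopifnot(inherits(c, "vb_contour"))
  p <- unclass(c)
  area <- abs(polygon_area(p))
  if (area <= .Machine$double.eps) stop("degenerate contour: zero area")
  perim <- polygon_perimeter(p)

  hull <- p[grDevices::chull(p), , drop = FALSE]
  nh <- nrow(hull)
  best <- Inf; best_sides <- c(NA_real_, NA_real_)
  for (i in seq_len(nh)) {
    e <- hull[(i %% nh) + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    d <- e / len
    n <- c(-d[2], d[1])
    u <- hull %*% d
    v <- hull %*% n
    side_u <- diff(range(u))
    side_v <- diff(range(v))
    a <- side_u * side_v
    if (a < best) {
      best <- a
      best_sides <- c(side_u, side_v)
    }
  }
  list(area = area, perimeter = perim,
       length = max(best_sides), width = min(best_sides))
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B x y + C y^2 + D x + E y + F = 0` to the
#' contour points with the ellipse-specific constraint
#' `4AC - B^2 = 1` (numerically stable block decomposition of the
#' direct least-squares method), then converts to geometric parameters.
#' The residual is the RMS of approximate orthogonal point-to-ellipse
#' distances: the algebraic value at each point divided by the local
#' gradient norm of the conic (Sampson distance).
#'
#' @param c a [vb_contour()] or 2-column point matrix with >= 6 distinct
#'   points, not all collinear.
#' @return list with `centre` (x, y), `major_a`, `minor_b` (semi-axes,
#'   `major_a >= minor_b`), `angle` (radians, major-axis direction), and
#'   `residual` (px, RMS).
#' @export
fit_ellipse <- function(c) {
  p <- unclass(c)
  p <- unique(p)
  if (nrow(p) < 6L) stop("ellipse fit needs at least 6 distinct points")
  x <- p[, 1]; y <- p[, 2]
  mx <- mean(x); my <- mean(y)
  sx <- x - mx; sy <- y - my

  D1 <- cbind(sx^2, sx * sy, sy^2)
  D2 <- cbind(sx, sy, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("degenerate point configuration (collinear input?)")
  })
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)  # inv(C1) %*% M
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("no elliptical solution (degenerate input)")
  a1 <- V[, ok[1L]]
  coef <- c(a1, as.vector(Tm %*% a1))   # A B C D E F in centred frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]

  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  mu <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(-mu / eg$values)
  if (anyNA(ax) || any(!is.finite(ax))) stop("degenerate ellipse fit")
  major_i <- which.max(ax)
  angle <- atan2(eg$vectors[2, major_i], eg$vectors[1, major_i])
  if (angle < 0) angle <- angle + pi   # canonical [0, pi)

  # Sampson (gradient-weighted algebraic) residual on original points
  alg <- A * sx^2 + B * sx * sy + C * sy^2 + D * sx + E * sy + F
  gx <- 2 * A * sx + B * sy + D
  gy <- B * sx + 2 * C * sy + E
  gn <- sqrt(gx^2 + gy^2)
  gn[gn < 1e-12] <- 1e-12
  residual <- sqrt(mean((alg / gn)^2))

  list(centre = c(x0 + mx, y0 + my),
       major_a = max(ax), minor_b = min(ax),
       angle = angle, residual = residual)
}

#' Ellipse eccentricity from its semi-axes
#'
#' `sqrt(1 - (b/a)^2)`: 0 for a circle (`a = b`), 1 in the degenerate
#' parabolic limit (`b = 0`).
#'
#' @param major_a major semi-axis (> 0).
#' @param minor_b minor semi-axis, `0 <= minor_b <= major_a`.
#' @return eccentricity in \[0, 1\].
#' @export
eccentricity <- function(major_a, minor_b) {
  stopifnot(major_a > 0)
  if (minor_b < 0 || minor_b > major_a) {
    stop("minor_b must lie in [0, major_a]")
  }
  sqrt(1 - (minor_b / major_a)^2)
}

#' Five shape descriptors of a major vascular bundle contour
#'
#' * form factor `4 * pi * area / perimeter^2` (1 for a circle,
#'   smaller for any other shape);
#' * aspect ratio `length / width` of the minimum-area oriented
#'   bounding rectangle;
#' * rectangularity `length * width / perimeter` (px; this quotient is
#'   not dimensionless -- it is kept exactly in this form, and feature
#'   standardization in the classifier absorbs the scale);
#' * eccentricity of the least-squares fitted ellipse;
#' * RMS residual of that fit (px).
#'
#' @param c a [vb_contour()].
#' @return list with `form_factor`, `aspect_ratio`, `rectangularity`,
#'   `eccentricity`, `residual`.
#' @export
mjvb_features <- function(c) {
  g <- contour_geometry(c)
  e <- fit_ellipse(c)
  list(
    form_factor = 4 * pi * g$area / g$perimeter^2,
    aspect_ratio = g$length / g$width,
    rectangularity = g$length * g$width / g$perimeter,
    eccentricity = eccentricity(e$major_a, e$minor_b),
    residual = e$residual
  )
}
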