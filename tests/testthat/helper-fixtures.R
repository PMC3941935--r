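# shared fixtures and independent oracles

# n points exactly on a circle / ellipse
make_circle <- function(r = 50, centre = c(0, 0), n = 512) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  vb_contour(cbind(centre[1] + r * cos(t), centre[2] + r * sin(t)))
}

make_ellipse <- function(a, b, centre = c(0, 0), angle = 0, n = 256) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  ex <- a * cos(t); ey <- b * sin(t)
  vb_contour(cbind(centre[1] + ex * cos(angle) - ey * sin(angle),
                   centre[2] + ex * sin(angle) + ey * cos(angle)))
}

# brute-force closed-tour minimum by full permutation enumeration
# (independent oracle for the Held-Karp implementation)
brute_force_tour <- function(points) {
  n <- nrow(points)
  if (n < 2) return(0)
  D <- as.matrix(dist(points))
  if (n == 2) return(2 * D[1, 2])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  for (p in perms(2:n)) {
    tour <- c(1, p)
    len <- sum(D[cbind(tour, c(tour[-1], 1))])
    if (len < best) best <- len
  }
  best
}

# random rectilinear hole-free blob: union of overlapping axis-aligned
# rectangles around the centre of an h x w canvas
random_blob_mask <- function(h = 24, w = 24, n_rect = 3) {
  m <- matrix(0L, h, w)
  r0 <- sample(5:(h - 10), 1); c0 <- sample(5:(w - 10), 1)
  for (k in seq_len(n_rect)) {
    dh <- sample(2:6, 1); dw <- sample(2:6, 1)
    rr <- min(max(1, r0 + sample(-2:2, 1)), h - dh)
    cc <- min(max(1, c0 + sample(-2:2, 1)), w - dw)
    m[rr:(rr + dh), cc:(cc + dw)] <- 1L
  }
  binary_mask(m)
}

# simple two-rectangle scene with given oval centres
make_scene <- function(centres, p1 = c(100, 250), p2 = c(700, 250),
                       label = NA_character_) {
  ovals <- lapply(seq_len(nrow(centres)), function(i) {
    oval_annotation(centres[i, 1], centres[i, 2], 5, 4)
  })
  suppressWarnings(scene_annotation(
    list(rect_annotation(p1[1], p1[2], 80, 120),
         rect_annotation(p2[1], p2[2], 80, 120)),
    ovals, label = label, scene_id = "fixture"))
}

# well-separated two-class Gaussian toy set for classifier tests
make_toy_classes <- function(n_per = 20, p = 9, sep = 6, seed = 99) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, labels = rep(c("a", "b"), each = n_per))
}
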