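test_that("baseline is the segment between the rectangle centres", {
  b <- baseline_from_rects(rect_annotation(0, 0, 10, 10),
                           rect_annotation(3, 4, 10, 10))
  expect_equal(b$length, 5)
  expect_equal(baseline_from_rects(rect_annotation(0, 0, 1, 1),
                                   rect_annotation(100, 0, 1, 1))$length,
               100)
  expect_error(baseline_from_rects(rect_annotation(5, 5, 2, 2),
                                   rect_annotation(5, 5, 3, 3)),
               "degenerate")
})

test_that("mnvb_ratio sums unsigned perpendicular distances", {
  b <- baseline_from_rects(rect_annotation(0, 0, 1, 1),
                           rect_annotation(100, 0, 1, 1))
  expect_equal(mnvb_ratio(rbind(c(10, 5), c(90, -15)), b), 0.2)
  expect_equal(mnvb_ratio(rbind(c(20, 0), c(80, 0)), b), 0)
  expect_equal(mnvb_ratio(matrix(numeric(0), 0, 2), b), 0)
  # mirror symmetry across the baseline (absolute value)
  set.seed(7)
  pts <- cbind(runif(6, 0, 100), runif(6, -30, 30))
  mirrored <- cbind(pts[, 1], -pts[, 2])
  expect_equal(mnvb_ratio(pts, b), mnvb_ratio(mirrored, b))
})

test_that("mnvb_ratio2 sums distances to the baseline midpoint", {
  b <- baseline_from_rects(rect_annotation(0, 0, 1, 1),
                           rect_annotation(100, 0, 1, 1))
  expect_equal(mnvb_ratio2(rbind(c(50, 10)), b), 0.1)
  expect_equal(mnvb_ratio2(rbind(c(50, 0)), b), 0)
  expect_equal(mnvb_ratio2(rbind(c(30, 0), c(70, 0)), b), 0.4)
})

test_that("salesman_ratio divides the optimal tour by baseline length", {
  b <- baseline_from_rects(rect_annotation(0, 0, 1, 1),
                           rect_annotation(2, 0, 1, 1))
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(salesman_ratio(sq, b), 2)
  expect_equal(salesman_ratio(rbind(c(5, 5)), b), 0)
})

test_that("minor-bundle features are rigid-motion and scale invariant", {
  set.seed(13)
  centres <- cbind(runif(8, 120, 680), 250 + rnorm(8, 0, 20))
  scene <- make_scene(centres)
  f0 <- mnvb_features(scene, time_budget = 1)
  expect_equal(f0$number, 8)
  for (k in 1:3) {
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.5, 3)
    shift <- runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tf <- function(p) s * (p %*% R) + rep(shift, each = nrow(p))
    centres2 <- tf(centres)
    p1 <- drop(tf(matrix(c(100, 250), 1))); p2 <- drop(tf(matrix(c(700, 250), 1)))
    f1 <- mnvb_features(make_scene(centres2, p1, p2), time_budget = 1)
    for (nm in c("ratio", "ratio2", "salesman_ratio")) {
      expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-9)
    }
    expect_equal(f1$number, f0$number)
  }
})

test_that("scene_annotation validates structure and warns on outliers", {
  expect_error(make_scene(matrix(numeric(0), 0, 2))$x, NA)
  expect_error(
    scene_annotation(list(rect_annotation(0, 0, 1, 1))),
    "exactly two")
  expect_warning(
    scene_annotation(list(rect_annotation(0, 0, 1, 1),
                          rect_annotation(100, 0, 1, 1)),
                     list(oval_annotation(150, 0, 3, 3))),
    "outside")
})

test_that("contour_geometry matches closed forms", {
  sq <- vb_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  g <- contour_geometry(sq)
  expect_equal(g$area, 1); expect_equal(g$perimeter, 4)
  expect_equal(g$length, 1); expect_equal(g$width, 1)

  circ <- make_circle(r = 10, n = 512)
  gc <- contour_geometry(circ)
  expect_lt(abs(gc$area - 100 * pi) / (100 * pi), 0.001)
  expect_lt(abs(gc$perimeter - 20 * pi) / (20 * pi), 0.001)

  # rotated rectangle: oriented bounding box recovers the sides
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rect <- rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2)) %*% t(R)
  gr <- contour_geometry(vb_contour(rect))
  expect_equal(gr$length, 4, tolerance = 1e-9)
  expect_equal(gr$width, 2, tolerance = 1e-9)

  expect_error(contour_geometry(vb_contour(rbind(c(0, 0), c(1, 1),
                                                 c(2, 2)))),
               "zero area")
})

test_that("fit_ellipse recovers noise-free ellipses and circles", {
  e <- fit_ellipse(make_ellipse(5, 3, centre = c(2, -1), angle = 0.7))
  expect_equal(e$major_a, 5, tolerance = 1e-6)
  expect_equal(e$minor_b, 3, tolerance = 1e-6)
  expect_equal(e$centre, c(2, -1), tolerance = 1e-6)
  expect_lt(e$residual, 1e-6)

  c7 <- fit_ellipse(make_circle(r = 7, n = 64))
  expect_equal(c7$major_a, 7, tolerance = 1e-6)
  expect_equal(c7$minor_b, 7, tolerance = 1e-6)

  collinear <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(fit_ellipse(collinear))
  expect_error(fit_ellipse(make_circle(n = 5)), "at least 6")
})

test_that("ellipse residual tracks injected boundary noise", {
  set.seed(17)
  for (sigma in c(0.5, 1)) {
    t <- 2 * pi * (0:399) / 400
    r_noise <- rnorm(400, 0, sigma)
    pts <- cbind((50 + r_noise) * cos(t), (35 + r_noise) * sin(t))
    e <- fit_ellipse(vb_contour(pts))
    expect_lt(abs(e$residual - sigma) / sigma, 0.2)
  }
})

test_that("eccentricity follows sqrt(1 - (b/a)^2)", {
  expect_equal(eccentricity(5, 3), 0.8)
  expect_equal(eccentricity(5, 5), 0)
  expect_equal(eccentricity(5, 0), 1)
  expect_error(eccentricity(3, 5), "minor_b")
  # strictly decreasing in b/a
  ratios <- seq(0.05, 1, by = 0.05)
  vals <- vapply(ratios, function(r) eccentricity(1, r), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("mjvb_features computes the printed descriptor formulas", {
  # sample polygon edges densely so the ellipse fit has enough support;
  # area/perimeter/box geometry are unchanged by densification
  densify <- function(p, per_edge = 25) {
    n <- nrow(p)
    vb_contour(do.call(rbind, lapply(seq_len(n), function(i) {
      a <- p[i, ]; b <- p[(i %% n) + 1, ]
      t <- (0:(per_edge - 1)) / per_edge
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    })))
  }
  s <- 3
  sq <- densify(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)))
  f <- mjvb_features(sq)
  expect_equal(f$form_factor, pi / 4, tolerance = 1e-12)
  expect_equal(f$aspect_ratio, 1)
  expect_equal(f$rectangularity, s / 4)

  fr <- mjvb_features(densify(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))))
  expect_equal(fr$aspect_ratio, 2)
  expect_equal(fr$rectangularity, 8 / 12)

  circ <- mjvb_features(make_circle(r = 30, n = 512))
  expect_gte(circ$form_factor, 0.999)
  expect_lt(circ$eccentricity, 0.01)
})

test_that("form factor obeys the isoperimetric inequality", {
  set.seed(19)
  for (k in 1:20) {
    t <- sort(runif(60, 0, 2 * pi))
    r <- 30 * (1 + runif(60, -0.4, 0.4))
    shape <- vb_contour(cbind(r * cos(t), r * sin(t)))
    g <- contour_geometry(shape)
    expect_lte(4 * pi * g$area / g$perimeter^2, 1 + 1e-3)
  }
})

test_that("assemble_feature_vector averages or passes through", {
  mn <- list(number = 5, ratio = 0.1, ratio2 = 0.2, salesman_ratio = 1.5)
  mj1 <- list(form_factor = 0.6, aspect_ratio = 2, rectangularity = 5,
              eccentricity = 0.8, residual = 0.3)
  mj2 <- list(form_factor = 0.8, aspect_ratio = 4, rectangularity = 7,
              eccentricity = 0.6, residual = 0.5)
  fv <- assemble_feature_vector(mn, list(mj1, mj2), label = "x")
  expect_equal(fv$form_factor, 0.7)
  expect_equal(fv$aspect_ratio, 3)
  expect_equal(names(fv), c(feature_names(), "label"))

  single <- assemble_feature_vector(mn, list(mj1))
  expect_equal(single$residual, 0.3)
  same <- assemble_feature_vector(mn, list(mj1, mj1))
  expect_equal(same$eccentricity, mj1$eccentricity)
  first <- assemble_feature_vector(mn, list(mj1, mj2), combine = "first")
  expect_equal(first$form_factor, 0.6)
  expect_error(assemble_feature_vector(mn, list()), "at least one")
})
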