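test_that("constrained enclosing circle matches forced-symmetry cases", {
  bl <- baseline_through(c(0, 0), c(1, 0))
  # symmetric 3-point contour: centre at the origin, radius 1
  c1 <- fit_occipital_circle(bl, rbind(c(-1, 0), c(0, 1), c(1, 0)))
  expect_equal(unname(c1$center), c(0, 0), tolerance = 1e-8)
  expect_equal(c1$radius, 1, tolerance = 1e-8)
  expect_equal(c1$f_diameter, 2, tolerance = 1e-8)
  # two points at height 1: centre midway, radius sqrt(5)
  c2 <- fit_occipital_circle(bl, rbind(c(0, 1), c(4, 1)))
  expect_equal(unname(c2$center), c(2, 0), tolerance = 1e-6)
  expect_equal(c2$radius, sqrt(5), tolerance = 1e-9)
})

test_that("circle fit is invariant under rigid motion", {
  set.seed(1)
  for (i in 1:10) {
    contour <- random_contour()
    bl <- baseline_through(c(0, 0), c(1, 0))
    r0 <- fit_occipital_circle(bl, contour)$radius
    theta <- runif(1, 0, 2 * pi); shift <- runif(2, -50, 50)
    blr <- baseline_through(rigid(matrix(c(0, 0), 1), theta, shift)[1, ],
                            rigid(matrix(c(1, 0), 1), theta, shift)[1, ])
    r1 <- fit_occipital_circle(blr, rigid(contour, theta, shift))$radius
    expect_equal(r1, r0, tolerance = 1e-9)
  }
})

test_that("every fit encloses all vertices with one touching the boundary", {
  set.seed(2)
  for (i in 1:20) {
    contour <- random_contour(sample(3:12, 1))
    bl <- baseline_through(c(0, 0), c(1, 0))
    fit <- fit_occipital_circle(bl, contour)
    d <- sqrt((contour[, 1] - fit$center[1])^2 + (contour[, 2] - fit$center[2])^2)
    expect_true(all(d <= fit$radius + 1e-9))
    expect_equal(max(d), fit$radius, tolerance = 1e-9)
    # centre stays on the baseline
    expect_lt(abs(fit$center[2]), 1e-9)
  }
})

test_that("degenerate circle inputs raise errors", {
  expect_error(baseline_through(c(1, 1), c(1, 1)), "degenerate")
  bl <- baseline_through(c(0, 0), c(1, 0))
  expect_error(fit_occipital_circle(bl, matrix(numeric(0), 0, 2)), "vertices")
})

test_that("point E solves the segment-circle quadratic with the dorsal tie rule", {
  bl <- baseline_through(c(0, 0), c(1, 0))
  circ <- fit_occipital_circle(bl, rbind(c(-1, 0), c(0, 1), c(1, 0))) # unit circle
  expect_equal(unname(intersect_circle_contour(circ, rbind(c(0, -2), c(0, 2)))),
               c(0, 1), tolerance = 1e-8)
  # chord at y = 0.5: two roots, the rostral (larger x) one wins the tie on y
  E <- intersect_circle_contour(circ, rbind(c(-2, 0.5), c(2, 0.5)))
  expect_equal(unname(E), c(sqrt(0.75), 0.5), tolerance = 1e-9)
  # contour entirely outside: classed error carrying the miss distance
  err <- tryCatch(intersect_circle_contour(circ, rbind(c(5, 5), c(6, 6))),
                  cmmorph_no_E = function(e) e)
  expect_s3_class(err, "cmmorph_no_E")
  expect_gt(err$min_distance, 0)
})

test_that("point I sits on both the circle and the baseline", {
  bl <- baseline_through(c(0, 0), c(1, 0))
  circ <- structure(list(center = c(10, 0), radius = 3), class = "occipital_circle")
  expect_equal(unname(derive_point_I(bl, circ)), c(7, 0))
  blv <- baseline_through(c(0, 0), c(0, 1))
  circv <- structure(list(center = c(0, 5), radius = 2), class = "occipital_circle")
  expect_equal(unname(derive_point_I(blv, circv)), c(0, 3))
  expect_equal(unname(derive_point_I(blv, circv, which = "far")), c(0, 7))
  set.seed(3)
  for (i in 1:10) {
    contour <- random_contour()
    bl <- baseline_through(runif(2, -5, 5), runif(2, 10, 20))
    fit <- fit_occipital_circle(bl, contour)
    I <- derive_point_I(bl, fit)
    expect_lt(abs(sqrt(sum((I - fit$center)^2)) - fit$radius), 1e-9)
    n <- c(-bl$direction[2], bl$direction[1])
    expect_lt(abs(sum((I - bl$origin) * n)), 1e-9)
  }
})

test_that("angles follow the arccos contract", {
  expect_equal(angle_at(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(angle_at(c(0, 0), c(1, 0), c(-1, 0)), 180)
  expect_equal(angle_at(c(0, 0), c(1, 0), c(1, 1)), 45)
  expect_error(angle_at(c(0, 0), c(0, 0), c(1, 1)), "zero-length")
})

test_that("the framework recovers forward-constructed targets", {
  t <- geometry_template(f_diameter = 40, angle2 = 70, angle5 = 46)
  fr <- compute_framework(gen_landmark_geometry(t))
  expect_equal(fr$f_diameter, 40, tolerance = 1e-6)
  expect_equal(unname(fr$angles["angle2"]), 70, tolerance = 1e-6)
  expect_equal(unname(fr$angles["angle5"]), 46, tolerance = 1e-6)
  expect_false(anyNA(fr$lines))
  expect_false(anyNA(fr$angles))
})

test_that("variables depending on an absent landmark are missing, not errors", {
  lm <- gen_landmark_geometry(geometry_template())
  lm$points$G <- NULL
  fr <- compute_framework(lm)
  expect_true(is.na(fr$lines["fg"]))
  expect_true(is.na(fr$angles["angle4"]))
  expect_true(is.na(fr$angles["angle5"]))
  expect_false(anyNA(fr$lines[c("ab", "ac", "ad", "ae", "ah", "ai", "bc", "bd")]))
  expect_false(anyNA(fr$angles[c("angle1", "angle2", "angle3")]))
})

test_that("scaling doubles every line and leaves every angle unchanged", {
  lm <- gen_landmark_geometry(geometry_template(jitter_sd = 0.3, seed = 5))
  fr1 <- compute_framework(lm)
  lm2 <- lm
  lm2$points <- lapply(lm$points, function(p) 2 * p)
  lm2$occipital_dorsum <- 2 * lm$occipital_dorsum
  lm2$cerebellum_dorsum <- 2 * lm$cerebellum_dorsum
  fr2 <- compute_framework(lm2)
  expect_equal(fr2$f_diameter, 2 * fr1$f_diameter, tolerance = 1e-9)
  expect_equal(fr2$lines, 2 * fr1$lines, tolerance = 1e-9)
  expect_equal(fr2$angles, fr1$angles, tolerance = 1e-9)
})
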