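# Phantom generators: geometry, ground truth, determinism.

test_that("annulus phantom carries constant analytic thickness", {
  ph <- make_annulus_phantom(40, 70, 720)
  expect_equal(ph$true_thickness(c(0, 500, 1e4)), rep(300, 3))
  expect_equal(ph$true_midline_radius, sqrt(40 * 70))
  expect_true(ph$contour_pair$closed)
})

test_that("degenerate annulus radii are rejected", {
  expect_error(make_annulus_phantom(50, 50, 360), class = "fcdmap_invalid_geometry")
  expect_error(make_annulus_phantom(70, 40, 360), class = "fcdmap_invalid_geometry")
})

test_that("gyral ribbon offsets reproduce the thickness profile", {
  cl <- cbind(seq(0, 300, by = 2), 50 + 10 * sin(seq(0, 300, by = 2) / 40))
  ph <- make_gyral_ribbon(cl, 20, pixel_size = 10)
  cp <- ph$contour_pair
  # perpendicular distance between the offset curves equals the profile
  gap <- sqrt(rowSums((cp$outer - cp$inner)^2))
  expect_true(all(abs(gap - 20) < 1))
  expect_equal(ph$true_thickness(c(0, 1000)), rep(200, 2))
})

test_that("implanted focus scales the true thickness exactly on its interval", {
  cl <- cbind(seq(0, 400, by = 2), rep(40, 201))
  focus <- list(s_start = 1500, s_end = 2500, multiplier = 0.5)
  ph <- make_gyral_ribbon(cl, 20, foci = list(focus), pixel_size = 10,
                          taper_um = 300)
  s_in <- seq(1500, 2500, by = 100)
  expect_equal(ph$true_thickness(s_in), rep(100, length(s_in)))
  s_out <- c(500, 1000, 3200, 3800)
  expect_equal(ph$true_thickness(s_out), rep(200, length(s_out)))
})

test_that("crest labels follow the analytic second derivative", {
  xs <- seq(0, 600, by = 2)
  cl <- cbind(xs, 60 + 12 * sin(2 * pi * xs / 200))
  ph <- make_gyral_ribbon(cl, 16, pixel_size = 10)
  # y-down coordinates: local minima of y bulge toward the outer side
  s_crest <- 150 * 10 # x = 150 px: sin = -1, minimum of y
  s_sulcus <- 50 * 10 # x = 50 px: sin = +1, maximum of y
  expect_equal(unname(ph$true_curvature_sign(s_crest)), "crest")
  expect_equal(unname(ph$true_curvature_sign(s_sulcus)), "sulcus")
})

test_that("self-intersecting offsets are rejected", {
  # tight hairpin with thickness larger than the bend radius
  th <- seq(0, pi, length.out = 80)
  cl <- cbind(50 + 8 * cos(th), 50 + 8 * sin(th))
  expect_error(make_gyral_ribbon(cl, 30, pixel_size = 10),
               class = "fcdmap_invalid_geometry")
})

test_that("Boolean field matches its analytic area fraction", {
  fracs <- vapply(1:5, function(s) {
    sim <- simulate_boolean_field(0.005, list(radius = 6), c(400, 400),
                                  noise_sd = 0, seed = s)
    mean(sim$image < 130)
  }, 1)
  target <- 1 - exp(-0.005 * pi * 36)
  # SE of the area fraction over a 400^2 window is well under 0.01
  expect_lt(abs(mean(fracs) - target), 0.015)
})

test_that("Boolean germ counts follow the Poisson mean over seeds", {
  lam <- 0.003; w <- c(300, 300); rmax <- 5
  counts <- vapply(1:20, function(s) {
    nrow(simulate_boolean_field(lam, list(radius = rmax), w,
                                seed = s)$truth$germs)
  }, 1)
  expected <- lam * (w[1] + 2 * rmax) * (w[2] + 2 * rmax)
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected))
})

test_that("empty-intensity Boolean process gives a blank field", {
  sim <- simulate_boolean_field(0, list(radius = 6), c(100, 100),
                                noise_sd = 0, seed = 1)
  expect_equal(nrow(sim$truth$germs), 0L)
  expect_true(all(sim$image == 200))
})

test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_boolean_field(0.004, list(radius = 5), c(200, 200),
                              noise_sd = 8, seed = 11)
  b <- simulate_boolean_field(0.004, list(radius = 5), c(200, 200),
                              noise_sd = 8, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$germs, b$truth$germs)
  m <- disc_mask(60, 60, 30, 30, 10)
  r1 <- make_rater_masks(m, 0.2, seed = 5)
  r2 <- make_rater_masks(m, 0.2, seed = 5)
  expect_identical(r1, r2)
  cf1 <- simulate_cell_field(20, radius = 5, window = c(150, 150), seed = 3)
  cf2 <- simulate_cell_field(20, radius = 5, window = c(150, 150), seed = 3)
  expect_identical(cf1$image, cf2$image)
})

test_that("rater masks have the prescribed disagreement", {
  m <- disc_mask(80, 80, 40, 40, 25)
  r0 <- make_rater_masks(m, 0, seed = 1)
  expect_identical(r0$mask_a, r0$mask_b)
  expect_identical(r0$mask_a, m > 0)
  # balanced base, flip 0.5: expected observed agreement 1/2
  base <- matrix(rep(c(TRUE, FALSE), 2000), 40)
  r5 <- make_rater_masks(base, 0.5, seed = 2)
  expect_lt(abs(mean(r5$mask_a == r5$mask_b) - 0.5), 0.03)
  expect_error(make_rater_masks(m, 1.5, seed = 1), class = "fcdmap_bad_argument")
})

test_that("contour CSV + sidecar round-trips through the I/O layer", {
  ph <- make_annulus_phantom(15, 25, 90, pixel_size = 12.5, slide_id = "rt")
  path <- file.path(tempdir(), "rt_contours.csv")
  write_contours(ph$contour_pair, path, y_mm = 4.5)
  cp <- read_contours(path)
  expect_equal(cp$outer, ph$contour_pair$outer, tolerance = 1e-8)
  expect_equal(cp$inner, ph$contour_pair$inner, tolerance = 1e-8)
  expect_equal(cp$pixel_size, 12.5)
  expect_equal(cp$slide_id, "rt")
  expect_true(cp$closed)
})
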