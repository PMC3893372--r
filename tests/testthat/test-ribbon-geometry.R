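# Rasterization, Laplace solve, field lines, midline sampling, curvature.

test_that("rasterized annulus area matches the analytic ring", {
  grid <- fix_annulus$grid
  n_ribbon <- sum(grid$labels > 0L)
  expect_lt(abs(n_ribbon - pi * (35^2 - 20^2)) / (pi * (35^2 - 20^2)), 0.03)
})

test_that("rasterized parallel band area matches the rectangle", {
  n_ribbon <- sum(fix_band$grid$labels > 0L)
  expect_lt(abs(n_ribbon - 20 * 200), 0.05 * 4000)
})

test_that("swapped contours are rejected as invalid geometry", {
  th <- seq(0, 2 * pi, length.out = 100)
  expect_error(
    contour_pair(outer = cbind(50 + 20 * cos(th), 50 + 20 * sin(th)),
                 inner = cbind(50 + 35 * cos(th), 50 + 35 * sin(th)),
                 pixel_size = 10),
    class = "fcdmap_invalid_geometry"
  )
})

test_that("solved annulus potential is log-harmonic", {
  grid <- fix_annulus$grid
  field <- fix_annulus$field
  idx <- which(grid$labels == 1L)
  rr <- ((idx - 1L) %% nrow(grid$labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(grid$labels)) + 1L
  xy <- fcdmap:::grid_to_px(grid, rr, cc)
  r <- sqrt((xy[, 1] - 50)^2 + (xy[, 2] - 50)^2)
  fit <- lm(field$phi[idx] ~ log(r))
  # small fixture (15 px wall): coarser relative discretization than the
  # benchmark annulus, hence the slightly wider band here
  expect_lt(max(abs(resid(fit))), 0.03)
})

test_that("solved band potential is linear across the width", {
  grid <- fix_band$grid
  field <- fix_band$field
  idx <- which(grid$labels >= 1L)
  y <- grid$y0 + (((idx - 1L) %% nrow(grid$labels)) + 1L - 1L) * grid$grid_spacing
  fit <- lm(field$phi[idx] ~ y)
  expect_lt(max(abs(resid(fit))), 0.01)
})

test_that("potential obeys the discrete maximum principle", {
  for (field in list(fix_annulus$field, fix_band$field)) {
    phi_grey <- field$phi[field$grid$labels == 1L]
    expect_true(all(phi_grey > -1 & phi_grey < 1))
    expect_lt(field$residual, field$tol)
  }
})

test_that("degenerate ribbon with no grey interior is reported", {
  th <- seq(0, 2 * pi, length.out = 200)
  expect_error(
    suppressWarnings(rasterize_ribbon(contour_pair(
      outer = cbind(30 + 10.2 * cos(th), 30 + 10.2 * sin(th)),
      inner = cbind(30 + 10.0 * cos(th), 30 + 10.0 * sin(th)),
      pixel_size = 10, validate = FALSE))),
    class = "fcdmap_empty_ribbon"
  )
})

test_that("field lines are radial in the annulus and span the band", {
  tl <- trace_field_line(fix_annulus$field, c(50 + fix_annulus$true_r, 50))
  expect_lt(abs(tl$length_um - 300) / 300, 0.02)
  tl2 <- trace_field_line(fix_band$field, c(100, 30))
  expect_lt(abs(tl2$length_um - 200) / 200, 0.01)
})

test_that("field lines do not cross", {
  starts <- cbind(50 + fix_annulus$true_r * cos(c(0.3, 0.45, 1.2)),
                  50 + fix_annulus$true_r * sin(c(0.3, 0.45, 1.2)))
  lines <- lapply(seq_len(nrow(starts)), function(i) {
    trace_field_line(fix_annulus$field, starts[i, ])$polyline
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_false(fcdmap:::polylines_cross(lines[[i]], lines[[j]]))
  }
})

test_that("flat potential raises a degenerate-gradient error", {
  field <- fix_band$field
  field$phi[] <- ifelse(is.na(field$phi), NA, 0)
  expect_error(trace_field_line(field, c(100, 30)),
               class = "fcdmap_degenerate_gradient")
})

test_that("midline thickness and radius match the annulus closed form", {
  prof <- fix_annulus$profile
  expect_true(all(abs(prof$t_um - 300) / 300 < 0.02))
  rad <- sqrt((prof$x_px - 50)^2 + (prof$y_px - 50)^2)
  expect_lt(max(abs(rad - fix_annulus$true_r)) / fix_annulus$true_r, 0.02)
  expect_true(all(diff(prof$arc_s_um) > 0))
})

test_that("thickness through the midline agrees with a single field line", {
  prof <- fix_annulus$profile
  i <- which.min(abs(prof$arc_s_um - median(prof$arc_s_um)))
  tl <- trace_field_line(fix_annulus$field, c(prof$x_px[i], prof$y_px[i]))
  expect_lt(abs(tl$length_um - prof$t_um[i]) / prof$t_um[i], 0.01)
})

test_that("halving the grid spacing changes annulus thickness by < 1%", {
  g2 <- rasterize_ribbon(fix_annulus$phantom$contour_pair, grid_spacing = 0.5)
  p2 <- midline_profile(solve_laplace(g2), sample_step = 200)
  expect_lt(abs(mean(p2$t_um) - mean(fix_annulus$profile$t_um)) /
              mean(fix_annulus$profile$t_um), 0.01)
})

test_that("degenerate midline raises a no-midline error", {
  field <- fix_band$field
  field$phi <- field$phi + 5 # shift: no zero level set
  expect_error(midline_profile(field), class = "fcdmap_no_midline")
})

test_that("curvature of a circular midline is +1/r toward the outer side", {
  # r = 50 px at 20 um/px -> r = 1 mm -> kappa = +1 /mm with outer outside
  prof <- fix_annulus$profile # r = 26.46 px at 20 um/px = 0.529 mm
  true_kappa <- 1 / (fix_annulus$true_r * 20 / 1000)
  expect_true(all(abs(prof$kappa_per_mm - true_kappa) / true_kappa < 0.05))
  expect_true(all(prof$kappa_per_mm > 0))
})

test_that("curvature is 0 for straight lines, analytic for sinusoid crests", {
  straight <- cbind(seq(0, 100, by = 1), rep(5, 101))
  k <- curvature(straight, window_um = 20, pixel_size = 1,
                 outward = cbind(rep(0, 101), rep(-1, 101)))
  expect_true(all(abs(k) < 1e-6))
  expect_error(curvature(straight[1:2, ]), class = "fcdmap_insufficient_curve")

  # y = A sin(x / L): |kappa| at a crest = A / L^2 (px units)
  A <- 10; L <- 20
  xs <- seq(0, 4 * pi * L, by = 0.5)
  sine <- cbind(xs, A * sin(xs / L))
  # outward = toward -y, so maxima of y(x) are sulci, minima are crests
  outward <- cbind(rep(0, length(xs)), rep(-1, length(xs)))
  k <- curvature(sine, window_um = 15 * 1000, pixel_size = 1000,
                 outward = outward)
  crest <- which.min(abs(xs - 3 * pi / 2 * L)) # sin = -1: bulge toward -y
  k_true <- A / L^2 # 1/px; pixel_size 1000 um makes 1 px = 1 mm
  expect_lt(abs(abs(k[crest]) - k_true) / k_true, 0.05)
  expect_gt(k[crest], 0) # convex toward outer = positive
})

test_that("gyral ribbon with a 0.5x focus halves the sampled thickness", {
  cl <- cbind(seq(0, 400, by = 2), rep(40, 201))
  focus <- list(s_start = 1600, s_end = 2600, multiplier = 0.5)
  ph <- make_gyral_ribbon(cl, 20, foci = list(focus), pixel_size = 10,
                          taper_um = 300)
  prof <- midline_profile(solve_laplace(rasterize_ribbon(ph$contour_pair)),
                          sample_step = 100, trim_um = 400)
  inside <- prof$arc_s_um > 1700 & prof$arc_s_um < 2500
  outside <- prof$arc_s_um < 1100 | prof$arc_s_um > 3100
  expect_true(all(abs(prof$t_um[inside] - 100) / 100 < 0.05))
  expect_true(all(abs(prof$t_um[outside] - 200) / 200 < 0.05))
})
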