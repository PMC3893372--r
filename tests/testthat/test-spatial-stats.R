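# Intrinsic densities, Boolean model inversion, granulometry, laminar stats.

test_that("densities of a single disk match the closed form", {
  m <- disc_mask(100, 100, 50, 50, 10)
  d <- measure_densities(m) # pixel_size 1 -> um = px
  expect_lt(abs(d$a_a - pi * 100 / 1e4) / (pi * 100 / 1e4), 0.05)
  expect_equal(d$chi_a, 1 / 1e4)
  expect_lt(abs(d$l_a - 2 * pi * 10 / 1e4) / (2 * pi * 10 / 1e4), 0.15)
})

test_that("degenerate masks measure sensibly", {
  full <- matrix(1L, 50, 50)
  d <- measure_densities(full)
  expect_equal(d$a_a, 1)
  expect_equal(d$l_a, 0)
  ring <- disc_mask(60, 60, 30, 30, 15)
  ring[stamp_disc_idx(30, 30, 7, 60, 60)] <- 0L
  expect_equal(euler_characteristic(ring), 0) # one component, one hole
  expect_error(measure_densities(matrix(1, 10, 10), edge_margin = 6),
               class = "fcdmap_window_too_small")
})

test_that("Euler characteristic counts components minus holes in both conventions", {
  m <- matrix(0L, 40, 80)
  m[stamp_disc_idx(20, 15, 6, 40, 80)] <- 1L
  m[stamp_disc_idx(20, 40, 6, 40, 80)] <- 1L
  m[stamp_disc_idx(20, 65, 6, 40, 80)] <- 1L
  expect_equal(euler_characteristic(m, 4), 3)
  expect_equal(euler_characteristic(m, 8), 3)
  expect_error(euler_characteristic(m, 6), class = "fcdmap_bad_argument")
})

test_that("Boolean fit approaches the sparse limit on disjoint grains", {
  m <- matrix(0L, 300, 300)
  centres <- expand.grid(row = seq(30, 270, by = 60), col = seq(30, 270, by = 60))
  for (i in seq_len(nrow(centres))) {
    m[stamp_disc_idx(centres$row[i], centres$col[i], 6, 300, 300)] <- 1L
  }
  fit <- fit_boolean(m)
  n_true <- nrow(centres)
  expect_lt(abs(fit$lambda_hat - n_true / 9e4) / (n_true / 9e4), 0.1)
  expect_lt(abs(fit$a_bar - 113) / 113, 0.1)
  expect_lt(abs(fit$u_bar - 2 * pi * 6) / (2 * pi * 6), 0.15)
})

test_that("Boolean estimates are invariant under 90-degree rotation", {
  sim <- simulate_boolean_field(0.004, list(radius = 5), c(300, 300),
                                noise_sd = 0, seed = 9)
  mask <- sim$image < 130
  rot <- t(mask)[ncol(mask):1, ] # 90-degree rotation
  f1 <- tidy(fit_boolean(mask))
  f2 <- tidy(fit_boolean(rot))
  expect_equal(f1$lambda_hat, f2$lambda_hat, tolerance = 1e-12)
  expect_equal(f1$u_bar, f2$u_bar, tolerance = 1e-12)
})

test_that("saturated and empty masks are rejected", {
  expect_error(fit_boolean(matrix(1, 20, 20)), class = "fcdmap_saturated_mask")
  expect_error(fit_boolean(matrix(0, 20, 20)), class = "fcdmap_empty_mask")
})

test_that("pattern spectrum is complete for arbitrary masks", {
  set.seed(10)
  m <- matrix(rbinom(2500, 1, 0.3), 50)
  sp <- granulometry(m, sizes = c(0, 1, 2, 4, 8))
  expect_equal(sum(sp$area_um2), sum(m))
  expect_true(all(sp$area_um2 >= 0))
  empty <- granulometry(matrix(0L, 30, 30), sizes = c(0, 2, 4))
  expect_true(all(empty$area_um2 == 0))
  expect_error(granulometry(m, sizes = c(0, 2, 2)),
               class = "fcdmap_invalid_sizes")
  expect_error(granulometry(m, sizes = c(1, 2)),
               class = "fcdmap_invalid_sizes")
})

test_that("openings are monotone non-increasing (sieving axiom)", {
  set.seed(11)
  m <- matrix(0L, 80, 80)
  for (i in 1:6) {
    m[stamp_disc_idx(runif(1, 10, 70), runif(1, 10, 70),
                     runif(1, 3, 9), 80, 80)] <- 1L
  }
  sizes <- c(0, 2, 4, 6, 8, 10)
  areas <- numeric(length(sizes))
  sp <- granulometry(m, sizes)
  # reconstruct cumulative areas from the spectrum: must be non-increasing
  cum <- sum(sp$area_um2) - cumsum(c(0, sp$area_um2[-nrow(sp)]))
  expect_true(all(diff(cum) <= 1e-9))
})

test_that("monodisperse disks concentrate the spectrum at their size", {
  m <- matrix(0L, 150, 150)
  centres <- list(c(25, 25), c(25, 75), c(25, 125), c(75, 25), c(75, 75))
  for (ct in centres) m[stamp_disc_idx(ct[1], ct[2], 5, 150, 150)] <- 1L
  total <- sum(m)
  sp <- granulometry(m, sizes = c(0, 2, 4, 6, 8))
  in_bin <- sp$area_um2[sp$size_lo == 4] # bin [4, 6) contains radius 5
  expect_gt(in_bin / total, 0.95)
})

test_that("a disk mixture gives a bimodal spectrum with proportional masses", {
  m <- matrix(0L, 220, 220)
  small <- list(c(30, 30), c(30, 90), c(30, 150), c(90, 30))
  big <- list(c(150, 80), c(150, 160), c(80, 170))
  for (ct in small) m[stamp_disc_idx(ct[1], ct[2], 5, 220, 220)] <- 1L
  for (ct in big) m[stamp_disc_idx(ct[1], ct[2], 10, 220, 220)] <- 1L
  sp <- granulometry(m, sizes = c(0, 2, 4, 6, 8, 10, 12))
  mass_small <- sum(sp$area_um2[sp$size_lo %in% c(4)])
  mass_big <- sum(sp$area_um2[sp$size_lo %in% c(8, 10)])
  area_small <- 4 * sum(disc_mask(30, 30, 15, 15, 5))
  area_big <- 3 * sum(disc_mask(40, 40, 20, 20, 10))
  expect_lt(abs(mass_small - area_small) / area_small, 0.05)
  expect_lt(abs(mass_big - area_big) / area_big, 0.05)
})

test_that("smaller grains shift the spectrum mode and fitted area downward", {
  sim6 <- simulate_boolean_field(0.003, list(radius = 6), c(400, 400),
                                 noise_sd = 0, seed = 12)
  sim5 <- simulate_boolean_field(0.003, list(radius = 5), c(400, 400),
                                 noise_sd = 0, seed = 12)
  m6 <- sim6$image < 130; m5 <- sim5$image < 130
  sizes <- seq(0, 12, by = 1)
  expect_lt(spectrum_mode(granulometry(m5, sizes)),
            spectrum_mode(granulometry(m6, sizes)))
  expect_lt(tidy(fit_boolean(m5))$a_bar, tidy(fit_boolean(m6))$a_bar)
})

test_that("per-lamina estimates agree with the global fit on homogeneous fields", {
  sim <- simulate_boolean_field(0.004, list(radius = 5), c(500, 500),
                                noise_sd = 0, seed = 13)
  mask <- sim$image < 130
  bands <- tibble::tibble(lamina = c("II", "III", "IV", "V", "VI"),
                          row_start = seq(1, 401, by = 100),
                          row_end = seq(100, 500, by = 100))
  res <- stats_by_lamina(mask, bands, which = "boolean")
  glob <- tidy(fit_boolean(mask))
  # each 100 x 500 band holds ~200 germs; lambda-hat carries ~8% relative
  # SE (Poisson counting plus Euler-density noise), so 3 SE is ~25%
  expect_true(all(abs(res$lambda_hat - glob$lambda_hat) / glob$lambda_hat < 0.25))
})

test_that("a band with doubled grain radius shows ~4x the fitted grain area", {
  m_top <- simulate_boolean_field(0.003, list(radius = 4), c(400, 200),
                                  noise_sd = 0, seed = 14)$image < 130
  m_bot <- simulate_boolean_field(0.0015, list(radius = 8), c(400, 200),
                                  noise_sd = 0, seed = 15)$image < 130
  mask <- rbind(m_top, m_bot)
  bands <- tibble::tibble(lamina = c("II", "III"),
                          row_start = c(1, 201), row_end = c(200, 400))
  res <- stats_by_lamina(mask, bands, which = "boolean")
  ratio <- res$a_bar[res$lamina == "III"] / res$a_bar[res$lamina == "II"]
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("single-band laminar analysis equals whole-mask analysis", {
  sim <- simulate_boolean_field(0.004, list(radius = 5), c(200, 200),
                                noise_sd = 0, seed = 16)
  mask <- sim$image < 130
  bands <- tibble::tibble(lamina = "II", row_start = 1, row_end = 200)
  res <- stats_by_lamina(mask, bands, which = "boolean")
  glob <- tidy(fit_boolean(mask))
  expect_equal(res$lambda_hat, glob$lambda_hat)
  expect_equal(res$a_bar, glob$a_bar)
  # out-of-range band skipped with a warning
  bad <- tibble::tibble(lamina = "VII", row_start = 150, row_end = 300)
  expect_warning(res2 <- stats_by_lamina(mask, bad, which = "boolean"),
                 "skipped")
  expect_equal(nrow(res2), 0L)
})

test_that("spectra average bin-wise across multiple masks", {
  m1 <- disc_mask(80, 80, 40, 40, 5)
  m2 <- disc_mask(80, 80, 40, 40, 5)
  m2[stamp_disc_idx(20, 20, 5, 80, 80)] <- 1L
  bands <- tibble::tibble(lamina = "III", row_start = 1, row_end = 80)
  res <- stats_by_lamina(list(m1, m2), bands, which = "granulometry",
                         sizes = c(0, 3, 6, 9))
  single1 <- granulometry(m1, c(0, 3, 6, 9))
  single2 <- granulometry(m2, c(0, 3, 6, 9))
  expect_equal(res$area_um2[res$size_lo == 3],
               (single1$area_um2[single1$size_lo == 3] +
                  single2$area_um2[single2$size_lo == 3]) / 2)
})
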