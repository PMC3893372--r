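# Medcouple, adjusted fences, region flagging, cohort summaries.

test_that("medcouple is 0 on symmetric samples and matches the brute-force kernel", {
  expect_equal(medcouple(1:5), 0)
  expect_equal(medcouple(c(-3, -1, 0, 1, 3)), 0)
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                rlnorm(n),
                round(runif(n, 0, 5))) # discrete: exercises ties
    x <- x + seq_len(n) * 1e-9 # guard against fully constant draws
    expect_equal(medcouple(x), oracle_medcouple(x), tolerance = 1e-12)
  }
})

test_that("medcouple is antisymmetric and bounded", {
  set.seed(7)
  for (i in 1:10) {
    x <- rlnorm(31)
    mc <- medcouple(x)
    expect_true(mc >= -1 && mc <= 1)
    expect_equal(medcouple(-x), -mc, tolerance = 1e-12)
  }
})

test_that("medcouple rejects degenerate samples", {
  expect_error(medcouple(c(2, 2, 2, 2)), class = "fcdmap_undefined_medcouple")
  expect_error(medcouple(c(1, 2)), class = "fcdmap_insufficient_sample")
})

test_that("fences reduce to Tukey's at MC = 0", {
  # symmetric sample with q1 = 2, q3 = 8 (type-7 quartiles)
  x <- c(1, 2, 5, 8, 9)
  x <- rep(x, 4) # n >= 8 floor
  f <- adjusted_fences(x)
  expect_equal(f$medcouple, 0)
  expect_equal(f$lower_fence, 2 - 1.5 * 6)
  expect_equal(f$upper_fence, 8 + 1.5 * 6)
  ft <- adjusted_fences(x, variant = "tukey")
  expect_equal(ft$lower_fence, f$lower_fence)
})

test_that("right skew pulls the lower fence in and pushes the upper out", {
  set.seed(1)
  x <- rlnorm(200, 0, 0.8)
  f <- adjusted_fences(x)
  expect_gt(f$medcouple, 0)
  tukey <- adjusted_fences(x, variant = "tukey")
  expect_gt(f$lower_fence, tukey$lower_fence)
  expect_gt(f$upper_fence, tukey$upper_fence)
})

test_that("adjusted fences flag few points of a lognormal sample", {
  set.seed(2)
  x <- rlnorm(10000, 0, 0.5)
  f <- adjusted_fences(x)
  frac <- mean(x < f$lower_fence | x > f$upper_fence)
  expect_lt(frac, 0.02)
})

test_that("fences are shift and scale equivariant", {
  set.seed(3)
  x <- rlnorm(150)
  f <- adjusted_fences(x)
  fs <- adjusted_fences(x + 10)
  expect_equal(fs$lower_fence, f$lower_fence + 10, tolerance = 1e-9)
  expect_equal(fs$upper_fence, f$upper_fence + 10, tolerance = 1e-9)
  fm <- adjusted_fences(x * 3)
  expect_equal(fm$lower_fence, f$lower_fence * 3, tolerance = 1e-9)
  expect_equal(fm$upper_fence, f$upper_fence * 3, tolerance = 1e-9)
  expect_error(adjusted_fences(rnorm(5)), class = "fcdmap_insufficient_sample")
})

make_profile <- function(t, slide = "s", step = 100) {
  structure(
    tibble::tibble(slide_id = slide, piece = 1L,
                   sample = seq_along(t),
                   x_px = seq_along(t), y_px = 0,
                   arc_s_um = (seq_along(t) - 1) * step,
                   t_um = t, kappa_per_mm = 0),
    class = c("midline_profile", class(tibble::tibble()))
  )
}

test_that("identical case and control flag nothing", {
  t <- 2500 + 100 * sin(seq(0, 20, by = 0.1))
  f <- adjusted_fences(t)
  expect_equal(nrow(flag_thin_regions(make_profile(t), f)), 0L)
})

test_that("a uniformly thin case flags one region spanning the midline", {
  t_ctrl <- rnorm(200, 2500, 50)
  f <- adjusted_fences(t_ctrl)
  prof <- make_profile(rep(1000, 200))
  reg <- flag_thin_regions(prof, f)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_samples, 200L)
  expect_lt(reg$s_start, 0 + 1e-9)
  expect_gt(reg$s_end, 199 * 100 - 1e-9)
})

test_that("flagged regions are invariant to sampling direction", {
  set.seed(4)
  t <- 2500 + rnorm(120, 0, 30)
  t[40:55] <- 1500
  f <- adjusted_fences(t[-(40:55)])
  prof <- make_profile(t)
  rev_prof <- prof[rev(seq_len(nrow(prof))), ]
  r1 <- flag_thin_regions(prof, f, min_len_um = 500)
  r2 <- flag_thin_regions(rev_prof, f, min_len_um = 500)
  expect_equal(r1$s_start, r2$s_start)
  expect_equal(r1$s_end, r2$s_end)
  expect_equal(r1$mean_t, r2$mean_t)
})

test_that("short runs below fence are discarded by min_len", {
  t <- rep(2500, 100); t[50] <- 1000
  f <- adjusted_fences(rnorm(100, 2500, 40))
  expect_equal(nrow(flag_thin_regions(make_profile(t), f, min_len_um = 500)), 0L)
})

test_that("an implanted focus is recovered from a phantom pair", {
  res <- focus_recovery_experiment(1)
  expect_equal(res$n_regions, 1L)
  expect_gte(res$jaccard, 0.8)
})

test_that("mean thickness per slide is the arithmetic mean", {
  profs <- dplyr::bind_rows(make_profile(c(100, 200, 300), "a"),
                            make_profile(c(50, 150), "b"))
  mt <- mean_thickness_by_slide(profs)
  expect_equal(mt$mean_t[mt$slide_id == "a"], 200)
  expect_equal(mt$mean_t[mt$slide_id == "b"], 100)
  # constant-thickness annulus phantom: 300 um within 2%
  mt2 <- mean_thickness_by_slide(fix_annulus$profile)
  expect_lt(abs(mt2$mean_t - 300) / 300, 0.02)
})

test_that("identical cohorts give zero delta-t in every populated bin", {
  set.seed(5)
  base <- tibble::tibble(
    y_mm = runif(500, -100, 70),
    kappa_per_mm = runif(500, -1, 1),
    t_um = rnorm(500, 2500, 100)
  )
  samples <- dplyr::bind_rows(
    dplyr::mutate(base, group = "case"),
    dplyr::mutate(base, group = "control")
  )
  dm <- position_curvature_map(samples, n_min = 1)
  expect_true(all(abs(dm$delta_t[!is.na(dm$delta_t)]) < 1e-9))
})

test_that("crest-only thinning shows up only in positive-curvature bins", {
  set.seed(6)
  n <- 3000
  base <- tibble::tibble(
    y_mm = runif(n, -100, 70),
    kappa_per_mm = runif(n, -1, 1),
    t_um = 2500
  )
  case <- dplyr::mutate(base,
                        t_um = ifelse(.data$kappa_per_mm > 0.2,
                                      .data$t_um - 400, .data$t_um),
                        group = "case")
  ctrl <- dplyr::mutate(base, group = "control")
  dm <- position_curvature_map(dplyr::bind_rows(case, ctrl), n_min = 5)
  pos_bins <- dm$kappa_mid >= 0.2 & !is.na(dm$delta_t)
  other <- dm$kappa_mid < 0.2 & !is.na(dm$delta_t)
  expect_true(all(dm$delta_t[pos_bins] < -100))
  expect_true(all(abs(dm$delta_t[other]) < 1e-9))
})

test_that("underpopulated bins are masked with their counts reported", {
  samples <- tibble::tibble(
    group = c("case", "control"),
    y_mm = c(5, 5), kappa_per_mm = c(0, 0), t_um = c(2400, 2500)
  )
  dm <- position_curvature_map(samples, n_min = 10)
  expect_true(all(is.na(dm$delta_t)))
  expect_equal(dm$n_case, 1L)
})

test_that("null phantom cohorts flag almost nothing", {
  res <- dplyr::bind_rows(lapply(1:3, null_flag_fraction))
  expect_true(all(res$flagged_fraction < 0.05))
})
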