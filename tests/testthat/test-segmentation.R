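# GGMRF relaxation, watershed, refinement, composed segmentation.

test_that("GGMRF leaves a constant image unchanged and reduces noise variance", {
  const <- matrix(120, 30, 30)
  expect_equal(as.numeric(ggmrf_relax(const)), rep(120, 900))
  set.seed(1)
  noisy <- matrix(150, 50, 50) + matrix(rnorm(2500, 0, 20), 50)
  sm <- ggmrf_relax(noisy)
  expect_lt(var(as.vector(sm)), var(as.vector(noisy)))
  expect_gte(min(sm), min(noisy))
  expect_lte(max(sm), max(noisy))
})

test_that("small p preserves step edges strictly better than p = 2", {
  img <- matrix(100, 40, 40); img[, 21:40] <- 200
  set.seed(2)
  noisy <- img + matrix(rnorm(1600, 0, 15), 40)
  grad_max <- function(m) max(abs(m[, -1] - m[, -ncol(m)]))
  s_edge <- ggmrf_relax(noisy, p = 1.1)
  s_quad <- ggmrf_relax(noisy, p = 2)
  expect_gt(grad_max(s_edge), grad_max(s_quad))
})

test_that("GGMRF validates its shape parameter", {
  expect_error(ggmrf_relax(matrix(1:4, 2), p = 1), class = "fcdmap_bad_argument")
  expect_error(ggmrf_relax(matrix(1:4, 2), p = 2.5), class = "fcdmap_bad_argument")
})

test_that("watershed finds two disjoint dark disks", {
  img <- matrix(200, 80, 80)
  img[stamp_disc_idx(25, 25, 8, 80, 80)] <- 60
  img[stamp_disc_idx(55, 55, 8, 80, 80)] <- 60
  labs <- watershed_initial(img)
  expect_equal(max(labs), 2L)
  for (ctr in list(c(25, 25), c(55, 55))) {
    truth <- matrix(FALSE, 80, 80)
    truth[stamp_disc_idx(ctr[1], ctr[2], 8, 80, 80)] <- TRUE
    lab_here <- labs[ctr[1], ctr[2]]
    expect_gt(sum(labs == lab_here & truth) / sum(truth), 0.9)
  }
})

test_that("overlapping disks split at the saddle between their minima", {
  img <- matrix(200, 60, 90)
  # intensity wells: two smooth minima with a saddle between
  for (i in 1:60) for (j in 1:90) {
    d1 <- sqrt((i - 30)^2 + (j - 32)^2)
    d2 <- sqrt((i - 30)^2 + (j - 58)^2)
    img[i, j] <- 200 - 140 * max(exp(-(d1 / 10)^2), exp(-(d2 / 10)^2))
  }
  labs <- watershed_initial(img, h_min = 5, blur_sigma = 1)
  expect_equal(max(labs), 2L)
  expect_true(labs[30, 32] != labs[30, 58])
  # the split line falls near the saddle column
  boundary_cols <- which(apply(labs[25:35, ], 2, function(v) length(unique(v[v > 0])) > 1))
  expect_true(all(abs(boundary_cols - 45) <= 4))
})

test_that("a blank image yields zero labels with a warning", {
  expect_warning(labs <- watershed_initial(matrix(200, 40, 40)), "markers")
  expect_equal(max(labs), 0L)
})

test_that("refinement recovers a full disk from an eroded initial region", {
  img <- matrix(200, 60, 60)
  truth_idx <- stamp_disc_idx(30, 30, 10, 60, 60)
  img[truth_idx] <- 50
  init_idx <- stamp_disc_idx(30, 30, 6, 60, 60)
  ref <- refine_object(img, init_idx)
  expect_true(attr(ref, "refined"))
  expect_true(attr(ref, "threshold") > 50 && attr(ref, "threshold") < 200)
  dice <- 2 * length(intersect(ref, truth_idx)) /
    (length(ref) + length(truth_idx))
  expect_gte(dice, 0.95)
})

test_that("refinement is idempotent and degrades gracefully", {
  set.seed(3)
  img <- matrix(200, 60, 60) + matrix(rnorm(3600, 0, 5), 60)
  truth_idx <- stamp_disc_idx(30, 30, 10, 60, 60)
  img[truth_idx] <- img[truth_idx] - 140
  r1 <- refine_object(img, stamp_disc_idx(30, 30, 6, 60, 60))
  r2 <- refine_object(img, as.integer(r1))
  changed <- length(setdiff(union(r1, r2), intersect(r1, r2)))
  expect_lte(changed / length(r1), 0.01)
  # uniform window: keep initial region with a warning
  flat <- matrix(100, 30, 30)
  expect_warning(rf <- refine_object(flat, stamp_disc_idx(15, 15, 4, 30, 30)),
                 "initial region")
  expect_false(attr(rf, "refined"))
})

test_that("segmentation recovers the simulated cell count deterministically", {
  sim <- simulate_cell_field(15, radius = 6, window = c(160, 160),
                             noise_sd = 10, seed = 4)
  labs1 <- segment_neurons(sim$image, pixel_size = 1, min_area_um2 = 20)
  labs2 <- segment_neurons(sim$image, pixel_size = 1, min_area_um2 = 20)
  expect_identical(labs1, labs2)
  expect_equal(attr(labs1, "n_objects"), 15L)
  st <- label_stats(labs1, sim$image, pixel_size = 1)
  expect_equal(nrow(st), 15L)
  expect_true(all(abs(st$area_um2 - 113) < 30))
})

test_that("segmentation is covariant under intensity inversion", {
  sim <- simulate_cell_field(8, radius = 6, window = c(120, 120),
                             noise_sd = 5, seed = 5)
  labs <- segment_neurons(sim$image, pixel_size = 1, min_area_um2 = 20)
  inv <- max(sim$image) + min(sim$image) - sim$image
  labs_inv <- segment_neurons(inv, pixel_size = 1, min_area_um2 = 20,
                              invert = TRUE)
  expect_equal(attr(labs_inv, "n_objects"), attr(labs, "n_objects"))
  expect_gt(mean((labs > 0) == (labs_inv > 0)), 0.995)
})
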