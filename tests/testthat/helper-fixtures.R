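# Shared fixtures, computed once per test run.

# Small annulus phantom: R_in 20, R_out 35 px at 20 um/px -> true thickness
# 300 um, midline radius sqrt(700) ~ 26.46 px.
fix_annulus <- local({
  ph <- make_annulus_phantom(20, 35, 360, pixel_size = 20, centre = c(50, 50))
  grid <- rasterize_ribbon(ph$contour_pair)
  field <- solve_laplace(grid)
  profile <- midline_profile(field, sample_step = 200)
  list(phantom = ph, grid = grid, field = field, profile = profile,
       centre = c(50, 50), true_t = 300, true_r = sqrt(20 * 35))
})

# Straight parallel band: width 20 px at 10 um/px -> 200 um.
fix_band <- local({
  cl <- cbind(seq(0, 200, by = 2), rep(30, 101))
  ph <- make_gyral_ribbon(cl, 20, pixel_size = 10, slide_id = "band")
  grid <- rasterize_ribbon(ph$contour_pair)
  field <- solve_laplace(grid)
  list(phantom = ph, grid = grid, field = field, true_t = 200)
})

# Brute-force medcouple oracle: explicit double loop over the kernel,
# independent of the vectorised implementation.
oracle_medcouple <- function(x) {
  m <- median(x)
  z <- sort(x - m)
  zp <- z[z >= 0]
  zm <- z[z <= 0]
  k <- sum(z == 0)
  vals <- c()
  for (i in seq_along(zp)) {
    for (j in seq_along(zm)) {
      a <- zp[i]; b <- zm[j]
      if (a == 0 && b == 0) {
        p <- i                      # rank among the zero block of zp (zeros first)
        q <- j - (length(zm) - k)   # rank among the zero block of zm (zeros last)
        vals <- c(vals, sign(p + q - (k + 1)))
      } else {
        vals <- c(vals, (a + b) / (a - b))
      }
    }
  }
  median(vals)
}

# Stamp a binary disc mask.
disc_mask <- function(nr, nc, row0, col0, r) {
  m <- matrix(0L, nr, nc)
  m[stamp_disc_idx(row0, col0, r, nr, nc)] <- 1L
  m
}
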