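#' Simulate a Boolean germ-grain cell field
#'
#' Realises a stationary Boolean model: germ points from a homogeneous Poisson
#' process of intensity `lambda_true`, each carrying an independent convex
#' grain (a disc), unioned and stamped dark on a light background, with
#' additive Gaussian noise. Germs are simulated on a window dilated by the
#' maximum grain radius so the observed window sees an edge-corrected,
#' stationary realisation. The analytic area fraction is
#' `1 - exp(-lambda * mean_grain_area)`.
#'
#' @param lambda_true Germ intensity, germs per px^2 (> 0). (Scale to um via
#'   `pixel_size` downstream; the simulator itself works in pixels.)
#' @param grain_spec Grain distribution: `list(shape = "disc", radius = 6)` for
#'   fixed radius, or `radius = c(min, max)` for uniform radii.
#' @param window `c(width, height)` of the observed window in px.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param seed Integer seed; the same seed reproduces the field bit for bit.
#' @param fg,bg Foreground (grain) and background intensities, dark on light.
#' @return List with `image` (height x width numeric matrix) and `truth`, a
#'   `boolean_field_truth` list: `germs` tibble (x, y, radius; window
#'   coordinates, possibly outside the window by up to the max radius),
#'   `lambda_true`, `grain_spec`, `window`, and the analytic `area_fraction`.
#' @examples
#' sim <- simulate_boolean_field(0.001, list(radius = 6), c(200, 200),
#'                               noise_sd = 0, seed = 1)
#' mean(sim$image < 130)  # close to sim$truth$area_fraction
#' @export
simulate_boolean_field <- function(lambda_true, grain_spec = list(radius = 6),
                                   window = c(1000, 1000), noise_sd = 0,
                                   seed = 0, fg = 60, bg = 200) {
  if (!is.numeric(lambda_true) || lambda_true < 0) {
    abort("`lambda_true` must be >= 0.", class = "fcdmap_bad_argument")
  }
  if (length(window) != 2L || any(window < 1)) {
    abort("`window` must be c(width, height) with positive entries.",
          class = "fcdmap_bad_argument")
  }
  radius <- grain_spec$radius %||% 6
  r_max <- max(radius)
  w <- window[1]; h <- window[2]
  nr <- as.integer(h); nc <- as.integer(w)
  with_seed(seed, {
    # dilated window for edge correction
    area_dil <- (w + 2 * r_max) * (h + 2 * r_max)
    n_germ <- rpois(1, lambda_true * area_dil)
    gx <- runif(n_germ, -r_max, w + r_max)
    gy <- runif(n_germ, -r_max, h + r_max)
    gr <- if (length(radius) == 2L) {
      runif(n_germ, radius[1], radius[2])
    } else {
      rep(radius[1], n_germ)
    }
    img <- matrix(bg, nr, nc)
    if (n_germ > 0) {
      for (k in seq_len(n_germ)) {
        idx <- stamp_disc_idx(gy[k], gx[k], gr[k], nr, nc)
        if (length(idx)) img[idx] <- fg
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
    mean_area <- if (length(radius) == 2L) {
      pi * (radius[1]^2 + radius[1] * radius[2] + radius[2]^2) / 3
    } else {
      pi * radius[1]^2
    }
    truth <- structure(
      list(germs = tibble(x = gx, y = gy, radius = gr),
           lambda_true = lambda_true,
           grain_spec = list(shape = "disc", radius = radius),
           window = window,
           area_fraction = 1 - exp(-lambda_true * mean_area)),
      class = "boolean_field_truth"
    )
    list(image = img, truth = truth)
  })
}

#' Simulate a field of well-separated cells
#'
#' Places exactly `n_cells` discs with a minimum centre separation (sequential
#' rejection sampling), dark on light, plus Gaussian noise. This is the
#' ground-truth fixture for validating the neuron segmentation stage, where
#' object count and per-object masks must be recovered.
#'
#' @param n_cells Number of cells.
#' @param radius Disc radius, px.
#' @param window `c(width, height)` px.
#' @param min_sep Minimum centre-to-centre distance, px (default keeps discs
#'   disjoint with a 4 px gap).
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @param fg,bg Foreground/background intensities.
#' @return List with `image`, `centres` tibble and `truth_labels` (integer
#'   matrix, one label per cell, 0 background).
#' @export
simulate_cell_field <- function(n_cells = 50, radius = 6,
                                window = c(400, 400),
                                min_sep = 2 * radius + 4,
                                noise_sd = 10, seed = 0, fg = 80, bg = 200) {
  nr <- as.integer(window[2]); nc <- as.integer(window[1])
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_cells && tries < 200000L) {
      tries <- tries + 1L
      cx <- runif(1, radius + 1, nc - radius - 1)
      cy <- runif(1, radius + 1, nr - radius - 1)
      if (!length(xs) || all((xs - cx)^2 + (ys - cy)^2 >= min_sep^2)) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    if (length(xs) < n_cells) {
      abort("Could not place all cells; lower n_cells or min_sep.",
            class = "fcdmap_bad_argument")
    }
    img <- matrix(bg, nr, nc)
    labs <- matrix(0L, nr, nc)
    for (k in seq_len(n_cells)) {
      idx <- stamp_disc_idx(ys[k], xs[k], radius, nr, nc)
      img[idx] <- fg
      labs[idx] <- k
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    list(image = img, centres = tibble(x = xs, y = ys),
         truth_labels = labs)
  })
}
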