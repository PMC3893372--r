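#' Intrinsic densities of a binary mask
#'
#' Measures the three planar intrinsic densities a Boolean germ-grain model
#' is fitted from: area fraction `A_A`, boundary length density `L_A`
#' (sub-pixel marching-squares contour length per unit area, which avoids the
#' up-to-4/pi overestimate of pixel-edge counting) and Euler characteristic
#' density `chi_A` (bit-quad counts, 8-connected foreground / 4-connected
#' background). With `edge_margin > 0` the window is minus-sampled (eroded)
#' before measuring.
#'
#' @param mask Logical or 0/1 matrix.
#' @param edge_margin Margin excluded on every side, um.
#' @param pixel_size Micrometres per pixel.
#' @param connectivity Foreground adjacency for the Euler count, see
#'   [euler_characteristic()].
#' @return One-row tibble: `a_a` (unitless), `l_a` (1/um), `chi_a` (1/um^2),
#'   `window_area_um2`.
#' @examples
#' m <- matrix(0, 100, 100)
#' m[as.matrix(expand.grid(41:60, 41:60))] <- 1  # 20 x 20 square
#' measure_densities(m)
#' @export
measure_densities <- function(mask, edge_margin = 0, pixel_size = 1,
                              connectivity = 4L) {
  m <- (mask > 0) * 1
  marg_px <- round(edge_margin / pixel_size)
  nr <- nrow(m); nc <- ncol(m)
  if (2 * marg_px >= min(nr, nc)) {
    abort("Window smaller than twice the edge margin.",
          class = "fcdmap_window_too_small")
  }
  if (marg_px > 0) {
    m <- m[(marg_px + 1):(nr - marg_px), (marg_px + 1):(nc - marg_px),
           drop = FALSE]
    nr <- nrow(m); nc <- ncol(m)
  }
  area_px <- nr * nc
  a_a <- sum(m) / area_px
  l_px <- mask_boundary_length(m)
  chi <- euler_characteristic(m, connectivity = connectivity)
  tibble(
    a_a = a_a,
    l_a = l_px / (area_px * pixel_size),
    chi_a = chi / (area_px * pixel_size^2),
    window_area_um2 = area_px * pixel_size^2
  )
}

# Sub-pixel boundary length via marching squares at level 0.5. Contours are
# not closed across the image border, so window-edge cuts contribute no
# artificial boundary.
mask_boundary_length <- function(m) {
  if (sum(m) == 0 || sum(m) == length(m)) return(0)
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                     z = m, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(p) polyline_length(cbind(p$x, p$y)), 1))
}

#' 2D Euler characteristic of a binary mask
#'
#' Bit-quad counting over all 2x2 neighbourhoods of the zero-padded mask:
#' `chi = (Q1 - Q3 + 2 QD) / 4` for the 4-connected-foreground convention
#' (the default) and `(Q1 - Q3 - 2 QD) / 4` for 8-connected foreground,
#' equal to connected components minus holes under the chosen adjacency.
#' Diagonal-only pixel contacts in masks of smooth convex grains are almost
#' always rasterized near-tangencies of grains that do not touch in the
#' continuum, so the 4-connected count tracks the continuous Euler density
#' of a germ-grain set better at coarse resolution.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 4 (default) or 8, the foreground adjacency.
#' @return Integer-valued Euler characteristic.
#' @export
euler_characteristic <- function(mask, connectivity = 4L) {
  if (!connectivity %in% c(4L, 8L)) {
    abort("`connectivity` must be 4 or 8.", class = "fcdmap_bad_argument")
  }
  m <- (mask > 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  a <- p[-(nr + 2L), -(nc + 2L)]
  b <- p[-(nr + 2L), -1]
  c_ <- p[-1, -(nc + 2L)]
  d <- p[-1, -1]
  s <- a + b + c_ + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a == 1L & d == 1L) | (b == 1L & c_ == 1L)))
  if (connectivity == 4L) (q1 - q3 + 2L * qd) / 4 else (q1 - q3 - 2L * qd) / 4
}

#' Fit a Boolean germ-grain model to a binary mask
#'
#' Method-of-densities inversion for a stationary, isotropic Boolean model
#' with convex grains. The measured densities determine the three parameters
#' through
#' \deqn{A_A = 1 - e^{-\lambda \bar A}, \quad
#'       L_A = \lambda \bar U e^{-\lambda \bar A}, \quad
#'       \chi_A = e^{-\lambda \bar A}\left(\lambda -
#'         \frac{\lambda^2 \bar U^2}{4\pi}\right),}
#' which solve in closed sequence for the germ intensity
#' `lambda = chi_A/(1 - A_A) + (L_A/(1 - A_A))^2 / (4 pi)`, the mean grain
#' perimeter `U_bar` and mean grain area `A_bar`. Heavily negative Euler
#' density can drive the intensity negative; that is reported as an
#' infeasible fit (with the sparse-limit diagnostic) rather than clipped.
#'
#' @param mask Logical or 0/1 matrix of segmented neurons.
#' @param edge_margin Minus-sampling margin, um.
#' @param pixel_size Micrometres per pixel.
#' @return A `boolean_fit`: list with `lambda_hat` (1/um^2), `a_bar` (um^2),
#'   `u_bar` (um), the observed densities tibble, `window_area_um2` and
#'   `feasible`.
#' @examples
#' sim <- simulate_boolean_field(0.002, list(radius = 5), c(400, 400),
#'                               noise_sd = 0, seed = 2)
#' fit <- fit_boolean(sim$image < 130)
#' tidy(fit)
#' @export
fit_boolean <- function(mask, edge_margin = 0, pixel_size = 1,
                        connectivity = 4L) {
  dens <- measure_densities(mask, edge_margin, pixel_size, connectivity)
  a_a <- dens$a_a
  if (a_a >= 1) {
    abort("Mask is saturated (area fraction 1); Boolean fit undefined.",
          class = "fcdmap_saturated_mask")
  }
  if (a_a <= 0) {
    abort("Mask is empty; Boolean fit undefined.",
          class = "fcdmap_empty_mask")
  }
  q <- 1 - a_a
  lam_u <- dens$l_a / q
  lambda <- dens$chi_a / q + lam_u^2 / (4 * pi)
  feasible <- is.finite(lambda) && lambda > 0
  if (!feasible) {
    warn("Boolean fit infeasible (non-positive intensity); reporting sparse-limit diagnostics.")
    lambda <- NA_real_
  }
  structure(
    list(
      lambda_hat = lambda,
      a_bar = if (feasible) -log(q) / lambda else NA_real_,
      u_bar = if (feasible) lam_u / lambda else NA_real_,
      densities = dens,
      window_area_um2 = dens$window_area_um2,
      feasible = feasible
    ),
    class = "boolean_fit"
  )
}

#' @export
print.boolean_fit <- function(x, ...) {
  cat(sprintf(
    "<boolean_fit> lambda = %.4g /um^2, A_bar = %.4g um^2, U_bar = %.4g um%s\n",
    x$lambda_hat, x$a_bar, x$u_bar,
    if (x$feasible) "" else " [INFEASIBLE]"))
  invisible(x)
}

#' @describeIn fit_boolean Parameter estimates as a one-row tibble.
#' @param x A `boolean_fit`.
#' @param ... Unused.
#' @export
tidy.boolean_fit <- function(x, ...) {
  tibble(lambda_hat = x$lambda_hat, a_bar = x$a_bar, u_bar = x$u_bar,
         feasible = x$feasible)
}

#' @describeIn fit_boolean Observed densities and window size.
#' @export
glance.boolean_fit <- function(x, ...) {
  dplyr::bind_cols(x$densities, tibble(feasible = x$feasible))
}

#' Granulometric pattern spectrum of a binary mask
#'
#' Sieves the mask through disc openings of increasing radius and reports
#' the area removed in each size band (the pattern spectrum). The opening
#' at radius r is computed as the union of inscribed discs via the Euclidean
#' distance transform: pixels covered by a disc of radius r centred where
#' the transform exceeds r - 1/2. The half-pixel tolerance compensates the
#' non-nested rasterization of similar-radius discs, which otherwise shaves
#' boundary pixels at every size and leaks mask area into small bins.
#' Openings are additionally forced monotone (each intersected with the
#' previous) so the sieving axiom holds exactly, and the final band collects
#' everything the largest element leaves, so the spectrum sums exactly to
#' the foreground area.
#'
#' @param mask Logical or 0/1 matrix.
#' @param sizes Strictly increasing disc radii starting at 0, um.
#' @param pixel_size Micrometres per pixel.
#' @return Tibble of class `pattern_spectrum`: `size_lo`, `size_hi` (um; last
#'   row has `size_hi = Inf`), `area_um2`.
#' @examples
#' m <- matrix(0, 60, 60)
#' xy <- expand.grid(r = 1:60, c = 1:60)
#' m[as.matrix(xy)[(xy$r - 30)^2 + (xy$c - 30)^2 <= 64, ]] <- 1
#' granulometry(m, sizes = c(0, 4, 8, 12))
#' @export
granulometry <- function(mask, sizes = seq(0, 30, by = 0.74),
                         pixel_size = 1) {
  if (length(sizes) < 2L || any(diff(sizes) <= 0) || sizes[1] != 0) {
    abort("`sizes` must be strictly increasing and start at 0.",
          class = "fcdmap_invalid_sizes")
  }
  m <- (mask > 0) * 1
  areas <- numeric(length(sizes))
  cur <- m
  px2 <- pixel_size^2
  dt <- if (any(m > 0)) ebi_mat(EBImage::distmap(m)) else m
  for (i in seq_along(sizes)) {
    if (sizes[i] > 0) {
      r_px <- sizes[i] / pixel_size
      centres <- (dt > r_px - 0.5) * 1
      op <- if (any(centres > 0)) {
        pmin(m, ebi_mat(EBImage::dilate(centres, disc_brush(r_px))))
      } else {
        matrix(0, nrow(m), ncol(m))
      }
      cur <- pmin(cur, op) # enforce the sieving axiom
    }
    areas[i] <- sum(cur) * px2
  }
  out <- tibble(
    size_lo = sizes,
    size_hi = c(sizes[-1], Inf),
    area_um2 = c(-diff(areas), areas[length(areas)])
  )
  class(out) <- c("pattern_spectrum", class(out))
  out
}

#' Per-lamina spatial statistics
#'
#' Computes the Boolean fit or the pattern spectrum independently within
#' each lamina band of a mask. Bands are transverse stripes given as row
#' intervals (the cortical depth direction along rows). When several masks
#' are supplied, pattern spectra are averaged bin-wise across masks and the
#' Boolean fits are returned per mask.
#'
#' @param mask A binary matrix, or a list of binary matrices (regions).
#' @param lamina_bands Tibble with `lamina`, `row_start`, `row_end` covering
#'   the cortical extent of the mask.
#' @param which `"boolean"` or `"granulometry"`.
#' @param ... Passed to [fit_boolean()] or [granulometry()].
#' @return For `"boolean"`: tibble of tidy fits with `lamina` (and `region`
#'   when several masks). For `"granulometry"`: tibble of spectra with
#'   `lamina`, averaged over masks.
#' @export
stats_by_lamina <- function(mask, lamina_bands,
                            which = c("boolean", "granulometry"), ...) {
  which <- match.arg(which)
  masks <- if (is.list(mask)) mask else list(mask)
  bands <- as_tibble(lamina_bands)
  req <- c("lamina", "row_start", "row_end")
  if (!all(req %in% names(bands))) {
    abort("`lamina_bands` needs columns lamina, row_start, row_end.",
          class = "fcdmap_bad_argument")
  }
  dots <- list(...)
  res <- purrr::imap(masks, function(m, region) {
    purrr::pmap(bands[c("lamina", "row_start", "row_end")],
                function(lamina, row_start, row_end) {
      if (row_start < 1 || row_end > nrow(m) || row_start > row_end) {
        warn(sprintf("Lamina %s outside mask extent; skipped.", lamina))
        return(NULL)
      }
      sub <- m[row_start:row_end, , drop = FALSE]
      if (which == "boolean") {
        fit <- tryCatch(do.call(fit_boolean, c(list(sub), dots)),
                        error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        dplyr::bind_cols(tibble(region = region, lamina = lamina), tidy(fit))
      } else {
        sp <- do.call(granulometry, c(list(sub), dots))
        dplyr::bind_cols(tibble(region = region, lamina = lamina),
                         as_tibble(sp))
      }
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (which == "granulometry" && length(masks) > 1L) {
    res <- res |>
      dplyr::group_by(.data$lamina, .data$size_lo, .data$size_hi) |>
      dplyr::summarise(area_um2 = mean(.data$area_um2), .groups = "drop")
  }
  res
}

#' Modal size of a pattern spectrum
#'
#' The centre of the finite size band holding the largest removed area: the
#' summary used to compare cell-size distributions between groups (a
#' downward modal shift indicates smaller stained objects).
#'
#' @param spectrum A `pattern_spectrum`.
#' @return Modal size, um.
#' @export
spectrum_mode <- function(spectrum) {
  sp <- spectrum[is.finite(spectrum$size_hi), , drop = FALSE]
  if (!nrow(sp) || all(sp$area_um2 <= 0)) return(NA_real_)
  i <- which.max(sp$area_um2)
  (sp$size_lo[i] + sp$size_hi[i]) / 2
}
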