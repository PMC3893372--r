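#' Signed curvature of an ordered curve by sliding circular-arc fit
#'
#' Fits a circle (algebraic least squares) to the points inside a sliding
#' window of fixed arc length around each sample and reports kappa = 1/r in
#' 1/mm. The sign convention is anatomical: positive where the curve is
#' locally convex toward the outer (pial) side, i.e. at gyral crests;
#' negative in sulcal fundi. The outward side is given per point via
#' `outward` (unit vectors toward the pial contour); without it the sign
#' comes from the traversal orientation (left turns positive in the y-down
#' pixel convention) and is relative, not anatomical.
#'
#' @param points n x 2 matrix of curve samples (px), ordered.
#' @param window_um Arc length of the fitting window, um (default 2000;
#'   window smoothing suppresses rasterization noise).
#' @param pixel_size Micrometres per pixel.
#' @param outward Optional n x 2 matrix of unit vectors pointing toward the
#'   outer contour at each sample.
#' @return Numeric vector of signed curvatures, 1/mm.
#' @export
curvature <- function(points, window_um = 2000, pixel_size = 1,
                      outward = NULL) {
  pts <- as_xy_matrix(points)
  n <- nrow(pts)
  if (n < 3L) {
    abort("Need at least 3 points to estimate curvature.",
          class = "fcdmap_insufficient_curve")
  }
  s_um <- polyline_arc(pts) * pixel_size
  half <- window_um / 2
  kappa <- numeric(n)
  for (i in seq_len(n)) {
    sel <- which(abs(s_um - s_um[i]) <= half)
    if (length(sel) < 3L) {
      sel <- max(1L, i - 1L):min(n, i + 1L)
    }
    kappa[i] <- fit_circle_kappa(pts[sel, , drop = FALSE], pts[i, ],
                                 if (is.null(outward)) NULL else outward[i, ])
  }
  kappa / (pixel_size / 1000) # 1/px -> 1/mm
}

# Kasa algebraic circle fit; returns signed 1/r (1/px units).
fit_circle_kappa <- function(w, p0, out_vec) {
  x <- w[, 1]; y <- w[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) return(0)
  cx <- fit[1]; cy <- fit[2]
  r2 <- fit[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(0)
  r <- sqrt(r2)
  if (r > 1e6) return(0)
  k <- 1 / r
  if (!is.null(out_vec)) {
    # centre of curvature on the inner side => convex toward outer => positive
    s <- sign((p0[1] - cx) * out_vec[1] + (p0[2] - cy) * out_vec[2])
    if (s == 0) s <- 1
    k * s
  } else {
    # orientation-based sign: left turn (counter-clockwise in y-down coords)
    i0 <- which.min((w[, 1] - p0[1])^2 + (w[, 2] - p0[2])^2)
    i1 <- max(1L, i0 - 1L); i2 <- min(nrow(w), i0 + 1L)
    t1 <- w[i0, ] - w[i1, ]; t2 <- w[i2, ] - w[i0, ]
    cr <- t1[1] * t2[2] - t1[2] * t2[1]
    if (cr == 0) k else k * sign(cr)
  }
}

#' Sample thickness and curvature on the mid-cortical equipotential
#'
#' Extracts the phi = 0 level set of the solved potential by marching squares
#' with linear (sub-pixel) interpolation, resamples it at a regular arc-length
#' step, and at every sample records the cortical thickness (length of the
#' field line through the sample, traced to both boundaries) and the signed
#' curvature of the midline (positive at gyral crests).
#'
#' @param field A `potential_field` from [solve_laplace()].
#' @param sample_step Arc-length sampling step on the midline, um.
#' @param curvature_window Arc window of the curvature fit, um.
#' @param min_piece_samples Contour pieces with fewer raw vertices are
#'   discarded as rasterization debris.
#' @param trim_um Arc length trimmed from each end of every open midline
#'   piece, um (field lines within roughly one cortical width of an open cut
#'   edge run into the insulating end face; default 0).
#' @return A tibble of class `midline_profile` with columns `slide_id`,
#'   `piece`, `sample`, `x_px`, `y_px`, `arc_s_um`, `t_um`, `kappa_per_mm`;
#'   attribute `pixel_size`.
#' @examples
#' ph <- make_annulus_phantom(20, 35, 360, pixel_size = 20)
#' field <- solve_laplace(rasterize_ribbon(ph$contour_pair))
#' prof <- midline_profile(field, sample_step = 200)
#' summary(prof$t_um)
#' @export
midline_profile <- function(field, sample_step = 1000,
                            curvature_window = 2000,
                            min_piece_samples = 5L, trim_um = 0) {
  stopifnot(inherits(field, "potential_field"))
  grid <- field$grid
  scale_um <- grid$grid_spacing * grid$pixel_size
  step_grid <- sample_step / scale_um

  pieces <- extract_level_set(field$phi, level = 0)
  pieces <- pieces[vapply(pieces, nrow, 1L) >= min_piece_samples]
  if (!length(pieces)) {
    abort("phi = 0 level set is empty (degenerate ribbon).",
          class = "fcdmap_no_midline")
  }

  grads <- gradient_rasters(field$phi)
  out <- vector("list", length(pieces))
  for (pc in seq_along(pieces)) {
    pts <- resample_polyline(pieces[[pc]], step_grid)
    closed_piece <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < step_grid
    # deterministic traversal direction: open pieces run in ascending x
    # (then y), so arc positions are reproducible across reruns
    if (!closed_piece) {
      a <- pts[1, ]; b <- pts[nrow(pts), ]
      if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) {
        pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      }
    }
    arc_um <- polyline_arc(pts) * scale_um
    if (trim_um > 0 && nrow(pts) > 2L && !closed_piece) {
      keep <- arc_um >= trim_um & arc_um <= max(arc_um) - trim_um
      if (sum(keep) >= 3L) {
        pts <- pts[keep, , drop = FALSE]
        arc_um <- arc_um[keep] # keep the untrimmed arc origin
      }
    }
    t_um <- thickness_at(field, pts)
    # outward (pial) direction = -grad(phi)
    gx <- interp_bilinear(grads$gx, pts[, 1], pts[, 2])
    gy <- interp_bilinear(grads$gy, pts[, 1], pts[, 2])
    nm <- sqrt(gx^2 + gy^2)
    outward <- cbind(-gx / nm, -gy / nm)
    outward[!is.finite(outward)] <- 0
    kappa <- curvature(pts, window_um = curvature_window,
                       pixel_size = scale_um, outward = outward)
    px <- grid$x0 + (pts[, 1] - 1) * grid$grid_spacing
    py <- grid$y0 + (pts[, 2] - 1) * grid$grid_spacing
    out[[pc]] <- tibble(
      slide_id = grid$slide_id,
      piece = pc,
      sample = seq_len(nrow(pts)),
      x_px = px, y_px = py,
      arc_s_um = arc_um,
      t_um = t_um,
      kappa_per_mm = kappa
    )
  }
  res <- dplyr::bind_rows(out)
  bad <- !is.finite(res$t_um) | res$t_um <= 0
  if (any(bad)) res <- res[!bad, , drop = FALSE]
  attr(res, "pixel_size") <- grid$pixel_size
  class(res) <- c("midline_profile", class(res))
  res
}

# Marching-squares level-set extraction via grDevices::contourLines,
# returning pieces as matrices in grid (col = x, row = y) coordinates.
extract_level_set <- function(phi, level = 0) {
  cl <- contourLines(x = seq_len(nrow(phi)), y = seq_len(ncol(phi)),
                     z = phi, levels = level)
  lapply(cl, function(p) cbind(p$y, p$x)) # (col, row) -> (x, y) grid coords
}

#' Write a midline profile as CSV
#' @param profile A `midline_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(as_tibble(profile), path)
  invisible(path)
}

#' @rdname write_profile
#' @param slide_id Slide identifier to attach when reading.
#' @export
read_profile <- function(path, slide_id = NULL) {
  res <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(slide_id)) res$slide_id <- slide_id
  class(res) <- c("midline_profile", class(res))
  res
}
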