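#' Annulus ribbon phantom with constant analytic thickness
#'
#' Builds a cortical-ribbon phantom from two concentric circles. The true
#' thickness is exactly `r_outer - r_inner` pixels at every arc position, and
#' the Laplace solution between the circles is the closed form
#' `phi(r) = a + b log(r)`, whose zero level sits at the geometric-mean radius
#' `sqrt(r_inner * r_outer)`. This makes the annulus the primary analytic
#' fixture for the thickness pipeline.
#'
#' @param r_inner,r_outer Radii of the inner (grey/white) and outer (pial)
#'   circles in pixels; `0 < r_inner < r_outer`.
#' @param n_points Vertices per contour.
#' @param pixel_size Micrometres per pixel.
#' @param centre Circle centre `(x, y)` in px.
#' @param slide_id Identifier.
#' @return A `ribbon_phantom`: list with the [contour_pair()], a
#'   `true_thickness(s_um)` function (um), `true_midline_radius` (px), and
#'   `implanted_foci` (empty).
#' @examples
#' ph <- make_annulus_phantom(40, 70, 720)
#' ph$true_thickness(0)  # 300 um at 10 um/px
#' @export
make_annulus_phantom <- function(r_inner, r_outer, n_points = 720,
                                 pixel_size = 10, centre = c(0, 0),
                                 slide_id = "annulus") {
  if (!(r_inner > 0 && r_outer > r_inner)) {
    abort("Require 0 < r_inner < r_outer.", class = "fcdmap_invalid_geometry")
  }
  th <- seq(0, 2 * pi, length.out = n_points + 1L)
  circ <- function(r) cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
  cp <- contour_pair(circ(r_outer), circ(r_inner), pixel_size,
                     slide_id = slide_id, closed = TRUE, validate = FALSE)
  t_um <- (r_outer - r_inner) * pixel_size
  structure(
    list(
      contour_pair = cp,
      true_thickness = function(s_um) rep(t_um, length(s_um)),
      true_curvature_sign = function(s_um) rep("crest", length(s_um)),
      true_midline_radius = sqrt(r_inner * r_outer),
      centre = centre,
      implanted_foci = list()
    ),
    class = "ribbon_phantom"
  )
}

#' Gyral ribbon phantom from a centreline with optional implanted thin foci
#'
#' Offsets a centreline by half the prescribed thickness profile along its
#' normals to obtain outer and inner contours, giving a ribbon whose true
#' thickness is the profile itself. Foci multiply the profile on an arc
#' interval (exactly inside the interval, with a short cosine taper outside it
#' so the offset curves stay smooth), emulating circumscribed dysplastic
#' thinning.
#'
#' @param centerline n x 2 matrix of points (px); traversed left to right, the
#'   outer (pial) side is "up" (decreasing y, y-down convention).
#' @param thickness_profile Either a single number (px) or a function of arc
#'   length along the centreline (px in, px out).
#' @param foci List of foci, each `list(s_start, s_end, multiplier)` with the
#'   interval in micrometres of centreline arc.
#' @param pixel_size Micrometres per pixel.
#' @param taper_um Length of the cosine taper applied outside each focus (um).
#' @param slide_id Identifier.
#' @param crest_threshold |d2y/dx2|-scale threshold below which arcs are
#'   labelled `flat` (1/px).
#' @return A `ribbon_phantom` whose `true_thickness(s_um)` returns um and whose
#'   `true_curvature_sign(s_um)` labels arcs `crest`, `sulcus` or `flat`
#'   (crest = centreline convex toward the outer contour).
#' @export
make_gyral_ribbon <- function(centerline, thickness_profile, foci = list(),
                              pixel_size = 100, taper_um = 800,
                              slide_id = "ribbon", crest_threshold = 1e-4) {
  centerline <- as_xy_matrix(centerline, "centerline")
  s_px <- polyline_arc(centerline)
  prof_fun <- if (is.function(thickness_profile)) {
    thickness_profile
  } else {
    function(s) rep(thickness_profile, length(s))
  }
  base_px <- prof_fun(s_px)
  if (any(base_px <= 0)) {
    abort("thickness_profile must be positive everywhere.",
          class = "fcdmap_invalid_geometry")
  }
  mult <- focus_multiplier(s_px * pixel_size, foci, taper_um)
  half <- base_px * mult / 2

  # unit tangents (central differences) and outward normals (rotate -90 deg:
  # for a left-to-right centreline the outward side is up, i.e. -y)
  n <- nrow(centerline)
  tx <- c(centerline[2, 1] - centerline[1, 1],
          centerline[3:n, 1] - centerline[1:(n - 2), 1],
          centerline[n, 1] - centerline[n - 1, 1])
  ty <- c(centerline[2, 2] - centerline[1, 2],
          centerline[3:n, 2] - centerline[1:(n - 2), 2],
          centerline[n, 2] - centerline[n - 1, 2])
  nm <- sqrt(tx^2 + ty^2)
  tx <- tx / nm; ty <- ty / nm
  nx <- ty; ny <- -tx
  outer_c <- cbind(centerline[, 1] + half * nx, centerline[, 2] + half * ny)
  inner_c <- cbind(centerline[, 1] - half * nx, centerline[, 2] - half * ny)

  # an offset larger than the local bend radius flips the offset curve's
  # direction (cusp) even when no segments cross outright
  flipped <- function(curve) {
    dx <- diff(curve[, 1]); dy <- diff(curve[, 2])
    any(dx * tx[-n] + dy * ty[-n] <= 0)
  }
  if (flipped(outer_c) || flipped(inner_c) ||
      polyline_self_intersects(outer_c, FALSE) ||
      polyline_self_intersects(inner_c, FALSE) ||
      polylines_cross(outer_c, inner_c)) {
    abort("Offset contours self-intersect; reduce thickness or curvature.",
          class = "fcdmap_invalid_geometry")
  }
  cp <- contour_pair(outer_c, inner_c, pixel_size, slide_id = slide_id,
                     closed = FALSE, validate = FALSE)

  truth_t <- function(s_um) {
    s <- s_um / pixel_size
    approx(s_px, base_px, xout = pmin(pmax(s, 0), max(s_px)))$y *
      focus_multiplier(pmin(pmax(s_um, 0), max(s_px) * pixel_size),
                       foci, taper_um) * pixel_size
  }

  # crest/sulcus labels from the analytic second derivative of the centreline:
  # crest where the curve bulges toward the outer contour (local min of y).
  # The arc-length second derivative points toward the centre of curvature.
  # At a gyral crest the ribbon bulges toward the outer contour, so the centre
  # of curvature lies on the inner side: d2 . n_outer < 0 there.
  d2 <- second_derivative(s_px, centerline)
  bend <- d2[, 1] * nx + d2[, 2] * ny
  lab <- ifelse(abs(bend) < crest_threshold, "flat",
                ifelse(bend < 0, "crest", "sulcus"))
  truth_lab <- function(s_um) {
    s <- pmin(pmax(s_um / pixel_size, 0), max(s_px))
    lab[pmax(1L, pmin(n, round(approx(s_px, seq_len(n), xout = s)$y)))]
  }

  structure(
    list(contour_pair = cp,
         true_thickness = truth_t,
         true_curvature_sign = truth_lab,
         centerline = centerline,
         arc_um = s_px * pixel_size,
         implanted_foci = foci),
    class = "ribbon_phantom"
  )
}

focus_multiplier <- function(s_um, foci, taper_um) {
  m <- rep(1, length(s_um))
  for (f in foci) {
    mult <- f$multiplier
    inside <- s_um >= f$s_start & s_um <= f$s_end
    m[inside] <- pmin(m[inside], mult)
    if (taper_um > 0) {
      lo <- s_um > f$s_start - taper_um & s_um < f$s_start
      frac <- (f$s_start - s_um[lo]) / taper_um
      m[lo] <- pmin(m[lo], mult + (1 - mult) * (1 - cos(pi * frac)) / 2)
      hi <- s_um > f$s_end & s_um < f$s_end + taper_um
      frac <- (s_um[hi] - f$s_end) / taper_um
      m[hi] <- pmin(m[hi], mult + (1 - mult) * (1 - cos(pi * frac)) / 2)
    }
  }
  m
}

second_derivative <- function(s, pts) {
  n <- nrow(pts)
  d1x <- c(NA, diff(pts[, 1])) / c(NA, diff(s))
  d1y <- c(NA, diff(pts[, 2])) / c(NA, diff(s))
  mid_s <- (s[-1] + s[-n]) / 2
  d2x <- c(NA, diff(d1x[-1]) / diff(mid_s), NA)
  d2y <- c(NA, diff(d1y[-1]) / diff(mid_s), NA)
  d2x[is.na(d2x)] <- 0; d2y[is.na(d2y)] <- 0
  cbind(d2x, d2y)
}

#' @export
print.ribbon_phantom <- function(x, ...) {
  cat(sprintf("<ribbon_phantom> slide '%s', %d foci\n",
              x$contour_pair$slide_id, length(x$implanted_foci)))
  invisible(x)
}

#' Matched case/control ribbon phantom pair
#'
#' Generates a randomised sinusoidal gyral ribbon, then an identical twin with
#' one implanted thin focus. Used for the focus-recovery validation of the
#' fence-based screening stage: the control twin supplies the thickness
#' distribution, the focus in the case twin is the ground truth to recover.
#'
#' @param seed Integer seed driving all randomness (geometry, focus placement).
#' @param focus_multiplier Thickness multiplier inside the focus (e.g. 0.5).
#' @param focus_len_um Focus length, um of arc.
#' @param length_px Centreline length in px.
#' @param base_thickness_px Baseline thickness in px.
#' @param pixel_size Micrometres per pixel.
#' @return List with `case` and `control` ribbon phantoms and the implanted
#'   `focus` interval (`s_start`, `s_end`, um of centreline arc).
#' @export
make_phantom_pair <- function(seed, focus_multiplier = 0.7,
                              focus_len_um = 4000, length_px = 700,
                              base_thickness_px = 25, pixel_size = 100,
                              taper_um = 500) {
  with_seed(seed, {
    amp <- runif(1, 8, 15)
    wav <- runif(1, 260, 340)
    phase <- runif(1, 0, 2 * pi)
    xs <- seq(0, length_px, by = 2)
    cl <- cbind(xs, 60 + amp * sin(2 * pi * xs / wav + phase))
    # smooth within-slide thickness variation of about +/-0.1 mm around the
    # 2.5 mm baseline: small enough that the fence rule retains sensitivity
    # to a 0.7x focus, the regime this phantom is built to probe. Two
    # incommensurate spatial frequencies give a roughly unimodal thickness
    # distribution (a single sinusoid produces a U-shaped marginal on which
    # the medcouple is unstable).
    a1 <- runif(1, 0.4, 0.6); ph1 <- runif(1, 0, 2 * pi)
    a2 <- 1 - a1; ph2 <- runif(1, 0, 2 * pi)
    # wavelengths short enough that the window holds many periods, so the
    # thickness distribution (and hence the fences) is stable across seeds
    prof <- function(s) {
      base_thickness_px + a1 * sin(2 * pi * s / 97 + ph1) +
        a2 * sin(2 * pi * s / 41 + ph2)
    }
    total_um <- polyline_length(cl) * pixel_size
    f_start <- runif(1, 0.2 * total_um, 0.8 * total_um - focus_len_um)
    focus <- list(s_start = f_start, s_end = f_start + focus_len_um,
                  multiplier = focus_multiplier)
    list(
      case = make_gyral_ribbon(cl, prof, foci = list(focus),
                               pixel_size = pixel_size, taper_um = taper_um,
                               slide_id = "case"),
      control = make_gyral_ribbon(cl, prof, pixel_size = pixel_size,
                                  taper_um = taper_um, slide_id = "control"),
      focus = focus
    )
  })
}

#' Simulated rater-mask pair with controlled disagreement
#'
#' Flips each pixel of `base_mask` independently with probability `flip_prob`,
#' twice, to emulate two raters tracing the same section. At `flip_prob = 0`
#' the raters agree perfectly; agreement decreases monotonically in
#' `flip_prob`.
#'
#' @param base_mask Logical or 0/1 matrix.
#' @param flip_prob Per-pixel label flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @return List with logical matrices `mask_a`, `mask_b`.
#' @export
make_rater_masks <- function(base_mask, flip_prob, seed) {
  if (!is.numeric(flip_prob) || flip_prob < 0 || flip_prob > 1) {
    abort("`flip_prob` must be in [0, 1].", class = "fcdmap_bad_argument")
  }
  base <- base_mask > 0
  with_seed(seed, {
    flip_a <- matrix(runif(length(base)) < flip_prob, nrow(base))
    flip_b <- matrix(runif(length(base)) < flip_prob, nrow(base))
    list(mask_a = xor(base, flip_a), mask_b = xor(base, flip_b))
  })
}
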