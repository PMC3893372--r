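# Field-line integration through the solved potential.
#
# Field lines follow the normalized gradient of phi, integrated with 4th-order
# Runge-Kutta at a fixed sub-pixel step on the bilinearly interpolated
# gradient. Cortical thickness at a midline point is the length of the full
# field line through it (traced toward both boundaries and summed).

# Central-difference gradient rasters (one-sided at the rim), NA outside.
gradient_rasters <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  pad <- function(m) {
    out <- matrix(NA_real_, nr + 2L, nc + 2L)
    out[2:(nr + 1L), 2:(nc + 1L)] <- m
    out
  }
  p <- pad(phi)
  xm <- p[2:(nr + 1L), 1:nc]       # col - 1
  xp <- p[2:(nr + 1L), 3:(nc + 2L)] # col + 1
  ym <- p[1:nr, 2:(nc + 1L)]       # row - 1
  yp <- p[3:(nr + 2L), 2:(nc + 1L)] # row + 1
  gx <- ifelse(!is.na(xm) & !is.na(xp), (xp - xm) / 2,
               ifelse(!is.na(xp), xp - phi, ifelse(!is.na(xm), phi - xm, NA)))
  gy <- ifelse(!is.na(ym) & !is.na(yp), (yp - ym) / 2,
               ifelse(!is.na(yp), yp - phi, ifelse(!is.na(ym), phi - ym, NA)))
  gx[is.na(phi)] <- NA
  gy[is.na(phi)] <- NA
  list(gx = gx, gy = gy)
}

# Bilinear interpolation at continuous (col = x, row = y) grid coordinates,
# vectorised over points; NA corners get zero weight (renormalised).
interp_bilinear <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  j0 <- floor(x); i0 <- floor(y)
  fx <- x - j0; fy <- y - i0
  j0 <- pmin(pmax(j0, 1L), nc - 1L)
  i0 <- pmin(pmax(i0, 1L), nr - 1L)
  v00 <- mat[cbind(i0, j0)]
  v01 <- mat[cbind(i0, j0 + 1L)]
  v10 <- mat[cbind(i0 + 1L, j0)]
  v11 <- mat[cbind(i0 + 1L, j0 + 1L)]
  w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
  w10 <- (1 - fx) * fy;       w11 <- fx * fy
  vals <- cbind(v00, v01, v10, v11)
  ws <- cbind(w00, w01, w10, w11)
  ws[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  tot <- rowSums(ws)
  out <- rowSums(vals * ws) / tot
  out[tot <= 0] <- NA_real_
  out
}

# Trace field lines from many start points at once, toward phi = `target`
# (+1 or -1). Returns per-start traversed length (grid units) and endpoint.
# `target_curve` (densified boundary polyline in grid coordinates) makes the
# final segment exact: the trace stops in the last clean cell before the rim
# and is extended by its distance to the traced contour. `keep_path`
# additionally records the polyline for the first start.
trace_toward <- function(phi, grads, starts, target, step = 0.25,
                         eps = 0.02, max_steps = NULL, keep_path = FALSE,
                         target_curve = NULL) {
  m <- nrow(starts)
  nr <- nrow(phi); nc <- ncol(phi)
  if (is.null(max_steps)) max_steps <- ceiling(6 * (nr + nc) / step)
  sgn <- if (target > 0) 1 else -1
  px <- starts[, 1]; py <- starts[, 2]
  len <- numeric(m)
  active <- rep(TRUE, m)
  done_ok <- rep(FALSE, m)
  phi_cur <- interp_bilinear(phi, px, py)
  path <- if (keep_path) list(cbind(px[1], py[1])) else NULL
  g_floor <- 1e-8

  dir_fun <- function(x, y) {
    gx <- interp_bilinear(grads$gx, x, y)
    gy <- interp_bilinear(grads$gy, x, y)
    nm <- sqrt(gx^2 + gy^2)
    bad <- is.na(nm) | nm < g_floor
    ux <- sgn * gx / nm; uy <- sgn * gy / nm
    ux[bad] <- NA; uy[bad] <- NA
    list(ux = ux, uy = uy, nm = nm)
  }

  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    ax <- px[active]; ay <- py[active]
    k1 <- dir_fun(ax, ay)
    k2 <- dir_fun(ax + step / 2 * k1$ux, ay + step / 2 * k1$uy)
    k3 <- dir_fun(ax + step / 2 * k2$ux, ay + step / 2 * k2$uy)
    k4 <- dir_fun(ax + step * k3$ux, ay + step * k3$uy)
    dx <- step / 6 * (k1$ux + 2 * k2$ux + 2 * k3$ux + k4$ux)
    dy <- step / 6 * (k1$uy + 2 * k2$uy + 2 * k3$uy + k4$uy)
    # fall back to Euler where higher-order samples left the field
    bad_rk <- is.na(dx) & !is.na(k1$ux)
    dx[bad_rk] <- step * k1$ux[bad_rk]
    dy[bad_rk] <- step * k1$uy[bad_rk]

    nx <- ax + dx; ny <- ay + dy
    phi_new <- interp_bilinear(phi, nx, ny)
    stopped <- is.na(dx) | is.na(phi_new)

    # a step should advance phi by about step * |grad phi|; a step that makes
    # almost no potential progress has entered a degenerate rim strip
    # (interpolation plateau) and is rejected like leaving the field
    no_prog <- !stopped &
      (sgn * (phi_new - phi_cur[active]) < 0.1 * step * pmax(k1$nm, g_floor))
    no_prog[is.na(no_prog)] <- FALSE
    stopped <- stopped | no_prog

    idx_act <- which(active)
    move <- !stopped
    if (any(move)) {
      ii <- idx_act[move]
      px[ii] <- nx[move]; py[ii] <- ny[move]
      len[ii] <- len[ii] + step
      phi_cur[ii] <- phi_new[move]
      if (keep_path && active[1] && move[1] && idx_act[1] == 1L) {
        path[[length(path) + 1L]] <- cbind(px[1], py[1])
      }
      # terminate once the estimated remaining distance to the +/-1 level
      # set drops below one grid unit; the final segment is the linear
      # extension onto the level set
      g <- dir_fun(px[ii], py[ii])
      rem <- (1 - sgn * phi_new[move]) / pmax(g$nm, g_floor)
      reach <- (rem <= 1) | (sgn * phi_new[move] >= 1 - eps)
      reach[is.na(reach)] <- FALSE
      if (any(reach)) {
        jj <- ii[reach]
        extra <- final_extension(px[jj], py[jj],
                                 pmin(pmax(rem[reach], 0), 2), target_curve)
        len[jj] <- len[jj] + extra
        ux <- g$ux[reach]; uy <- g$uy[reach]
        px[jj] <- px[jj] + extra * ifelse(is.na(ux), 0, ux)
        py[jj] <- py[jj] + extra * ifelse(is.na(uy), 0, uy)
        active[jj] <- FALSE
        done_ok[jj] <- TRUE
      }
    }
    if (any(stopped)) {
      jj <- idx_act[stopped]
      # extend from the last good position (no length credit for the
      # rejected step)
      g <- dir_fun(px[jj], py[jj])
      rem <- (1 - sgn * phi_cur[jj]) / pmax(g$nm, g_floor)
      rem[!is.finite(rem)] <- 0
      extra <- final_extension(px[jj], py[jj], pmin(pmax(rem, 0), 2),
                               target_curve)
      len[jj] <- len[jj] + extra
      active[jj] <- FALSE
      done_ok[jj] <- TRUE
    }
  }
  done_ok[active] <- FALSE
  list(length = len, end = cbind(px, py), ok = done_ok,
       path = if (keep_path) do.call(rbind, path) else NULL)
}

# Final segment of a trace: exact distance to the traced boundary contour if
# available, otherwise the harmonic extrapolation `fallback`.
final_extension <- function(x, y, fallback, target_curve) {
  if (is.null(target_curve) || !length(x)) return(fallback)
  d <- dist_to_curve(x, y, target_curve)
  ifelse(is.finite(d) & d <= 3, d, fallback)
}

#' Trace the field line through a point
#'
#' Integrates the field line of the solved potential through `start` toward
#' both boundaries (4th-order Runge-Kutta, step 0.25 px, bilinear gradient
#' interpolation, final segment linearly interpolated onto the +/-1 level
#' sets). The returned length is the cortical thickness at `start`.
#'
#' @param field A `potential_field` from [solve_laplace()].
#' @param start `c(x, y)` in contour pixel coordinates, strictly inside the
#'   grey matter.
#' @param step Integration step in grid cells.
#' @return List with `polyline` (n x 2, px coordinates, ordered from the
#'   outer to the inner boundary), `length_um`, and the two endpoint rows.
#' @export
trace_field_line <- function(field, start, step = 0.25) {
  stopifnot(inherits(field, "potential_field"))
  grid <- field$grid
  g <- (rbind(start) - c(grid$x0, grid$y0)) / grid$grid_spacing + 1
  phi0 <- interp_bilinear(field$phi, g[1], g[2])
  if (is.na(phi0)) {
    abort("`start` is not inside the grey matter.", class = "fcdmap_bad_argument")
  }
  grads <- gradient_rasters(field$phi)
  gx <- interp_bilinear(grads$gx, g[1], g[2])
  gy <- interp_bilinear(grads$gy, g[1], g[2])
  if (is.na(gx) || sqrt(gx^2 + gy^2) < 1e-8) {
    abort("Gradient magnitude below floor at `start` (flat field).",
          class = "fcdmap_degenerate_gradient")
  }
  up <- trace_toward(field$phi, grads, g, +1, step, keep_path = TRUE,
                     target_curve = grid$inner_curve)
  dn <- trace_toward(field$phi, grads, g, -1, step, keep_path = TRUE,
                     target_curve = grid$outer_curve)
  scale_um <- grid$grid_spacing * grid$pixel_size
  to_px <- function(p) {
    cbind(grid$x0 + (p[, 1] - 1) * grid$grid_spacing,
          grid$y0 + (p[, 2] - 1) * grid$grid_spacing)
  }
  poly <- rbind(to_px(dn$end)[1, , drop = FALSE],
                to_px(dn$path[rev(seq_len(nrow(dn$path))), , drop = FALSE]),
                to_px(up$path),
                to_px(up$end)[1, , drop = FALSE])
  list(
    polyline = poly,
    length_um = (up$length + dn$length) * scale_um,
    end_inner = to_px(up$end)[1, ],
    end_outer = to_px(dn$end)[1, ]
  )
}

# Thickness at many grid-coordinate start points (both directions summed),
# in um. Internal workhorse for midline_profile.
thickness_at <- function(field, starts_grid, step = 0.25) {
  grads <- gradient_rasters(field$phi)
  up <- trace_toward(field$phi, grads, starts_grid, +1, step,
                     target_curve = field$grid$inner_curve)
  dn <- trace_toward(field$phi, grads, starts_grid, -1, step,
                     target_curve = field$grid$outer_curve)
  scale_um <- field$grid$grid_spacing * field$grid$pixel_size
  (up$length + dn$length) * scale_um
}
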