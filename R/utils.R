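# Internal geometry and raster helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards. All stochastic operations in the package funnel through
#' this, so a seed argument fully determines the output without disturbing
#' the session's random stream.
#'
#' @param seed A single integer.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "fcdmap_bad_seed")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

as_xy_matrix <- function(points, arg = "points") {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y"), names(points))
    if (length(cols) == 2L) {
      points <- cbind(points$x, points$y)
    } else {
      points <- as.matrix(points[, 1:2])
    }
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L || !is.numeric(points)) {
    abort(sprintf("`%s` must be an n x 2 numeric matrix of (x, y).", arg),
          class = "fcdmap_bad_points")
  }
  unname(points)
}

# Cumulative arc length of an open polyline, in the units of its coordinates.
polyline_arc <- function(pts) {
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(d))
}

polyline_length <- function(pts) {
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

# Resample a polyline at (approximately) regular arc-length steps.
resample_polyline <- function(pts, step) {
  s <- polyline_arc(pts)
  total <- s[length(s)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  n_out <- max(2L, floor(total / step) + 1L)
  s_new <- seq(0, total, length.out = n_out)
  cbind(approx(s, pts[, 1], xout = s_new)$y,
        approx(s, pts[, 2], xout = s_new)$y)
}

# Proper segment intersection test (shared endpoints excluded), vectorised over
# segment pairs. a1,a2,b1,b2: n x 2 matrices.
segments_cross <- function(a1, a2, b1, b2) {
  cross <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  d1 <- cross(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a1[, 1], a1[, 2])
  d2 <- cross(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a2[, 1], a2[, 2])
  d3 <- cross(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b1[, 1], b1[, 2])
  d4 <- cross(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b2[, 1], b2[, 2])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# TRUE if the polyline (optionally closed) intersects itself.
polyline_self_intersects <- function(pts, closed = FALSE) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  seg_a <- pts[-n, , drop = FALSE]
  seg_b <- pts[-1, , drop = FALSE]
  if (closed && !isTRUE(all.equal(pts[1, ], pts[n, ]))) {
    seg_a <- rbind(seg_a, pts[n, ])
    seg_b <- rbind(seg_b, pts[1, ])
  }
  m <- nrow(seg_a)
  idx <- which(outer(seq_len(m), seq_len(m), function(i, j) j > i + 1L), arr.ind = TRUE)
  # skip the wrap-around adjacency for closed curves
  if (closed) idx <- idx[!(idx[, 1] == 1L & idx[, 2] == m), , drop = FALSE]
  if (nrow(idx) == 0L) return(FALSE)
  any(segments_cross(seg_a[idx[, 1], , drop = FALSE], seg_b[idx[, 1], , drop = FALSE],
                     seg_a[idx[, 2], , drop = FALSE], seg_b[idx[, 2], , drop = FALSE]))
}

polylines_cross <- function(p, q) {
  np <- nrow(p); nq <- nrow(q)
  if (np < 2L || nq < 2L) return(FALSE)
  idx <- expand.grid(i = seq_len(np - 1L), j = seq_len(nq - 1L))
  any(segments_cross(p[idx$i, , drop = FALSE], p[idx$i + 1L, , drop = FALSE],
                     q[idx$j, , drop = FALSE], q[idx$j + 1L, , drop = FALSE]))
}

# Even-odd point-in-polygon, vectorised over query points. The closing edge
# is always appended: if first and last vertex coincide it has zero length
# and is a no-op, and if they differ only by floating fuzz, skipping it
# would leave a parity gap.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  poly <- rbind(poly, poly[1, ])
  n <- n + 1L
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n - 1L)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    x2 <- poly[k + 1L, 1]; y2 <- poly[k + 1L, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xin <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- xin > px[crosses]
      inside[crosses][hit] <- !inside[crosses][hit]
    }
  }
  inside
}

# Densify a polyline so consecutive samples are at most `step` apart.
densify_polyline <- function(pts, step = 0.25) {
  out <- vector("list", nrow(pts) - 1L)
  for (k in seq_len(nrow(pts) - 1L)) {
    d <- sqrt(sum((pts[k + 1L, ] - pts[k, ])^2))
    m <- max(1L, ceiling(d / step))
    tt <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    out[[k]] <- cbind(pts[k, 1] + tt * (pts[k + 1L, 1] - pts[k, 1]),
                      pts[k, 2] + tt * (pts[k + 1L, 2] - pts[k, 2]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), ])
}

# Minimum distance from each query point to a dense point sampling of a curve.
# Chunked to bound memory on large rims.
dist_to_curve <- function(px, py, curve_pts) {
  nq <- length(px)
  out <- numeric(nq)
  chunk <- max(1L, floor(4e6 / nrow(curve_pts)))
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    dx <- outer(px[s:e], curve_pts[, 1], "-")
    dy <- outer(py[s:e], curve_pts[, 2], "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1L, min))
  }
  out
}

# 3x3 min/max filters via shifted copies (border handled by replication).
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

minfilt3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- pmin(out, shift_mat(m, di, dj))
  }
  out
}

maxfilt3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- pmax(out, shift_mat(m, di, dj))
  }
  out
}

# Disc structuring element: pixels with centre distance <= r (px).
disc_brush <- function(r) {
  r <- max(0, r)
  k <- floor(r)
  ix <- -k:k
  d2 <- outer(ix^2, ix^2, "+")
  out <- (d2 <= r^2) * 1
  if (all(dim(out) == c(1L, 1L))) out[1, 1] <- 1
  out
}

#' Pixel indices of a rasterized disc
#'
#' Linear indices (into an `nr` x `nc` matrix) of the pixels whose centres lie
#' within distance `r` of `(row0, col0)`. Used for stamping grains into
#' simulated cell fields and for building disc fixtures; the same disc
#' definition is used for granulometry structuring elements, so rasterized
#' grains and sieves agree exactly.
#'
#' @param row0,col0 Disc centre (matrix coordinates, may be fractional).
#' @param r Radius, px.
#' @param nr,nc Matrix dimensions.
#' @return Integer vector of linear indices.
#' @export
stamp_disc_idx <- function(row0, col0, r, nr, nc) {
  k <- ceiling(r)
  rows <- (floor(row0) - k):(ceiling(row0) + k)
  cols <- (floor(col0) - k):(ceiling(col0) + k)
  rows <- rows[rows >= 1L & rows <= nr]
  cols <- cols[cols >= 1L & cols <= nc]
  if (!length(rows) || !length(cols)) return(integer(0))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  keep <- (rr - row0)^2 + (cc - col0)^2 <= r^2
  (cc[keep] - 1L) * nr + rr[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
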