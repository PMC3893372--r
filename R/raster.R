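#' Rasterize a cortical ribbon onto a labelled grid
#'
#' Discretises the region between the outer and inner contours onto a regular
#' grid, labelling each pixel `outside`, `grey`, `inner_boundary` (grey/white,
#' potential +1) or `outer_boundary` (pial, potential -1). Rim pixels (region
#' pixels adjacent to the outside) are assigned to whichever contour they lie
#' on; rim pixels far from both contours (the open ends of a gyral band) stay
#' grey and receive a zero-flux (insulating) condition in the solver.
#'
#' @param cp A [contour_pair()].
#' @param grid_spacing Grid spacing in px of the contour coordinate system
#'   (default 1; use 0.5 for a refined solve).
#' @param pad Padding around the bounding box, in grid cells.
#' @return A `grey_matter_grid`: list with `labels` (integer matrix, 0 =
#'   outside, 1 = grey, 2 = inner boundary, 3 = outer boundary), the grid
#'   origin `x0`, `y0` (px), `grid_spacing`, `pixel_size` and `slide_id`.
#' @export
rasterize_ribbon <- function(cp, grid_spacing = 1, pad = 2L) {
  stopifnot(inherits(cp, "contour_pair"))
  h <- grid_spacing
  outer_g <- cp$outer / h
  inner_g <- cp$inner / h

  all_pts <- rbind(outer_g, inner_g)
  x0 <- floor(min(all_pts[, 1])) - pad
  y0 <- floor(min(all_pts[, 2])) - pad
  nc <- ceiling(max(all_pts[, 1])) + pad - x0 + 1L
  nr <- ceiling(max(all_pts[, 2])) + pad - y0 + 1L

  # pixel centres in grid coordinates
  cx <- x0 + (seq_len(nc) - 1L)
  cy <- y0 + (seq_len(nr) - 1L)
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)

  if (cp$closed) {
    inside <- points_in_polygon(px, py, outer_g) &
      !points_in_polygon(px, py, inner_g)
  } else {
    poly <- rbind(outer_g, inner_g[rev(seq_len(nrow(inner_g))), , drop = FALSE])
    inside <- points_in_polygon(px, py, poly)
  }
  region <- matrix(inside, nr, nc)
  if (!any(region)) {
    abort("Rasterized ribbon is empty.", class = "fcdmap_empty_ribbon")
  }

  labels <- matrix(0L, nr, nc)
  labels[region] <- 1L

  # rim = region pixels 4-adjacent to outside (or the grid border)
  pad_reg <- matrix(FALSE, nr + 2L, nc + 2L)
  pad_reg[2:(nr + 1L), 2:(nc + 1L)] <- region
  nbr_out <- !pad_reg[1:nr, 2:(nc + 1L)] | !pad_reg[3:(nr + 2L), 2:(nc + 1L)] |
    !pad_reg[2:(nr + 1L), 1:nc] | !pad_reg[2:(nr + 1L), 3:(nc + 2L)]
  rim <- region & nbr_out
  rim_idx <- which(rim)
  dense_out <- densify_polyline(outer_g, 0.5)
  dense_in <- densify_polyline(inner_g, 0.5)
  if (length(rim_idx)) {
    rr <- ((rim_idx - 1L) %% nr) + 1L
    cc <- ((rim_idx - 1L) %/% nr) + 1L
    qx <- cx[cc]; qy <- cy[rr]
    d_out <- dist_to_curve(qx, qy, dense_out)
    d_in <- dist_to_curve(qx, qy, dense_in)
    thresh <- 1.5
    lab_rim <- ifelse(pmin(d_out, d_in) > thresh, 1L,
                      ifelse(d_in <= d_out, 2L, 3L))
    labels[rim_idx] <- lab_rim
  }
  # distance (grid units) from each boundary pixel centre to its contour;
  # used by the solver's sub-pixel Dirichlet correction
  rim_dist <- matrix(NA_real_, nr, nc)
  if (length(rim_idx)) {
    rim_dist[rim_idx] <- ifelse(labels[rim_idx] == 2L, d_in,
                                ifelse(labels[rim_idx] == 3L, d_out, NA_real_))
  }

  # densified contours in matrix (col = x, row = y) grid coordinates, used by
  # the field-line tracer to finish each trace exactly on the traced boundary
  to_grid_coords <- function(pts) {
    cbind(pts[, 1] - x0 + 1, pts[, 2] - y0 + 1)
  }
  grid <- structure(
    list(labels = labels, rim_dist = rim_dist, x0 = x0 * h, y0 = y0 * h,
         grid_spacing = h, pixel_size = cp$pixel_size, slide_id = cp$slide_id,
         closed = cp$closed,
         outer_curve = to_grid_coords(dense_out),
         inner_curve = to_grid_coords(dense_in)),
    class = "grey_matter_grid"
  )
  validate_grid(grid)
}

# Drop grey components not connected to both boundary families; error if
# nothing remains.
validate_grid <- function(grid) {
  labels <- grid$labels
  comp <- EBImage::bwlabel(labels > 0L)
  comp <- matrix(as.integer(comp), nrow(labels))
  keep <- logical(max(comp))
  for (k in seq_len(max(comp))) {
    labs_k <- labels[comp == k]
    keep[k] <- any(labs_k == 2L) && any(labs_k == 3L)
  }
  if (!any(keep)) {
    abort("No grey-matter component touches both boundaries (empty ribbon?).",
          class = "fcdmap_empty_ribbon")
  }
  if (!all(keep)) {
    drop <- comp > 0L & !keep[pmax(comp, 1L)]
    labels[drop] <- 0L
    grid$labels <- labels
    warn(sprintf("Dropped %d stray raster component(s) not linking both boundaries.",
                 sum(!keep)))
  }
  if (!any(grid$labels == 1L)) {
    abort("Ribbon has no grey interior (contours closer than the grid spacing?).",
          class = "fcdmap_empty_ribbon")
  }
  grid
}

#' @export
print.grey_matter_grid <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("outside", "grey", "inner", "outer")))
  cat(sprintf("<grey_matter_grid> %d x %d, spacing %.3g px (slide '%s')\n",
              nrow(x$labels), ncol(x$labels), x$grid_spacing, x$slide_id))
  print(tab)
  invisible(x)
}

# Convert matrix indices to contour-space px coordinates.
grid_to_px <- function(grid, row, col) {
  cbind(x = grid$x0 + (col - 1) * grid$grid_spacing,
        y = grid$y0 + (row - 1) * grid$grid_spacing)
}
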