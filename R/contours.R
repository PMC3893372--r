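#' Paired cortical contours for one section
#'
#' Bundles the manually traced outer (pial, lamina I/II) and inner (grey/white)
#' cortical boundaries of a single 2D section, together with the pixel size.
#' This is the source geometry for the Laplacian thickness computation.
#'
#' @param outer,inner Ordered point lists (n x 2 matrices or data frames with
#'   `x`, `y` columns) in pixel coordinates, y increasing downwards.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param slide_id Identifier for the section.
#' @param closed Are the contours closed curves? If `NULL`, inferred from
#'   whether first and last vertices coincide (within half a pixel).
#' @param validate Run geometric validation (simple curves that do not cross
#'   each other; for closed pairs, inner strictly inside outer). Validation is
#'   quadratic in vertex count; disable for very dense traces you trust.
#'
#' @return An object of class `contour_pair`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 120)
#' cp <- contour_pair(
#'   outer = cbind(100 + 70 * cos(th), 100 + 70 * sin(th)),
#'   inner = cbind(100 + 40 * cos(th), 100 + 40 * sin(th)),
#'   pixel_size = 10, slide_id = "demo"
#' )
#' cp
#' @export
contour_pair <- function(outer, inner, pixel_size, slide_id = "slide",
                         closed = NULL, validate = TRUE) {
  outer <- as_xy_matrix(outer, "outer")
  inner <- as_xy_matrix(inner, "inner")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/px).",
          class = "fcdmap_invalid_geometry")
  }
  if (is.null(closed)) {
    eps <- 0.5
    closed <- sqrt(sum((outer[1, ] - outer[nrow(outer), ])^2)) < eps &&
      sqrt(sum((inner[1, ] - inner[nrow(inner), ])^2)) < eps
  }
  if (validate) {
    if (polyline_self_intersects(outer, closed) ||
        polyline_self_intersects(inner, closed)) {
      abort("Contours must be simple (non-self-intersecting) curves.",
            class = "fcdmap_invalid_geometry")
    }
    if (polylines_cross(outer, inner)) {
      abort("Outer and inner contours must not cross each other.",
            class = "fcdmap_invalid_geometry")
    }
    if (closed) {
      # pull test points a hair toward the inner centroid: vertices of the
      # two contours often share exact coordinates (e.g. equal angular
      # sampling), which degenerates the even-odd ray test
      cen <- colMeans(inner)
      eps <- 1e-6
      px <- inner[, 1] * (1 - eps) + cen[1] * eps
      py <- inner[, 2] * (1 - eps) + cen[2] * eps
      if (!all(points_in_polygon(px, py, outer))) {
        abort("For closed contours the inner boundary must lie inside the outer boundary (contours swapped?).",
              class = "fcdmap_invalid_geometry")
      }
    }
  }
  structure(
    list(outer = outer, inner = inner, pixel_size = pixel_size,
         slide_id = slide_id, closed = closed),
    class = "contour_pair"
  )
}

#' @export
print.contour_pair <- function(x, ...) {
  cat(sprintf(
    "<contour_pair> slide '%s': outer %d pts, inner %d pts, %s, %.3g um/px\n",
    x$slide_id, nrow(x$outer), nrow(x$inner),
    if (x$closed) "closed" else "open", x$pixel_size
  ))
  invisible(x)
}

#' Write and read contour pairs as CSV + JSON sidecar
#'
#' The on-disk dialect is a CSV with columns `contour_id` (`outer`/`inner`),
#' `vertex_index`, `x_px`, `y_px`, plus a JSON sidecar (same path with
#' extension `.json`) holding `pixel_size_um`, `slide_id` and optionally
#' `y_mm`. Phantoms are written in the same format the analysis reads, so
#' tests exercise the I/O layer as well.
#'
#' @param cp A [contour_pair()].
#' @param path Path of the CSV file to write / read.
#' @param y_mm Optional stereotaxic position stored in the sidecar.
#' @return `write_contours()` returns `path` invisibly; `read_contours()`
#'   returns a [contour_pair()].
#' @export
write_contours <- function(cp, path, y_mm = NULL) {
  stopifnot(inherits(cp, "contour_pair"))
  df <- dplyr::bind_rows(
    tibble(contour_id = "outer", vertex_index = seq_len(nrow(cp$outer)),
           x_px = cp$outer[, 1], y_px = cp$outer[, 2]),
    tibble(contour_id = "inner", vertex_index = seq_len(nrow(cp$inner)),
           x_px = cp$inner[, 1], y_px = cp$inner[, 2])
  )
  readr::write_csv(df, path)
  side <- list(pixel_size_um = cp$pixel_size, slide_id = cp$slide_id,
               closed = cp$closed)
  if (!is.null(y_mm)) side$y_mm <- y_mm
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pick <- function(id) {
    sub <- df[df$contour_id == id, , drop = FALSE]
    sub <- sub[order(sub$vertex_index), , drop = FALSE]
    cbind(sub$x_px, sub$y_px)
  }
  contour_pair(pick("outer"), pick("inner"),
               pixel_size = side$pixel_size_um,
               slide_id = side$slide_id %||% "slide",
               closed = side$closed %||% NULL)
}

sidecar_path <- function(path) {
  sub("\\.[^.]+$", ".json", path)
}
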