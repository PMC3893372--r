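#' Assign normalized anterior-posterior coordinates to a slide series
#'
#' Positions coronal slides in a normalized stereotaxic space anchored at
#' three landmarks: the frontal pole at y = +73 mm, the slide containing the
#' anterior commissure at y = 0, and the occipital pole at y = -106 mm.
#' Intermediate slides are interpolated linearly in slide index on the two
#' landmark segments.
#'
#' @param series A data frame with columns `slide_id`, `slide_index` (ordered
#'   anterior to posterior) and `landmark` (one of `"frontal_pole"`, `"AC"`,
#'   `"occipital_pole"`, or `NA`/`""` for ordinary slides). Extra columns are
#'   carried through.
#' @param spacing_mm Nominal physical inter-slide spacing used for a
#'   consistency warning (sections cut 1.2 mm apart); set `NULL` to skip.
#' @return The input tibble with a `y_mm` column added, ordered anterior to
#'   posterior (`y_mm` strictly decreasing).
#' @examples
#' series <- tibble::tibble(
#'   slide_id = paste0("s", 1:9), slide_index = 1:9,
#'   landmark = c("frontal_pole", NA, NA, NA, "AC", NA, NA, NA,
#'                "occipital_pole")
#' )
#' assign_y(series)
#' @export
assign_y <- function(series, spacing_mm = 1.2) {
  series <- as_tibble(series)
  req <- c("slide_id", "slide_index", "landmark")
  if (!all(req %in% names(series))) {
    abort(paste("`series` needs columns:", paste(req, collapse = ", ")),
          class = "fcdmap_bad_argument")
  }
  lm_col <- as.character(series$landmark)
  lm_col[is.na(lm_col)] <- ""
  anchors <- c(frontal_pole = 73, AC = 0, occipital_pole = -106)
  idx <- vapply(names(anchors), function(l) {
    w <- which(lm_col == l)
    if (length(w) != 1L) NA_integer_ else w
  }, 1L)
  if (anyNA(idx)) {
    missing <- names(anchors)[is.na(idx)]
    abort(paste("Missing or duplicated landmark(s):",
                paste(missing, collapse = ", ")),
          class = "fcdmap_landmark_missing")
  }
  li <- series$slide_index[idx]
  if (!(li[1] <= li[2] && li[2] <= li[3])) {
    abort("Landmarks out of order: need frontal_pole <= AC <= occipital_pole in slide index.",
          class = "fcdmap_landmark_order")
  }
  series$y_mm <- approx(x = li, y = anchors, xout = series$slide_index,
                        rule = 2, ties = "ordered")$y
  if (!is.null(spacing_mm)) {
    implied <- c(73 / max(li[2] - li[1], 1L), 106 / max(li[3] - li[2], 1L))
    off <- abs(implied - spacing_mm) / spacing_mm
    if (any(off > 0.25)) {
      warn(sprintf(
        "Implied inter-slide spacing (%.2f / %.2f mm) deviates > 25%% from nominal %.2f mm.",
        implied[1], implied[2], spacing_mm))
    }
  }
  dplyr::arrange(series, dplyr::desc(.data$y_mm))
}

#' Match case slides to control slides by stereotaxic position
#'
#' Pairs each case slide with the control slide nearest in normalized y;
#' pairs farther apart than `max_dy` are dropped. Ties break toward the more
#' anterior (larger y) control slide so output is deterministic.
#'
#' @param case,control Data frames with columns `slide_id` and `y_mm` (e.g.
#'   from [assign_y()]).
#' @param max_dy Maximum |y difference| in mm for an accepted pair (default
#'   one nominal inter-slide spacing, 1.2 mm).
#' @return Tibble with `case_id`, `control_id`, `y_case`, `y_control`, `dy`
#'   (case minus control, mm); dropped case slides are absent.
#' @export
match_slides <- function(case, control, max_dy = 1.2) {
  case <- as_tibble(case); control <- as_tibble(control)
  if (!nrow(case) || !nrow(control)) {
    abort("`case` and `control` must be nonempty.", class = "fcdmap_bad_argument")
  }
  ord <- order(-control$y_mm) # anterior first for deterministic ties
  ctrl <- control[ord, , drop = FALSE]
  res <- purrr::map(seq_len(nrow(case)), function(i) {
    d <- abs(ctrl$y_mm - case$y_mm[i])
    j <- which.min(d) # first minimum = most anterior on ties
    tibble(case_id = case$slide_id[i],
           control_id = ctrl$slide_id[j],
           y_case = case$y_mm[i],
           y_control = ctrl$y_mm[j],
           dy = case$y_mm[i] - ctrl$y_mm[j])
  })
  out <- dplyr::bind_rows(res)
  dropped <- abs(out$dy) > max_dy
  if (any(dropped)) {
    warn(sprintf("Dropped %d pairing(s) with |dy| > %.2f mm: %s",
                 sum(dropped), max_dy,
                 paste(out$case_id[dropped], collapse = ", ")))
  }
  out[!dropped, , drop = FALSE]
}
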