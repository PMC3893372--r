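#' Flag candidate dysplastic regions below the control fence
#'
#' Identifies maximal contiguous midline runs where case thickness falls
#' below the matched control slide's lower fence, discarding runs shorter
#' than `min_len_um` of arc. Each region carries its mean thickness and mean
#' curvature. Runs are computed within contour pieces, so region intervals
#' never jump across disconnected midline segments; the result is invariant
#' to reversing the sampling direction.
#'
#' @param case_profile A `midline_profile` tibble (case slide).
#' @param control_fences A `fence_result` computed from the y-matched control
#'   slide's thickness sample.
#' @param min_len_um Minimum region arc length, um (default 1000; field lines
#'   are reported at millimetre spacing so sub-millimetre runs are noise).
#' @return Tibble with one row per region: `slide_id`, `piece`, `s_start`,
#'   `s_end`, `length_um`, `n_samples`, `mean_t`, `mean_kappa`. Zero rows if
#'   nothing falls below the fence.
#' @export
flag_thin_regions <- function(case_profile, control_fences, min_len_um = 1000) {
  stopifnot(inherits(control_fences, "fence_result"))
  prof <- as_tibble(case_profile)
  if (!nrow(prof)) return(empty_regions())
  if (!"piece" %in% names(prof)) prof$piece <- 1L
  lf <- control_fences$lower_fence

  out <- prof |>
    dplyr::group_by(.data$slide_id, .data$piece) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$arc_s_um), , drop = FALSE]
      below <- d$t_um < lf
      if (!any(below)) return(empty_regions()[, c("s_start", "s_end", "length_um",
                                                  "n_samples", "mean_t", "mean_kappa")])
      r <- rle(below)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      step <- median(diff(d$arc_s_um))
      runs <- which(r$values)
      res <- purrr::map(runs, function(k) {
        i0 <- starts[k]; i1 <- ends[k]
        tibble(
          s_start = d$arc_s_um[i0] - step / 2,
          s_end = d$arc_s_um[i1] + step / 2,
          length_um = (i1 - i0 + 1L) * step,
          n_samples = i1 - i0 + 1L,
          mean_t = mean(d$t_um[i0:i1]),
          mean_kappa = mean(d$kappa_per_mm[i0:i1])
        )
      })
      dplyr::bind_rows(res)
    }) |>
    dplyr::ungroup()
  out <- out[out$length_um >= min_len_um, , drop = FALSE]
  out
}

empty_regions <- function() {
  tibble(slide_id = character(), piece = integer(), s_start = numeric(),
         s_end = numeric(), length_um = numeric(), n_samples = integer(),
         mean_t = numeric(), mean_kappa = numeric())
}

#' Mean midline thickness per slide
#'
#' Unweighted mean of midline thickness samples per slide, optionally joined
#' with slide positions and pair/group metadata for a position-vs-thickness
#' plot across a cohort.
#'
#' @param profiles One `midline_profile` or a tibble of row-bound profiles
#'   (multiple slides distinguished by `slide_id`).
#' @param positions Optional tibble with `slide_id` and `y_mm` (and any of
#'   `pair_id`, `group`) to join.
#' @return Tibble with `slide_id`, `n_samples`, `mean_t` (um) and any joined
#'   metadata, one row per slide.
#' @export
mean_thickness_by_slide <- function(profiles, positions = NULL) {
  res <- as_tibble(profiles) |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::summarise(n_samples = dplyr::n(), mean_t = mean(.data$t_um),
                     .groups = "drop")
  if (!is.null(positions)) {
    res <- dplyr::left_join(res, as_tibble(positions), by = "slide_id")
    if ("y_mm" %in% names(res)) res <- dplyr::arrange(res, dplyr::desc(.data$y_mm))
  }
  res
}

#' Thickness difference by position and curvature
#'
#' Bins midline samples from matched case and control slides on a
#' (stereotaxic y) x (curvature) grid and reports the mean case-minus-control
#' thickness difference per bin. Bins with fewer than `n_min` samples in
#' either group are masked (`delta_t = NA`).
#'
#' @param samples Tibble of midline samples across the cohort with columns
#'   `group` (`"case"`/`"control"`), `y_mm`, `kappa_per_mm`, `t_um`.
#' @param y_breaks,kappa_breaks Bin edges (defaults: 10 mm steps spanning
#'   -106..73; curvature edges at -Inf, -0.2, 0.2, Inf per mm, i.e. sulcus /
#'   flat / crest).
#' @param n_min Minimum per-group samples for a bin to be reported.
#' @return Tibble of class `delta_t_map` with bin indices, bin centres
#'   `y_mid`, `kappa_mid`, counts `n_case`, `n_control` and `delta_t` (um).
#' @export
position_curvature_map <- function(samples,
                                   y_breaks = seq(-110, 75, by = 10),
                                   kappa_breaks = c(-Inf, -0.2, 0.2, Inf),
                                   n_min = 10L) {
  samples <- as_tibble(samples)
  req <- c("group", "y_mm", "kappa_per_mm", "t_um")
  if (!all(req %in% names(samples))) {
    abort(paste("`samples` needs columns:", paste(req, collapse = ", ")),
          class = "fcdmap_bad_argument")
  }
  samples <- samples |>
    mutate(
      y_bin = cut(.data$y_mm, y_breaks, include.lowest = TRUE),
      kappa_bin = cut(.data$kappa_per_mm, kappa_breaks, include.lowest = TRUE)
    ) |>
    filter(!is.na(.data$y_bin), !is.na(.data$kappa_bin))
  agg <- samples |>
    dplyr::group_by(.data$y_bin, .data$kappa_bin, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_t = mean(.data$t_um),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("n", "mean_t"),
                       values_fill = list(n = 0L))
  for (col in c("n_case", "n_control")) {
    if (!col %in% names(agg)) agg[[col]] <- 0L
    agg[[col]][is.na(agg[[col]])] <- 0L
  }
  for (col in c("mean_t_case", "mean_t_control")) {
    if (!col %in% names(agg)) agg[[col]] <- NA_real_
  }
  out <- agg |>
    mutate(
      delta_t = ifelse(.data$n_case >= n_min & .data$n_control >= n_min,
                       .data$mean_t_case - .data$mean_t_control, NA_real_),
      y_mid = bin_mid(.data$y_bin),
      kappa_mid = bin_mid(.data$kappa_bin)
    ) |>
    select("y_bin", "kappa_bin", "y_mid", "kappa_mid",
           "n_case", "n_control", "delta_t")
  class(out) <- c("delta_t_map", class(out))
  out
}

bin_mid <- function(f) {
  lab <- as.character(f)
  lo <- as.numeric(sub("^[\\[(]([^,]+),.*$", "\\1", lab))
  hi <- as.numeric(sub("^.*,([^]\\)]+)[]\\)]$", "\\1", lab))
  m <- (lo + hi) / 2
  m[!is.finite(m)] <- ifelse(is.finite(lo[!is.finite(m)]),
                             lo[!is.finite(m)], hi[!is.finite(m)])
  m
}
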