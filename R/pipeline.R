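#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()]. All
#' numeric parameters are in the units stated; the configuration round-trips
#' losslessly through YAML via [write_config()] / [read_config()].
#'
#' @param pixel_size_slide um/px of the slide-scale contour tracings.
#' @param pixel_size_cell um/px of high-resolution cell crops.
#' @param grid_spacing Raster grid spacing, px.
#' @param solver_tol Laplace residual tolerance.
#' @param sample_step_um Midline sampling step, um.
#' @param curvature_window_um Curvature fitting window, um.
#' @param trim_um Arc trimmed from open midline ends, um.
#' @param fence_variant `"adjusted"` or `"tukey"`.
#' @param min_region_um Minimum flagged-region length, um.
#' @param max_dy_mm Maximum slide-matching distance, mm.
#' @param seed Base seed for any stochastic stages.
#' @param segmentation Named list of [segment_neurons()] arguments.
#' @param se_sizes_um Granulometry structuring-element radii, um.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_slide = 100,
                            pixel_size_cell = 0.74,
                            grid_spacing = 1,
                            solver_tol = 1e-6,
                            sample_step_um = 1000,
                            curvature_window_um = 2000,
                            trim_um = 2000,
                            fence_variant = "adjusted",
                            min_region_um = 1000,
                            max_dy_mm = 1.2,
                            seed = 0L,
                            segmentation = list(),
                            se_sizes_um = seq(0, 30, by = 0.74)) {
  # numerics normalised to double and rounded to 9 decimals (seed to
  # integer) so the configuration and its hash survive a YAML round trip
  # exactly
  num <- function(x) round(as.numeric(x), 9)
  cfg <- list(
    pixel_size_slide = num(pixel_size_slide),
    pixel_size_cell = num(pixel_size_cell),
    grid_spacing = num(grid_spacing),
    solver_tol = num(solver_tol),
    sample_step_um = num(sample_step_um),
    curvature_window_um = num(curvature_window_um),
    trim_um = num(trim_um),
    fence_variant = as.character(fence_variant),
    min_region_um = num(min_region_um),
    max_dy_mm = num(max_dy_mm),
    seed = as.integer(seed),
    segmentation = segmentation,
    se_sizes_um = num(se_sizes_um)
  )
  stopifnot(
    cfg$pixel_size_slide > 0, cfg$pixel_size_cell > 0,
    cfg$grid_spacing > 0, cfg$solver_tol > 0, cfg$sample_step_um > 0,
    cfg$min_region_um >= 0, cfg$max_dy_mm > 0,
    cfg$fence_variant %in% c("adjusted", "tukey")
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the thickness-screening pipeline over a cohort
#'
#' End-to-end composition of the section-scale stages: per-slide Laplacian
#' thickness profiles, stereotaxic positioning, case/control slide matching,
#' control-fence estimation, sub-fence region flagging, and the cohort
#' summary tables (mean thickness per slide; thickness difference by
#' position and curvature).
#'
#' @param manifest Tibble with one row per slide: `slide_id`, `group`
#'   (`"case"`/`"control"`), `pair` (integer pair index), `slide_index`,
#'   `landmark` (landmark name or `NA`), `contour_file` (path to a contour
#'   CSV as written by [write_contours()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV together with a JSON run record (config, hash).
#' @return A list of class `fcd_report`: `profiles`, `positions`, `matches`,
#'   `fences`, `regions`, `mean_t`, `delta_map`, `config`, `config_hash`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  manifest <- as_tibble(manifest)
  req <- c("slide_id", "group", "pair", "slide_index", "landmark",
           "contour_file")
  if (!all(req %in% names(manifest))) {
    abort(paste("Manifest needs columns:", paste(req, collapse = ", ")),
          class = "fcdmap_bad_argument")
  }
  missing <- manifest$contour_file[!file.exists(manifest$contour_file)]
  if (length(missing)) {
    abort(paste0("Missing contour file(s): ",
                 paste(missing, collapse = ", ")),
          class = "fcdmap_missing_file")
  }

  # stage 1: thickness profiles per slide
  profiles <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cp <- read_contours(row$contour_file)
    cp$slide_id <- row$slide_id
    field <- tryCatch(
      solve_laplace(rasterize_ribbon(cp, grid_spacing = config$grid_spacing),
                    tol = config$solver_tol),
      error = function(e) {
        abort(sprintf("Stage thickness failed on slide '%s': %s",
                      row$slide_id, conditionMessage(e)),
              class = "fcdmap_stage_failure")
      })
    midline_profile(field, sample_step = config$sample_step_um,
                    curvature_window = config$curvature_window_um,
                    trim_um = config$trim_um)
  }) |> dplyr::bind_rows()

  # stage 2: stereotaxic positions per donor, then case-control matching
  positions <- manifest |>
    dplyr::group_by(.data$group, .data$pair) |>
    dplyr::group_modify(~ assign_y(.x, spacing_mm = NULL)) |>
    dplyr::ungroup() |>
    select("slide_id", "group", "pair", "y_mm")
  matches <- positions |>
    dplyr::group_by(.data$pair) |>
    dplyr::group_modify(function(d, key) {
      match_slides(d[d$group == "case", ], d[d$group == "control", ],
                   max_dy = config$max_dy_mm)
    }) |>
    dplyr::ungroup()

  # stage 3: control fences and flagged case regions per matched slide pair
  fence_rows <- list(); region_rows <- list()
  for (i in seq_len(nrow(matches))) {
    mt <- matches[i, ]
    ctrl_t <- profiles$t_um[profiles$slide_id == mt$control_id]
    fr <- tryCatch(
      adjusted_fences(ctrl_t, variant = config$fence_variant),
      error = function(e) NULL)
    if (is.null(fr)) next
    fence_rows[[i]] <- dplyr::bind_cols(
      tibble(pair = mt$pair, case_id = mt$case_id,
             control_id = mt$control_id), tidy(fr))
    case_prof <- profiles[profiles$slide_id == mt$case_id, ]
    region_rows[[i]] <- flag_thin_regions(case_prof, fr,
                                          min_len_um = config$min_region_um)
  }
  fences <- dplyr::bind_rows(fence_rows)
  regions <- dplyr::bind_rows(region_rows)
  if (!nrow(regions)) regions <- empty_regions()

  # stage 4: cohort summaries
  mean_t <- mean_thickness_by_slide(profiles, positions)
  samples <- profiles |>
    dplyr::left_join(positions, by = "slide_id")
  delta_map <- position_curvature_map(samples)

  report <- structure(
    list(profiles = profiles, positions = positions, matches = matches,
         fences = fences, regions = regions, mean_t = mean_t,
         delta_map = delta_map, config = config,
         config_hash = config_hash(config)),
    class = "fcd_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fcd_report <- function(x, ...) {
  cat(sprintf(
    "<fcd_report> %d slides, %d matched pairs, %d flagged region(s)\n  config %s\n",
    dplyr::n_distinct(x$profiles$slide_id), nrow(x$matches),
    nrow(x$regions), x$config_hash))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("profiles", "positions", "matches", "fences", "regions",
            "mean_t", "delta_map")
  for (nm in tabs) {
    df <- as_tibble(report[[nm]])
    df$config_hash <- report$config_hash
    readr::write_csv(df, file.path(out_dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(
    list(config = unclass(report$config), config_hash = report$config_hash,
         n_slides = dplyr::n_distinct(report$profiles$slide_id),
         n_regions = nrow(report$regions)),
    file.path(out_dir, "run_record.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
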