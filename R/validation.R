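# Seeded validation experiments for the screening stage. These are the
# package's own calibration checks: they exercise the full phantom ->
# thickness -> fence -> flag path and report recovery metrics against the
# phantom ground truth.

#' Focus recovery experiment on a matched phantom pair
#'
#' Builds a [make_phantom_pair()] twin, runs both ribbons through the
#' Laplacian thickness pipeline, estimates fences from the control twin and
#' flags sub-fence runs in the case twin, then scores the flagged arc
#' intervals against the implanted focus by interval Jaccard overlap. The
#' ground-truth interval is the full support of the implanted perturbation,
#' i.e. the focus plus its entry/exit tapers, since the tapered shoulders
#' are genuinely thinned tissue.
#'
#' @param seed Integer seed for the phantom pair.
#' @param focus_multiplier,focus_len_um Focus parameters, see
#'   [make_phantom_pair()].
#' @param sample_step_um Midline sampling step, um. Scoring a 4 mm interval
#'   by Jaccard overlap needs interval resolution well below the focus
#'   length, hence the fine default.
#' @param trim_um Arc trimmed at the open ribbon ends, um.
#' @param min_len_um Minimum flagged-region length, um.
#' @return One-row tibble: `seed`, `n_regions`, `jaccard` (implanted focus
#'   interval vs union of flagged intervals).
#' @export
focus_recovery_experiment <- function(seed, focus_multiplier = 0.7,
                                      focus_len_um = 4000,
                                      sample_step_um = 250,
                                      trim_um = 3000, min_len_um = 1000) {
  pp <- make_phantom_pair(seed, focus_multiplier = focus_multiplier,
                          focus_len_um = focus_len_um)
  prof_case <- midline_profile(
    solve_laplace(rasterize_ribbon(pp$case$contour_pair)),
    sample_step = sample_step_um, trim_um = trim_um)
  prof_ctrl <- midline_profile(
    solve_laplace(rasterize_ribbon(pp$control$contour_pair)),
    sample_step = sample_step_um, trim_um = trim_um)
  fences <- adjusted_fences(prof_ctrl$t_um)
  regions <- flag_thin_regions(prof_case, fences, min_len_um = min_len_um)
  taper <- formals(make_phantom_pair)$taper_um
  truth_lo <- pp$focus$s_start - taper
  truth_hi <- pp$focus$s_end + taper
  if (!nrow(regions)) {
    return(tibble(seed = seed, n_regions = 0L, jaccard = 0))
  }
  inter <- sum(pmax(0, pmin(regions$s_end, truth_hi) -
                      pmax(regions$s_start, truth_lo)))
  union <- (truth_hi - truth_lo) +
    sum(regions$s_end - regions$s_start) - inter
  tibble(seed = seed, n_regions = nrow(regions), jaccard = inter / union)
}

#' Null-cohort false-flag calibration
#'
#' Takes one phantom ribbon, treats its midline thickness sample as the
#' control, adds i.i.d. Gaussian measurement noise to form a null "case"
#' (no focus), and reports the fraction of arc length flagged below the
#' control fence. Under a calibrated fence rule this stays small.
#'
#' @param seed Integer seed.
#' @param noise_sd_um Measurement noise added to the case thickness, um.
#' @param sample_step_um,trim_um,min_len_um As in
#'   [focus_recovery_experiment()]. The default `min_len_um` is the
#'   screening rule's own region-length floor: flagged regions carry a
#'   minimum length by definition, so isolated single-sample noise dips do
#'   not count as flagged arc.
#' @return One-row tibble: `seed`, `flagged_fraction` (flagged arc length /
#'   total arc length).
#' @export
null_flag_fraction <- function(seed, noise_sd_um = 20,
                               sample_step_um = 500, trim_um = 3000,
                               min_len_um = 1000) {
  pp <- make_phantom_pair(seed, focus_multiplier = 1, focus_len_um = 4000)
  prof <- midline_profile(
    solve_laplace(rasterize_ribbon(pp$control$contour_pair)),
    sample_step = sample_step_um, trim_um = trim_um)
  fences <- adjusted_fences(prof$t_um)
  case_prof <- prof
  case_prof$t_um <- with_seed(seed + 1000L, {
    prof$t_um + rnorm(nrow(prof), 0, noise_sd_um)
  })
  regions <- flag_thin_regions(case_prof, fences, min_len_um = min_len_um)
  total <- max(prof$arc_s_um) - min(prof$arc_s_um)
  tibble(seed = seed,
         flagged_fraction = sum(regions$length_um) / total)
}

#' Segmentation recovery experiment on a simulated cell field
#'
#' Simulates a field of disjoint noisy cells ([simulate_cell_field()]), runs
#' the full three-step segmentation and scores it against the ground truth:
#' recovered object count and mean per-cell Dice overlap (each true cell
#' matched to the label with which it overlaps most).
#'
#' @param seed Integer seed.
#' @param n_cells,radius,window,noise_sd Field parameters, see
#'   [simulate_cell_field()].
#' @return One-row tibble: `seed`, `n_objects`, `mean_dice`.
#' @export
segmentation_recovery_experiment <- function(seed, n_cells = 50, radius = 6,
                                             window = c(400, 400),
                                             noise_sd = 10) {
  sim <- simulate_cell_field(n_cells, radius = radius, window = window,
                             noise_sd = noise_sd, seed = seed)
  labs <- segment_neurons(sim$image, pixel_size = 1, min_area_um2 = 20)
  truth <- sim$truth_labels
  dice <- vapply(seq_len(n_cells), function(k) {
    tk <- truth == k
    ov <- labs[tk]
    ov <- ov[ov > 0]
    if (!length(ov)) return(0)
    best <- as.integer(names(which.max(table(ov))))
    lk <- labs == best
    2 * sum(tk & lk) / (sum(tk) + sum(lk))
  }, 1)
  tibble(seed = seed, n_objects = attr(labs, "n_objects"),
         mean_dice = mean(dice))
}

#' Boolean parameter recovery experiment
#'
#' Simulates a Boolean disc field at known parameters, thresholds it at the
#' intensity midpoint and fits the germ-grain model, reporting estimates
#' alongside the simulation truth.
#'
#' @param seed Integer seed.
#' @param lambda_true Germ intensity, 1/px^2.
#' @param radius Disc radius, px.
#' @param window Window size, px.
#' @param noise_sd Image noise sd.
#' @return One-row tibble with estimates (`lambda_hat`, `a_bar`, `u_bar`) and
#'   truths (`lambda_true`, `a_true`, `u_true`).
#' @export
boolean_recovery_experiment <- function(seed, lambda_true = 0.005,
                                        radius = 6, window = c(1000, 1000),
                                        noise_sd = 0) {
  sim <- simulate_boolean_field(lambda_true, list(radius = radius), window,
                                noise_sd = noise_sd, seed = seed)
  mask <- sim$image < 130
  fit <- tidy(fit_boolean(mask))
  dplyr::bind_cols(tibble(seed = seed), fit,
                   tibble(lambda_true = lambda_true,
                          a_true = pi * radius^2,
                          u_true = 2 * pi * radius))
}
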