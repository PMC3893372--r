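#' Parse a donor cohort table into a paired manifest
#'
#' Reads a cohort table of tissue donors (columns `atp_case`, `age`, `sex`,
#' `seizures`, `group`, `pair`) and returns a validated, paired manifest.
#' Ages recorded with a trailing dash (archival shorthand for an unknown
#' decimal, e.g. `"13.-"`) parse as `.0` and are flagged in `age_imputed`.
#' Every pair index must appear exactly once per group.
#'
#' The packaged example table is at
#' `system.file("extdata", "table1_cohort.csv", package = "fcdmap")`:
#' 7 ASD donors and 7 age/sex-matched neurotypical controls.
#'
#' @param table Path to a CSV file, or a data frame.
#' @return Tibble of class `cohort_manifest` with `atp_case`, `age` (years),
#'   `age_imputed`, `sex`, `seizures` (logical), `group` (`"asd"` /
#'   `"control"`), `pair`. Use [glance()] for cohort summary statistics.
#' @examples
#' path <- system.file("extdata", "table1_cohort.csv", package = "fcdmap")
#' cohort <- parse_cohort_table(path)
#' glance(cohort)
#' @export
parse_cohort_table <- function(table) {
  df <- if (is.character(table)) {
    readr::read_csv(table, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    as_tibble(table) |> mutate(across(dplyr::everything(), as.character))
  }
  req <- c("atp_case", "age", "sex", "seizures", "group", "pair")
  if (!all(req %in% names(df))) {
    abort(paste("Cohort table needs columns:", paste(req, collapse = ", ")),
          class = "fcdmap_bad_argument")
  }
  age_raw <- trimws(df$age)
  dash <- grepl("\\.[-–]$", age_raw)
  age <- suppressWarnings(as.numeric(sub("[-–]$", "0", age_raw)))
  if (anyNA(age)) {
    abort(sprintf("Unparseable age value(s): %s",
                  paste(age_raw[is.na(age)], collapse = ", ")),
          class = "fcdmap_bad_argument")
  }
  out <- tibble(
    atp_case = df$atp_case,
    age = age,
    age_imputed = dash,
    sex = toupper(df$sex),
    seizures = toupper(trimws(df$seizures)) %in% c("Y", "YES", "TRUE", "1"),
    group = tolower(df$group),
    pair = as.integer(df$pair)
  )
  if (!all(out$group %in% c("asd", "control"))) {
    abort("`group` must be 'asd' or 'control'.", class = "fcdmap_bad_argument")
  }
  counts <- table(out$group, out$pair)
  if (!all(counts == 1L)) {
    abort("Unpaired rows: every pair index must appear exactly once per group.",
          class = "fcdmap_pairing_error")
  }
  class(out) <- c("cohort_manifest", class(out))
  out
}

#' @describeIn parse_cohort_table Cohort summary: donor counts, the maximum
#'   within-pair age gap, and seizure counts by group.
#' @param x A `cohort_manifest`.
#' @param ... Unused.
#' @export
glance.cohort_manifest <- function(x, ...) {
  wide <- as_tibble(x) |>
    select("pair", "group", "age") |>
    tidyr::pivot_wider(names_from = "group", values_from = "age")
  tibble(
    n_asd = sum(x$group == "asd"),
    n_control = sum(x$group == "control"),
    max_pair_age_gap = max(abs(wide$asd - wide$control)),
    seizures_asd = sum(x$seizures & x$group == "asd"),
    seizures_control = sum(x$seizures & x$group == "control"),
    n_age_imputed = sum(x$age_imputed)
  )
}
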