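#' Gwet's AC1 chance-corrected agreement
#'
#' Computes Gwet's first-order agreement coefficient between two raters:
#' `AC1 = (Pa - Pe) / (1 - Pe)`, where `Pa` is the observed fraction of
#' identically labelled items and the chance agreement is
#' `Pe = (1/(K-1)) * sum_k q_k (1 - q_k)` with `q_k` the mean marginal
#' proportion of category k across the two raters. Unlike Cohen's kappa, AC1
#' is stable under strong prevalence imbalance (the usual situation for
#' grey-matter masks, where most pixels are background). Pairwise only;
#' multi-rater sets are summarised by [rater_agreement()].
#'
#' @param labels_a,labels_b Equal-length vectors (or matrices, e.g. rasterized
#'   tracings) of categorical ratings.
#' @param categories Label universe; defaults to the values observed in
#'   either rater. Must have at least 2 categories.
#' @return A `gwet_ac1` list: `ac1`, `pa`, `pe`, `n_items`, `n_categories`.
#' @examples
#' a <- rep(c(1, 1, 1, 0), c(40, 10, 0, 50))
#' b <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
#' gwet_ac1(a, b)$ac1  # 0.6
#' @export
gwet_ac1 <- function(labels_a, labels_b, categories = NULL) {
  a <- as.vector(labels_a); b <- as.vector(labels_b)
  if (length(a) != length(b) || !length(a)) {
    abort("Raters must label the same nonempty item set.",
          class = "fcdmap_bad_argument")
  }
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  if (length(categories) < 2L) {
    abort("Need at least 2 categories in the label universe.",
          class = "fcdmap_bad_argument")
  }
  k <- length(categories)
  n <- length(a)
  pa <- mean(a == b)
  q <- (tabulate(match(a, categories), k) +
          tabulate(match(b, categories), k)) / (2 * n)
  pe <- sum(q * (1 - q)) / (k - 1)
  if (pe >= 1) {
    abort("Degenerate marginals (Pe = 1); AC1 undefined.",
          class = "fcdmap_undefined_coefficient")
  }
  structure(
    list(ac1 = (pa - pe) / (1 - pe), pa = pa, pe = pe,
         n_items = n, n_categories = k),
    class = "gwet_ac1"
  )
}

#' @export
print.gwet_ac1 <- function(x, ...) {
  cat(sprintf("<gwet_ac1> AC1 = %.4f (Pa = %.4f, Pe = %.4f, n = %d)\n",
              x$ac1, x$pa, x$pe, x$n_items))
  invisible(x)
}

#' @describeIn gwet_ac1 Coefficient components as a one-row tibble.
#' @param x A `gwet_ac1`.
#' @param ... Unused.
#' @export
tidy.gwet_ac1 <- function(x, ...) {
  tibble(ac1 = x$ac1, pa = x$pa, pe = x$pe, n_items = x$n_items,
         n_categories = x$n_categories)
}

#' Pairwise AC1 over several raters' masks
#'
#' Inter-rater reliability for two or more rasterized tracings of the same
#' section: AC1 for every rater pair plus their mean. The pooling across
#' pairs is reported explicitly (per-pair rows and a mean) rather than as a
#' single opaque number.
#'
#' @param masks Named list (>= 2) of equal-sized label matrices or vectors.
#' @param categories Optional label universe passed to [gwet_ac1()].
#' @return List with `pairs` (tibble: `rater_a`, `rater_b`, `ac1`, `pa`,
#'   `pe`) and `mean_ac1`.
#' @export
rater_agreement <- function(masks, categories = NULL) {
  if (length(masks) < 2L) {
    abort("Need at least two raters.", class = "fcdmap_bad_argument")
  }
  nm <- names(masks) %||% paste0("rater", seq_along(masks))
  if (is.null(names(masks))) names(masks) <- nm
  combs <- utils::combn(seq_along(masks), 2L)
  rows <- purrr::map(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    g <- gwet_ac1(masks[[i1]], masks[[i2]], categories = categories)
    tibble(rater_a = nm[i1], rater_b = nm[i2],
           ac1 = g$ac1, pa = g$pa, pe = g$pe)
  })
  pairs <- dplyr::bind_rows(rows)
  list(pairs = pairs, mean_ac1 = mean(pairs$ac1))
}
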