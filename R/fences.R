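#' Medcouple robust skewness
#'
#' The medcouple is the median of the kernel
#' `h(x_i, x_j) = ((x_i - m) - (m - x_j)) / (x_i - x_j)` over all pairs with
#' `x_i >= m >= x_j` (m the sample median), with the standard -1/0/+1 rule for
#' pairs tied at the median. It lies in \[-1, 1\], is 0 for symmetric samples
#' and positive for right-skewed ones. Computed here by the full O(n^2)
#' kernel evaluation, which is ample for per-slide thickness samples.
#'
#' @param x Numeric sample, `n >= 3`, not all values equal.
#' @return The medcouple, a single number in \[-1, 1\].
#' @examples
#' medcouple(c(1, 2, 3, 4, 5))   # 0: symmetric
#' medcouple(c(0, 1, 2, 3, 10))  # > 0: right skew
#' @export
medcouple <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) {
    abort("medcouple needs at least 3 finite values.",
          class = "fcdmap_insufficient_sample")
  }
  if (diff(range(x)) == 0) {
    abort("medcouple is undefined for a constant sample.",
          class = "fcdmap_undefined_medcouple")
  }
  m <- median(x)
  z <- sort(x - m)
  zp <- z[z >= 0]          # ascending
  zm <- z[z <= 0]          # ascending
  np <- length(zp); nm <- length(zm)
  h <- outer(zp, zm, function(a, b) (a + b) / (a - b))
  # pairs tied at the median: antisymmetric -1/0/+1 pattern by rank
  k <- sum(z == 0)
  if (k > 0) {
    ip <- matrix(seq_len(np), np, nm)[zp == 0, zm == 0, drop = FALSE]
    ip <- ip - min(ip) + 1L # 1..k among the zero block
    jq <- matrix(rep(seq_len(nm), each = np), np, nm)[zp == 0, zm == 0, drop = FALSE]
    jq <- jq - min(jq) + 1L
    h[zp == 0, zm == 0] <- sign(ip + jq - (k + 1L))
  }
  median(h)
}

#' Skewness-adjusted boxplot fences for thickness screening
#'
#' Computes the robust outlier fences of the adjusted boxplot: with
#' MC the medcouple and IQR = q3 - q1,
#' \deqn{[q1 - 1.5 e^{-4 MC} IQR,\; q3 + 1.5 e^{+3 MC} IQR]} for MC >= 0 and
#' \deqn{[q1 - 1.5 e^{-3 MC} IQR,\; q3 + 1.5 e^{+4 MC} IQR]} for MC < 0.
#' At MC = 0 these reduce to Tukey's 1.5 IQR fences. The lower fence of a
#' control slide's thickness sample is the screening threshold below which
#' matched case thickness is flagged as possibly dysplastic.
#'
#' @param x Numeric sample (per-slide midline thickness values, um).
#' @param n_min Minimum sample size (configurable floor, default 8).
#' @param variant `"adjusted"` (medcouple fences) or `"tukey"` (plain
#'   1.5 IQR fences, for sensitivity analysis).
#' @return A `fence_result`: list with `q1`, `q2`, `q3`, `iqr`, `medcouple`,
#'   `lower_fence`, `upper_fence`, `n`, `variant`. Quantiles are type-7
#'   (linear interpolation).
#' @examples
#' adjusted_fences(rnorm(100, 2500, 200))
#' @export
adjusted_fences <- function(x, n_min = 8L, variant = c("adjusted", "tukey")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]
  if (length(x) < n_min) {
    abort(sprintf("Need at least %d values to estimate fences (got %d).",
                  n_min, length(x)),
          class = "fcdmap_insufficient_sample")
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  mc <- if (variant == "adjusted" && diff(range(x)) > 0) medcouple(x) else 0
  if (mc >= 0) {
    lf <- q[1] - 1.5 * exp(-4 * mc) * iqr
    uf <- q[3] + 1.5 * exp(3 * mc) * iqr
  } else {
    lf <- q[1] - 1.5 * exp(-3 * mc) * iqr
    uf <- q[3] + 1.5 * exp(4 * mc) * iqr
  }
  structure(
    list(q1 = q[1], q2 = q[2], q3 = q[3], iqr = iqr, medcouple = mc,
         lower_fence = lf, upper_fence = uf, n = length(x),
         variant = variant),
    class = "fence_result"
  )
}

#' @export
print.fence_result <- function(x, ...) {
  cat(sprintf(
    "<fence_result> n = %d, q = [%.4g, %.4g, %.4g], MC = %.3f\n  fences: [%.4g, %.4g] (%s)\n",
    x$n, x$q1, x$q2, x$q3, x$medcouple, x$lower_fence, x$upper_fence,
    x$variant))
  invisible(x)
}

#' @describeIn adjusted_fences Fence components as a one-row tibble.
#' @param ... Unused.
#' @export
tidy.fence_result <- function(x, ...) {
  tibble(q1 = x$q1, q2 = x$q2, q3 = x$q3, iqr = x$iqr,
         medcouple = x$medcouple, lower_fence = x$lower_fence,
         upper_fence = x$upper_fence, n = x$n, variant = x$variant)
}
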