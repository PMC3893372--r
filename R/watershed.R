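#' Marker-controlled watershed segmentation of dark objects
#'
#' Initial neuron segmentation from a (GGMRF-relaxed) image: markers are the
#' regional minima of the Gaussian-smoothed intensity that survive an
#' h-minima depth filter (shallow minima caused by residual noise are
#' suppressed by grayscale reconstruction); nearby markers within
#' `min_sep_px` merge. The background marker is the set of pixels above the
#' global intermeans threshold. Each foreground pixel is then assigned to a
#' marker by watershed-style seeded growing on the intensity relief
#' (EBImage's `propagate`), so touching objects split along the saddle ridge
#' between their minima.
#'
#' @param img Numeric matrix, dark objects on light background.
#' @param h_min Depth of the h-minima filter (intensity units on the image's
#'   own scale; default 10, suited to an 8-bit range).
#' @param blur_sigma Gaussian smoothing sigma (px) before marker detection.
#' @param min_sep_px Markers closer than this merge into one (px).
#' @param lambda Regularisation of the seeded growing (small values make the
#'   split follow the intensity relief closely).
#' @return Integer label matrix (`0` background, `1..K` objects), with the
#'   marker count as attribute `n_markers`. Zero markers give an empty mask
#'   with a warning.
#' @export
watershed_initial <- function(img, h_min = 10, blur_sigma = 2,
                              min_sep_px = 4, lambda = 1e-4) {
  sm <- ebi_mat(EBImage::gblur(img, sigma = blur_sigma))
  thr <- intermeans_threshold(sm)
  fg <- sm < thr

  # h-minima: grayscale reconstruction-by-erosion of (sm + h) over sm;
  # regional minima of the reconstruction are the surviving markers
  rec <- reconstruct_by_erosion(sm + h_min, sm)
  minima <- rec <= minfilt3(rec) + 1e-9
  minima <- minima & fg
  if (!any(minima)) {
    warn("No watershed markers found; returning empty mask.")
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "n_markers") <- 0L
    return(out)
  }
  # merge markers closer than min_sep_px
  if (min_sep_px > 1) {
    grown <- EBImage::dilate(minima * 1, disc_brush(min_sep_px / 2))
    lab_grown <- EBImage::bwlabel(ebi_mat(grown) > 0)
    seeds <- matrix(as.integer(ebi_mat(lab_grown)), nrow(img))
    seeds[!minima] <- 0L
  } else {
    seeds <- matrix(as.integer(ebi_mat(EBImage::bwlabel(minima))), nrow(img))
  }

  ws <- EBImage::propagate(x = sm, seeds = seeds, mask = fg, lambda = lambda)
  out <- matrix(as.integer(ebi_mat(ws)), nrow(img))
  out <- renumber_labels(out)
  attr(out, "n_markers") <- max(seeds)
  out
}

# Grayscale reconstruction-by-erosion of `seed` (>= mask) constrained below
# by `mask`: iterate seed = max(erode3(seed), mask) to stability.
reconstruct_by_erosion <- function(seed, mask, max_iter = 500L) {
  cur <- pmax(seed, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmax(minfilt3(cur), mask)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# Global intermeans (isodata) threshold: fixed point of
# thr = (mean below + mean above) / 2.
intermeans_threshold <- function(v, max_iter = 100L) {
  v <- as.numeric(v)
  thr <- mean(range(v))
  for (i in seq_len(max_iter)) {
    lo <- v[v <= thr]; hi <- v[v > thr]
    if (!length(lo) || !length(hi)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < 1e-6 * diff(range(v))) {
      thr <- new
      break
    }
    thr <- new
  }
  thr
}

renumber_labels <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (!length(u)) return(labels)
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- seq_along(u)
  out <- labels
  out[labels > 0L] <- lut[labels[labels > 0L] + 1L]
  out
}

# EBImage returns Image objects; flatten back to a plain matrix.
ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}
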