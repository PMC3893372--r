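# TIFF I/O helpers. Grayscale images are stored 8- or 16-bit; label masks
# 16-bit. The tiff package works in [0, 1], so intensities are scaled by the
# bit depth on the way in and out.

#' Read and write grayscale images and label masks as TIFF
#'
#' `write_image_tiff()`/`read_image_tiff()` handle grayscale intensity images
#' (values on a 0..255 or 0..65535 scale); `write_mask_tiff()`/
#' `read_mask_tiff()` handle integer label masks losslessly up to 65535
#' labels.
#'
#' @param img Numeric matrix of intensities.
#' @param path File path.
#' @param bits 8 or 16.
#' @return Readers return a numeric (or integer, for masks) matrix; writers
#'   return `path` invisibly.
#' @export
write_image_tiff <- function(img, path, bits = 8L) {
  top <- 2^bits - 1
  m <- pmin(pmax(img, 0), top) / top
  tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, bits = 8L) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * (2^bits - 1)
}

#' @rdname write_image_tiff
#' @param mask Integer label matrix (0 = background).
#' @export
write_mask_tiff <- function(mask, path) {
  if (max(mask) > 65535L) {
    abort("Masks with > 65535 labels cannot be stored as 16-bit TIFF.",
          class = "fcdmap_bad_argument")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m))
}
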