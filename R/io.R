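#' Read a grayscale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit PNG or TIFF file and returns a numeric matrix
#' normalized to \[0, 1\] (full-scale white maps to 1). Multi-channel images
#' are converted to luminance with the Rec. 709 weights
#' `0.2126 R + 0.7152 G + 0.0722 B`; an alpha channel is ignored.
#'
#' @param path File path; format inferred from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected): %s",
                 ext, path), call. = FALSE))
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) {
      raw <- 0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
    } else {
      raw <- raw[, , 1]
    }
  }
  img <- as.matrix(raw)
  validate_image(img)
  pmin(pmax(img, 0), 1)
}

#' Write a grayscale image as PNG or TIFF
#'
#' Quantizes intensities to the requested bit depth with round-half-to-even
#' and writes the file. Values outside \[0, 1\] are clipped with a warning.
#' PNG output is 8-bit; TIFF supports 8 or 16 bits.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path; format inferred from the extension.
#' @param bit_depth 8 or 16. Default 8.
#' @return Invisibly, the quantized matrix that was written.
#' @export
save_image <- function(img, path, bit_depth = 8L) {
  validate_image(img)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16",
                                       call. = FALSE)
  if (any(img < 0) || any(img > 1)) {
    warning("intensities outside [0, 1] clipped on write")
    img <- pmin(pmax(img, 0), 1)
  }
  levels <- 2^bit_depth - 1
  q <- round(img * levels) / levels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (bit_depth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit",
                                call. = FALSE)
      png::writePNG(q, path)
    },
    tif = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = bit_depth),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected): %s",
                 ext, path), call. = FALSE))
  invisible(q)
}
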