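#' Load a grayscale fluorescence image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG and returns a numeric
#' matrix of intensities normalized to \[0, 1\] (pixel value divided by the
#' bit-depth maximum, the contract the rest of the pipeline assumes). The
#' source bit depth is recorded in the `"source_bit_depth"` attribute.
#'
#' @param path Path to the image file.
#' @param channel For multi-channel (e.g. RGB) input, the 1-based index of
#'   the channel to extract (the GFP channel of a whole-mount photograph).
#'   Required when the file has more than one channel.
#' @return A numeric matrix in \[0, 1\] with attribute `source_bit_depth`
#'   (8 or 16).
#' @export
load_image <- function(path, channel = NULL) {
  if (!file.exists(path)) {
    stop("cannot read image file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(px, "bits.per.sample")
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    depth <- attr(px, "info")$bit.depth
  } else {
    stop("unsupported image format '", ext, "' for file: ", path)
  }
  if (is.null(depth) || !depth %in% c(8L, 16L)) {
    stop("unsupported bit depth (", depth, ") in file: ", path,
         " (8- or 16-bit required)")
  }
  if (length(dim(px)) == 3L) {
    if (is.null(channel)) {
      stop("channel required: ", path, " has ", dim(px)[3],
           " channels; supply `channel` to select one")
    }
    if (channel < 1L || channel > dim(px)[3]) {
      stop("channel ", channel, " out of range for file: ", path)
    }
    px <- px[, , channel]
  }
  px <- unclass(px)  # tiff/png already normalize by the bit-depth maximum
  attributes(px) <- list(dim = dim(px))
  attr(px, "source_bit_depth") <- as.integer(depth)
  px
}

#' Load a binary region-of-interest mask
#'
#' Any nonzero pixel is part of the ROI. Multi-channel masks use the first
#' channel.
#'
#' @param path Path to a PNG or TIFF mask.
#' @return A logical matrix.
#' @export
load_mask <- function(path) {
  px <- load_image(path, channel = 1L)
  m <- unclass(px) > 0
  attr(m, "source_bit_depth") <- NULL
  m
}

#' Write a grayscale image to disk
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Output path; `.tif`/`.tiff` writes 16-bit TIFF (default
#'   cohort format), `.png` writes 8-bit PNG.
#' @param bits Bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bits = 16L) {
  img <- pmin(pmax(unclass(img), 0), 1)
  attributes(img) <- list(dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported output format: ", path)
  }
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
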