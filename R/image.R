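#' Construct a single-channel fluorescence image
#'
#' A `channel_image` stores one fluorescence channel as a 2D grid of
#' non-negative intensities together with its pixel-size calibration.
#' Pixel coordinates are 0-based with `x` running along columns and `y`
#' along rows (y increases downwards, the usual image convention); the
#' center of pixel `(i, j)` is at `(x = i, y = j)`.
#'
#' @param pixels Numeric matrix of intensities, `[row = y, col = x]`, all
#'   values `>= 0`.
#' @param channel Channel label (e.g. `"DAPI"`, `"Ki67"`, `"calretinin"`).
#' @param bit_depth Source bit depth (8 or 16); intensities are on the
#'   `[0, 2^bit_depth - 1]` scale.
#' @param pixel_size_um Physical pixel size in micrometres per pixel
#'   (default 0.36, the calibration at which a 50 px cell body spans 18 um).
#' @param background_subtracted Logical flag recording whether a background
#'   frame has already been subtracted.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = "unknown", bit_depth = 16,
                          pixel_size_um = 0.36, background_subtracted = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) < 1L)) {
    abort("`pixels` must be a numeric matrix with at least one pixel")
  }
  if (any(pixels < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  if (!bit_depth %in% c(8, 16)) abort("`bit_depth` must be 8 or 16")
  assert_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-12)
  structure(
    list(pixels = pixels, channel = as.character(channel),
         bit_depth = as.integer(bit_depth), pixel_size_um = pixel_size_um,
         background_subtracted = isTRUE(background_subtracted)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s'> %d x %d px, %d-bit, %.3g um/px%s\n",
              x$channel, ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              x$pixel_size_um,
              if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Read a grayscale or RGB image from TIFF or PNG
#'
#' Reads 8- or 16-bit images losslessly at their native bit depth. A
#' grayscale file yields one [channel_image()]; an RGB file yields a named
#' list of three, labelled through `channel_map`.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel Channel label for a grayscale image.
#' @param channel_map For RGB images, named character vector mapping
#'   `c(R = , G = , B = )` to channel labels.
#' @param pixel_size_um Pixel calibration to attach (not stored in the file).
#' @return A `channel_image`, or a named list of them for RGB input.
#' @export
read_image <- function(path, channel = "unknown",
                       channel_map = c(R = "R", G = "G", B = "B"),
                       pixel_size_um = 0.36) {
  if (!file.exists(path)) abort(sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path, as.is = TRUE, info = TRUE),
      png = png::readPNG(path),
      abort(sprintf("unsupported image format '%s' for '%s'", ext, path))
    ),
    error = function(e) abort(sprintf("failed to read image '%s': %s", path, conditionMessage(e)))
  )
  if (ext == "png") {
    # png::readPNG normalises to [0,1]; recover integer levels assuming the
    # common 8-bit encoding unless 16-bit precision is evident
    scaled255 <- arr * 255
    depth <- if (max(abs(scaled255 - round(scaled255))) < 1e-9) 8L else 16L
    arr <- round(arr * (2^depth - 1))
  } else {
    bits <- attr(arr, "bits.per.sample") %||% (if (max(arr) > 255) 16L else 8L)
    depth <- if (as.integer(bits[[1]]) > 8) 16L else 8L
  }
  make1 <- function(m, lab) channel_image(m, channel = lab, bit_depth = depth,
                                          pixel_size_um = pixel_size_um)
  if (length(dim(arr)) == 2L) return(make1(unclass(arr), channel))
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    labs <- channel_map[c("R", "G", "B")]
    out <- lapply(1:3, function(k) make1(arr[, , k], labs[[k]]))
    names(out) <- labs
    return(out)
  }
  abort(sprintf("unsupported image layout in '%s'", path))
}

#' Write a channel image to TIFF or PNG at its native bit depth
#'
#' @param image A [channel_image()].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  maxv <- 2^image$bit_depth - 1
  norm <- pmin(pmax(image$pixels / maxv, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(norm, path, bits.per.sample = image$bit_depth),
    png = png::writePNG(norm, path),
    abort(sprintf("unsupported output format '%s'", ext))
  )
  invisible(path)
}

#' Subtract a background frame from an image
#'
#' Mirrors the standard immunofluorescence protocol: a background frame
#' acquired outside the tissue section is subtracted pixel-wise from the
#' stained-section image. Differences are clipped at zero so intensities
#' stay non-negative (they feed an 8-bit conversion downstream).
#'
#' @param image,background Two [channel_image()]s of identical dimensions
#'   and channel.
#' @return A `channel_image` flagged `background_subtracted`.
#' @export
subtract_background <- function(image, background) {
  stopifnot(inherits(image, "channel_image"), inherits(background, "channel_image"))
  if (!identical(dim(image$pixels), dim(background$pixels))) {
    abort(sprintf("dimension mismatch: image is %s, background is %s",
                  paste(dim(image$pixels), collapse = "x"),
                  paste(dim(background$pixels), collapse = "x")))
  }
  if (!identical(image$channel, background$channel)) {
    abort(sprintf("channel mismatch: '%s' vs '%s'", image$channel, background$channel))
  }
  out <- image
  out$pixels <- pmax(image$pixels - background$pixels, 0)
  out$background_subtracted <- TRUE
  out
}

#' Convert an image to 8-bit grayscale
#'
#' Linear rescale mapping 0 to 0 and the source bit-depth maximum (65535
#' for 16-bit input) to 255, rounding half-up. Idempotent on 8-bit input.
#'
#' @param image A [channel_image()].
#' @return An 8-bit `channel_image`.
#' @export
to_grayscale8 <- function(image) {
  stopifnot(inherits(image, "channel_image"))
  if (image$bit_depth == 8L) return(image)
  out <- image
  out$pixels <- floor(image$pixels * 255 / (2^image$bit_depth - 1) + 0.5)
  out$bit_depth <- 8L
  out
}
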