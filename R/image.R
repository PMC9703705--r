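#' HSV threshold set for background masking
#'
#' Inclusive `[low, high]` ranges for hue, saturation and value, each on
#' the 0--1 scale. The defaults (`h = [0, 1]`, `s = [0, 1]`,
#' `v = [0.15, 1]`) keep every hue and saturation and drop only dark
#' pixels, which removes a black imaging-chamber background while
#' leaving the panicle untouched.
#'
#' @param h,s,v length-2 numeric `[low, high]` pairs in `[0, 1]`.
#' @return An object of class `hsv_thresholds`.
#' @export
hsv_thresholds <- function(h = c(0, 1), s = c(0, 1), v = c(0.15, 1)) {
  chk <- function(r, nm) {
    r <- as.numeric(r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0 || r[2] > 1)
      stop("'", nm, "' must be a [low, high] pair within [0, 1]")
    r
  }
  structure(list(h = chk(h, "h"), s = chk(s, "s"), v = chk(v, "v")),
            class = "hsv_thresholds")
}

#' @export
print.hsv_thresholds <- function(x, ...) {
  cat(sprintf("HSV thresholds: h [%g, %g], s [%g, %g], v [%g, %g]\n",
              x$h[1], x$h[2], x$s[1], x$s[2], x$v[1], x$v[2]))
  invisible(x)
}

#' Read an RGB image
#'
#' Thin wrapper over [EBImage::readImage()] returning an H x W x 3
#' array of intensities on the 0--255 scale.
#'
#' @param path path to a PNG/JPEG/TIFF image.
#' @return Numeric H x W x 3 array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L)
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores x (width) as the first dimension; present as H x W
  aperm(px * 255, c(2, 1, 3))
}

#' Write an RGB image as PNG
#'
#' @param pixels H x W x 3 array of intensities in `[0, 255]`.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  pixels <- .check_pixels(pixels)
  img <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)),
                        colormode = "Color")
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

.check_pixels <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  pixels
}

#' Mask the image background by HSV thresholding
#'
#' Converts pixels to HSV and retains those whose hue, saturation and
#' value all fall inside the (inclusive) threshold ranges; removed
#' pixels are set to black. With the default thresholds only pixels
#' with value below 0.15 are removed, i.e. the dark chamber background.
#'
#' @param pixels H x W x 3 RGB array in `[0, 255]`.
#' @param thresholds an [hsv_thresholds()] object.
#' @return A list of class `masked_image`: `pixels` (masked image,
#'   background black) and `mask` (H x W logical, `TRUE` = retained).
#' @examples
#' img <- array(51, dim = c(4, 4, 3))  # uniform gray, V = 0.2
#' m <- mask_background(img)
#' all(m$mask)
#' @export
mask_background <- function(pixels, thresholds = hsv_thresholds()) {
  pixels <- .check_pixels(pixels)
  if (!inherits(thresholds, "hsv_thresholds"))
    stop("'thresholds' must be an hsv_thresholds() object")
  d <- dim(pixels)
  flat <- matrix(pixels, ncol = 3L)  # pixels x rgb, column-major
  hsv <- rgb2hsv(t(flat), maxColorValue = 255)
  keep <- hsv[1, ] >= thresholds$h[1] & hsv[1, ] <= thresholds$h[2] &
          hsv[2, ] >= thresholds$s[1] & hsv[2, ] <= thresholds$s[2] &
          hsv[3, ] >= thresholds$v[1] & hsv[3, ] <= thresholds$v[2]
  out <- flat
  out[!keep, ] <- 0
  structure(list(pixels = array(out, dim = d),
                 mask = matrix(keep, nrow = d[1], ncol = d[2])),
            class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  cat(sprintf("Masked image: %d x %d, %.1f%% of pixels retained\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}
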