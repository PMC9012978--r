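#' Binary root-crown image
#'
#' Container for a segmented root-crown raster: a 0/1 integer matrix
#' (foreground = root, row 1 = top of the crown) together with the pixel
#' scale of the photograph.
#'
#' @param pixels Integer or logical matrix; nonzero entries are root
#'   foreground.
#' @param px_per_mm Positive scalar, pixels per millimetre.
#' @param image_id Character identifier.
#' @return An object of class `root_image`.
#' @export
root_image <- function(pixels, px_per_mm, image_id = "img") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  pixels[pixels != 0L] <- 1L
  if (!is.finite(px_per_mm) || px_per_mm <= 0)
    stop("`px_per_mm` must be finite and positive")
  structure(list(pixels = pixels, px_per_mm = px_per_mm,
                 image_id = as.character(image_id)),
            class = "root_image")
}

#' @export
print.root_image <- function(x, ...) {
  cat(sprintf("<root_image '%s': %d x %d px, %.3g px/mm, %d foreground px>\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), x$px_per_mm,
              sum(x$pixels)))
  invisible(x)
}

#' @export
plot.root_image <- function(x, ...) {
  m <- x$pixels
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = c("white", "black"),
                  axes = FALSE, asp = nrow(m) / ncol(m),
                  main = x$image_id, ...)
  invisible(x)
}

#' Pixel scale from a circular marker
#'
#' Photographs taken at varying working distance carry a circular tag of
#' known diameter; its measured pixel width gives the image scale.
#'
#' @param pixel_width Measured width of the marker in pixels.
#' @param known_diameter_mm True marker diameter in mm.
#' @return Pixels per millimetre.
#' @export
px_per_mm_from_marker <- function(pixel_width, known_diameter_mm) {
  if (!is.finite(pixel_width) || pixel_width <= 0)
    stop("`pixel_width` must be positive")
  if (!is.finite(known_diameter_mm) || known_diameter_mm <= 0)
    stop("`known_diameter_mm` must be positive")
  pixel_width / known_diameter_mm
}

#' Threshold a grayscale raster into a binary root mask
#'
#' Polarity is auto-detected: of the two sides of the threshold, the side
#' holding the minority of pixels is taken as root foreground (a root crown
#' occupies far less than half the frame). Already-binary masks pass through
#' unchanged. Matrices whose values all lie in \[0, 1\] are interpreted as
#' 8-bit intensities scaled to \[0, 255\].
#'
#' @param raster Numeric matrix with values in \[0, 255\] (or \[0, 1\]).
#' @param threshold Intensity threshold, default 200.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(raster, threshold = 200) {
  if (!is.matrix(raster)) stop("`raster` must be a matrix")
  v <- raster
  if (max(v) <= 1) v <- v * 255
  hi <- v > threshold
  n_hi <- sum(hi)
  n_lo <- length(v) - n_hi
  fg <- if (n_hi == 0 || (n_lo > 0 && n_hi <= n_lo)) hi else !hi
  if (!any(fg))
    stop(sprintf("no foreground pixels at threshold %s", threshold))
  m <- matrix(0L, nrow(v), ncol(v))
  m[fg] <- 1L
  m
}

#' Read a binary root-crown PNG
#'
#' @param path PNG file path.
#' @param px_per_mm Pixel scale of the image.
#' @param image_id Identifier; defaults to the file name.
#' @param threshold Binarization threshold applied after reading.
#' @return A [root_image()].
#' @export
read_root_image <- function(path, px_per_mm, image_id = NULL,
                            threshold = 200) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  if (is.null(image_id))
    image_id <- sub("\\.png$", "", basename(path), ignore.case = TRUE)
  root_image(binarize(a, threshold), px_per_mm, image_id)
}

#' Write a root-crown mask as an 8-bit PNG (foreground 255, background 0)
#'
#' @param img A [root_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_root_image <- function(img, path) {
  stopifnot(inherits(img, "root_image"))
  png::writePNG(img$pixels * 1.0, path)
  invisible(path)
}
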