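#' Grayscale image container
#'
#' An `image2d` is a numeric matrix of finite intensities carrying a nominal
#' bit depth and, optionally, the physical pixel spacing. It is the common
#' currency of every operation in the package. Rows index the vertical image
#' coordinate y (top row first) and columns the horizontal coordinate x, so
#' `pix[y, x]` addresses the pixel at column x, row y of the displayed image.
#'
#' Intensities are carried as real numbers throughout; quantization to
#' integers happens only when an image is written to disk. The nominal
#' dynamic range is `[0, 2^bit_depth - 1]` but intermediate images (e.g. an
#' unsharp-masked image before its range policy is applied) may exceed it.
#'
#' @param pixels numeric matrix of intensities, at least 3 x 3, all finite.
#' @param bit_depth nominal bit depth, one of 8, 12 or 16 (default 12, the
#'   depth of computed-radiography chest images).
#' @param pixel_spacing_mm optional numeric pair `c(dy, dx)` of positive
#'   pixel spacings in millimetres.
#' @return an object of class `image2d`.
#' @examples
#' img <- image2d(matrix(runif(64, 0, 4095), 8, 8))
#' img
#' @export
image2d <- function(pixels, bit_depth = 12L, pixel_spacing_mm = NULL) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop(sprintf("image must be at least 3 x 3 (got %d x %d)",
                 nrow(pixels), ncol(pixels)))
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite (no NA/NaN/Inf)")
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || !(bit_depth %in% c(8L, 12L, 16L)))
    stop("'bit_depth' must be one of 8, 12, 16")
  if (!is.null(pixel_spacing_mm)) {
    pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
    if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
        any(pixel_spacing_mm <= 0))
      stop("'pixel_spacing_mm' must be two positive numbers")
  }
  structure(pixels, bit_depth = bit_depth, pixel_spacing_mm = pixel_spacing_mm,
            class = c("image2d", "matrix"))
}

#' Coerce to an image2d
#'
#' Matrices pass through [image2d()]; an existing `image2d` is returned
#' unchanged (with `bit_depth` overridden if supplied).
#'
#' @param x matrix or `image2d`.
#' @param bit_depth optional bit depth override.
#' @return an `image2d`.
#' @export
as_image2d <- function(x, bit_depth = NULL) {
  if (is_image2d(x)) {
    if (is.null(bit_depth)) return(x)
    return(image2d(pixels(x), bit_depth = bit_depth,
                   pixel_spacing_mm = attr(x, "pixel_spacing_mm")))
  }
  image2d(x, bit_depth = if (is.null(bit_depth)) 12L else bit_depth)
}

#' @rdname as_image2d
#' @export
is_image2d <- function(x) inherits(x, "image2d")

#' Extract the bare pixel matrix of an image
#'
#' @param img an `image2d` (a plain matrix is returned as-is).
#' @return a plain numeric matrix without image attributes.
#' @export
pixels <- function(img) {
  m <- unclass(img)
  attr(m, "bit_depth") <- NULL
  attr(m, "pixel_spacing_mm") <- NULL
  m
}

#' @export
print.image2d <- function(x, ...) {
  sp <- attr(x, "pixel_spacing_mm")
  cat(sprintf("<image2d> %d x %d, %d-bit, intensities [%.6g, %.6g]%s\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              min(x), max(x),
              if (is.null(sp)) ""
              else sprintf(", spacing %.4g x %.4g mm", sp[1], sp[2])))
  invisible(x)
}

#' @export
summary.image2d <- function(object, ...) {
  m <- pixels(object)
  c(min = min(m), q1 = unname(stats::quantile(m, 0.25)),
    median = stats::median(m), mean = mean(m),
    q3 = unname(stats::quantile(m, 0.75)), max = max(m))
}

#' Display an image with a gray palette
#'
#' Renders the image in its natural orientation (top row of the matrix at
#' the top of the plot) using [graphics::image()].
#'
#' @param x an `image2d`.
#' @param zlim intensity range mapped onto the palette; defaults to the
#'   image's own range.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.image2d <- function(x, zlim = range(x), main = NULL, ...) {
  m <- pixels(x)
  # image() draws column-major with y increasing upward; transpose and flip
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  zlim = zlim, axes = FALSE, asp = nrow(m) / ncol(m),
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

# white level of the nominal dynamic range
white_level <- function(img) 2^attr(img, "bit_depth") - 1

# rebuild an image2d from a matrix, copying metadata from a template
im_like <- function(m, template) {
  image2d(m, bit_depth = attr(template, "bit_depth"),
          pixel_spacing_mm = attr(template, "pixel_spacing_mm"))
}
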