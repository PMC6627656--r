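#' Specification of a chest-like synthetic phantom
#'
#' Describes a reproducible test image emulating the content of a portable
#' chest radiograph at desk scale: a smooth low-frequency background with a
#' vertical intensity gradient, smooth periodic horizontal "rib" bands, thin
#' bright curvilinear "tube" structures (the endotracheal / feeding /
#' nasogastric tubes the enhancement is aimed at), plus Gaussian sensor
#' noise and sparse impulse pixels. The defaults are the package's standard
#' phantom, used throughout the test and acceptance suites; identical spec
#' and seed always produce the identical phantom.
#'
#' @param height,width image size in pixels (default 256 x 256).
#' @param base_level background base intensity (default 1500 of the 12-bit
#'   range).
#' @param gradient_amplitude total top-to-bottom span of the linear
#'   background gradient (default 400).
#' @param rib_count number of smooth periodic horizontal bands (default 5).
#' @param rib_amplitude amplitude of the rib bands (default 200).
#' @param tubes list of tube descriptions, each a list with `rows` (control
#'   row positions, interpolated by a natural spline across the width),
#'   `width` (band width in pixels, default 3) and `contrast` (additive
#'   intensity, default +600).
#' @param gaussian_noise_sigma standard deviation of i.i.d. Gaussian noise
#'   (default 20).
#' @param impulse_density fraction of pixels replaced by impulses, in
#'   `[0, 0.05]` (default 0.005). The impulse count is exact —
#'   `round(density * npixels)` pixels are chosen by a seeded draw — so
#'   tests can assert counts.
#' @param impulse_amplitude additive amplitude of each impulse (default
#'   +400). Impulse pixels take the noise-free rendered value plus this
#'   amplitude (they are not additionally perturbed by Gaussian noise).
#' @param seed RNG seed (default 20190424).
#' @param bit_depth nominal bit depth; intensities are clamped to its range
#'   (default 12).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         base_level = 1500, gradient_amplitude = 400,
                         rib_count = 5L, rib_amplitude = 200,
                         tubes = list(
                           list(rows = c(70, 92, 78, 100, 86) * height / 256,
                                width = 3, contrast = 600),
                           list(rows = c(186, 162, 174, 150, 166) * height / 256,
                                width = 3, contrast = 600)),
                         gaussian_noise_sigma = 20,
                         impulse_density = 0.005, impulse_amplitude = 400,
                         seed = 20190424L, bit_depth = 12L) {
  height <- as.integer(height); width <- as.integer(width)
  stopifnot(height >= 3L, width >= 3L,
            is.finite(base_level), is.finite(gradient_amplitude),
            rib_count >= 0L, is.finite(rib_amplitude),
            gaussian_noise_sigma >= 0,
            impulse_density >= 0, impulse_density <= 0.05,
            is.finite(impulse_amplitude))
  tubes <- lapply(tubes, function(tb) {
    stopifnot(is.list(tb), is.numeric(tb$rows), length(tb$rows) >= 2L)
    if (is.null(tb$width)) tb$width <- 3
    if (is.null(tb$contrast)) tb$contrast <- 600
    stopifnot(tb$width >= 1, is.finite(tb$contrast))
    tb
  })
  structure(list(height = height, width = width, base_level = base_level,
                 gradient_amplitude = gradient_amplitude,
                 rib_count = as.integer(rib_count),
                 rib_amplitude = rib_amplitude, tubes = tubes,
                 gaussian_noise_sigma = gaussian_noise_sigma,
                 impulse_density = impulse_density,
                 impulse_amplitude = impulse_amplitude,
                 seed = as.integer(seed), bit_depth = as.integer(bit_depth)),
            class = "phantom_spec")
}

#' Render a synthetic chest-like phantom
#'
#' Renders the background, ribs and tubes of a [phantom_spec()], adds seeded
#' Gaussian noise, then sets the seeded impulse pixels, and clamps to the
#' nominal intensity range. Ground-truth masks of the tube pixels and of the
#' impulse locations are returned with the image; they power the
#' edge-versus-noise selectivity tests.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: a list with fields `img`
#'   ([image2d()]), `edge_map` (logical matrix marking tube-band pixels),
#'   `impulse_map` (logical matrix) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec())
#' ph$img
#' sum(ph$impulse_map)
#' @export
make_phantom <- function(spec = phantom_spec()) {
  H <- spec$height; W <- spec$width
  t_row <- (seq_len(H) - 1) / (H - 1)
  bg <- spec$base_level + spec$gradient_amplitude * (t_row - 0.5)
  if (spec$rib_count > 0L)
    bg <- bg + spec$rib_amplitude * sin(2 * pi * spec$rib_count * t_row)
  clean <- matrix(bg, H, W)
  edge_map <- matrix(FALSE, H, W)
  rowmat <- matrix(seq_len(H), H, W)
  for (tb in spec$tubes) {
    ctrl_cols <- seq(1, W, length.out = length(tb$rows))
    center <- stats::spline(ctrl_cols, tb$rows, xout = seq_len(W),
                            method = "natural")$y
    if (min(center) - tb$width / 2 < 1 || max(center) + tb$width / 2 > H)
      stop(sprintf("tube leaves the image: centerline spans [%.1f, %.1f] in a height-%d image",
                   min(center), max(center), H))
    band <- abs(rowmat - matrix(center, H, W, byrow = TRUE)) <= tb$width / 2
    clean <- clean + tb$contrast * band
    edge_map <- edge_map | band
  }
  with_seed(spec$seed, function() {
    img <- clean
    if (spec$gaussian_noise_sigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec$gaussian_noise_sigma), H, W)
    impulse_map <- matrix(FALSE, H, W)
    n_imp <- round(spec$impulse_density * H * W)
    if (n_imp > 0) {
      idx <- sample.int(H * W, n_imp)
      img[idx] <- clean[idx] + spec$impulse_amplitude
      impulse_map[idx] <- TRUE
    }
    img <- pmin(pmax(img, 0), 2^spec$bit_depth - 1)
    structure(list(img = image2d(img, bit_depth = spec$bit_depth),
                   edge_map = edge_map, impulse_map = impulse_map,
                   spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d, %d tube(s), %d impulse pixel(s), seed %d\n",
              x$spec$height, x$spec$width, length(x$spec$tubes),
              sum(x$impulse_map), x$spec$seed))
  invisible(x)
}

#' Step-edge test image
#'
#' A two-level image: columns with 0-based x-coordinate `< edge_column` at
#' `level_low`, the rest at `level_high`. The elementary fixture for
#' edge-attenuation measurements.
#'
#' @param height,width image size, each >= 3.
#' @param level_low,level_high the two intensity levels.
#' @param edge_column 0-based column index of the first high column,
#'   `0 < edge_column < width`.
#' @param bit_depth nominal bit depth of the result (default 12).
#' @return an [image2d()].
#' @export
make_step_edge <- function(height, width, level_low, level_high, edge_column,
                           bit_depth = 12L) {
  edge_column <- as.integer(edge_column)
  if (edge_column <= 0L || edge_column >= width)
    stop("'edge_column' must satisfy 0 < edge_column < width")
  m <- matrix(level_low, height, width)
  m[, (edge_column + 1L):width] <- level_high
  image2d(m, bit_depth = bit_depth)
}
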