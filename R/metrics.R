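#' EMEE block configuration
#'
#' @param block_h,block_w block size in pixels (default 40 x 40).
#' @param c positive stabilizing constant added to each block minimum so
#'   blocks containing zero-intensity pixels keep a finite ratio
#'   (default 30).
#' @return an object of class `emee_config`.
#' @export
emee_config <- function(block_h = 40L, block_w = 40L, c = 30) {
  block_h <- as.integer(block_h); block_w <- as.integer(block_w)
  stopifnot(block_h >= 1L, block_w >= 1L, is.numeric(c), c > 0)
  structure(list(block_h = block_h, block_w = block_w, c = c),
            class = "emee_config")
}

#' Measurement of enhancement by entropy evaluation (EMEE)
#'
#' Tiles the image into non-overlapping `block_h x block_w` blocks from the
#' top-left (partial blocks at the right/bottom edges are included as-is, so
#' every pixel contributes); for each block forms the stabilized contrast
#' ratio `r = I_max / (I_min + c)` and accumulates the entropy-style term
#' `r * ln(r)` (with `0 * ln(0) := 0` by continuity, covering all-zero
#' blocks); returns the mean over blocks. Larger values indicate stronger
#' local contrast. The logarithm is natural — absolute EMEE values depend on
#' this choice, relative comparisons do not.
#'
#' @param img an [image2d()] with nonnegative intensities.
#' @param config an [emee_config()].
#' @return a single number.
#' @examples
#' emee(image2d(matrix(100, 40, 40)))   # single constant block
#' @export
emee <- function(img, config = emee_config()) {
  m <- pixels(as_image2d(img))
  if (min(m) < 0)
    stop("EMEE is defined for nonnegative intensities; apply a range policy first")
  rs <- seq(1L, nrow(m), by = config$block_h)
  cs <- seq(1L, ncol(m), by = config$block_w)
  total <- 0
  for (r0 in rs) {
    r1 <- min(r0 + config$block_h - 1L, nrow(m))
    for (c0 in cs) {
      c1 <- min(c0 + config$block_w - 1L, ncol(m))
      blk <- m[r0:r1, c0:c1]
      ratio <- max(blk) / (min(blk) + config$c)
      if (ratio > 0) total <- total + ratio * log(ratio)
    }
  }
  total / (length(rs) * length(cs))
}

#' Signal-to-noise ratio over two rectangular regions
#'
#' A region-of-interest SNR: the mean intensity over a signal rectangle
#' divided by the sample standard deviation (denominator n - 1) over a
#' noise rectangle. This definition is this package's own — it is the
#' conventional ROI form, but no claim is made that it matches any
#' particular published SNR protocol for radiographs.
#'
#' @param img an [image2d()].
#' @param signal_region,noise_region integer vectors
#'   `c(row_min, row_max, col_min, col_max)` (1-based, inclusive) within the
#'   image; the noise region must contain at least 2 pixels.
#' @return a single number.
#' @export
snr <- function(img, signal_region, noise_region) {
  m <- pixels(as_image2d(img))
  rect <- function(r, what) {
    r <- as.integer(r)
    if (length(r) != 4L || r[1] > r[2] || r[3] > r[4] ||
        r[1] < 1L || r[3] < 1L || r[2] > nrow(m) || r[4] > ncol(m))
      stop_dim(sprintf("%s c(%s) is not a valid rectangle within the %d x %d image",
                       what, paste(r, collapse = ", "), nrow(m), ncol(m)))
    m[r[1]:r[2], r[3]:r[4]]
  }
  sig <- rect(signal_region, "signal_region")
  noi <- rect(noise_region, "noise_region")
  if (length(noi) < 2L) stop_dim("noise_region must contain at least 2 pixels")
  s <- stats::sd(noi)
  if (s == 0)
    stop(errorCondition("noise region has zero standard deviation; SNR is undefined",
                        class = c("radusm_undefined_snr_error", "error")))
  mean(sig) / s
}
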