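#' Unsharp-mask weighting and range policy
#'
#' @param alpha_usm nonnegative weight of the unsharp mask in
#'   `I_en = I + alpha_usm * (I - I_smoothed)`. Default 1, i.e. the mask is
#'   added to the original at full strength. Distinct from the diffusion
#'   weight `alpha_diff` of [diffusion_params()].
#' @param range_policy what to do when the enhanced image leaves the nominal
#'   dynamic range: `"clip"` (default) clamps to `[0, 2^bit_depth - 1]`,
#'   `"rescale"` affinely maps the result onto the range only if it exceeds
#'   it, `"none"` returns raw values (possibly negative — the classical USM
#'   dark-halo defect).
#' @return an object of class `usm_params`.
#' @export
usm_params <- function(alpha_usm = 1, range_policy = c("clip", "rescale", "none")) {
  stopifnot(is.numeric(alpha_usm), length(alpha_usm) == 1L,
            is.finite(alpha_usm), alpha_usm >= 0)
  structure(list(alpha_usm = alpha_usm, range_policy = match.arg(range_policy)),
            class = "usm_params")
}

#' @export
print.usm_params <- function(x, ...) {
  cat(sprintf("<usm_params> alpha_usm=%g, range_policy=%s\n",
              x$alpha_usm, x$range_policy))
  invisible(x)
}

#' Unsharp mask of an image pair
#'
#' The raw high-frequency mask `original - smoothed`, returned un-clipped as
#' a plain signed matrix (it legitimately contains negative values).
#'
#' @param original,smoothed conformable [image2d()]s (or matrices).
#' @return a numeric matrix.
#' @export
unsharp_mask <- function(original, smoothed) {
  a <- pixels(as_image2d(original)); b <- pixels(as_image2d(smoothed))
  check_same_dim(a, b)
  a - b
}

#' Unsharp-mask enhancement
#'
#' Computes `I + alpha_usm * (I - I_smoothed)` and applies the range policy
#' of [usm_params()]. With `range_policy = "none"` the operation is exactly
#' linear in the mask.
#'
#' @param original an [image2d()].
#' @param smoothed the smoothed companion image, same size.
#' @param params a [usm_params()].
#' @return the enhanced [image2d()].
#' @export
usm_enhance <- function(original, smoothed, params = usm_params()) {
  original <- as_image2d(original)
  raw <- pixels(original) + params$alpha_usm * unsharp_mask(original, smoothed)
  top <- white_level(original)
  out <- switch(params$range_policy,
    clip = pmin(pmax(raw, 0), top),
    rescale = {
      lo <- min(raw); hi <- max(raw)
      if (lo < 0 || hi > top) {
        if (hi > lo) (raw - lo) * (top / (hi - lo)) else pmin(pmax(raw, 0), top)
      } else raw
    },
    none = raw)
  im_like(out, original)
}

#' RAD-based unsharp-mask enhancement
#'
#' The full pipeline: smooth the image with reverse anisotropic diffusion
#' ([rad_smooth()]), subtract to form the edge-selective unsharp mask, add
#' the mask back onto the original. All three stages are returned so the
#' smoothed image and the mask can be inspected alongside the enhancement.
#'
#' @param img an [image2d()].
#' @param dparams a [diffusion_params()].
#' @param uparams a [usm_params()].
#' @return an object of class `rad_usm`: a list with fields `original`,
#'   `smoothed`, `mask`, `enhanced`, `dparams`, `uparams`.
#' @examples
#' ph <- make_phantom(phantom_spec(height = 64, width = 64))
#' fit <- rad_usm(ph$img)
#' fit
#' @export
rad_usm <- function(img, dparams = diffusion_params(), uparams = usm_params()) {
  img <- as_image2d(img)
  smoothed <- rad_smooth(img, dparams)
  mask <- unsharp_mask(img, smoothed)
  enhanced <- usm_enhance(img, smoothed, uparams)
  structure(list(original = img, smoothed = smoothed, mask = mask,
                 enhanced = enhanced, dparams = dparams, uparams = uparams),
            class = "rad_usm")
}

#' @export
print.rad_usm <- function(x, ...) {
  cat(sprintf("<rad_usm> %d x %d image, alpha_diff=%g, alpha_usm=%g (%s)\n",
              nrow(x$original), ncol(x$original), x$dparams$alpha_diff,
              x$uparams$alpha_usm, x$uparams$range_policy))
  cat(sprintf("  mask range [%.4g, %.4g], EMEE %0.4g -> %0.4g\n",
              min(x$mask), max(x$mask),
              emee(x$original), emee(x$enhanced)))
  invisible(x)
}

#' Panel plot of a RAD-USM result
#'
#' Draws original, RAD-smoothed image, unsharp mask and enhancement in a
#' 2 x 2 layout.
#'
#' @param x a [rad_usm()] result.
#' @param ... ignored.
#' @export
plot.rad_usm <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  plot(x$original, main = "original")
  plot(x$smoothed, main = "RAD smoothed")
  plot(im_like(x$mask, x$original), main = "unsharp mask")
  plot(x$enhanced, main = "enhanced")
  invisible(x)
}
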