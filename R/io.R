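#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8- or 16-bit single-channel PNG or TIFF file into an [image2d()].
#' Stored integer sample values are recovered exactly — no rescaling to
#' `[0, 1]` survives into the result.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param bit_depth_hint optional nominal bit depth for the returned image
#'   (e.g. 12 for radiograph data stored in a 16-bit container). Defaults to
#'   the container's sample depth.
#' @return an [image2d()].
#' @seealso [write_image()], [read_jsrt_raw()]
#' @export
read_image <- function(path, bit_depth_hint = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- png_header(path)
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L)
      stop_fmt(sprintf("'%s' has %d channels; only single-channel grayscale is supported",
                       path, dim(arr)[3]))
    m <- round(arr * (2^hdr$bit_depth - 1))
    depth <- hdr$bit_depth
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(arr)) == 3L)
      stop_fmt(sprintf("'%s' has %d channels; only single-channel grayscale is supported",
                       path, dim(arr)[3]))
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 16L
    m <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  } else {
    stop_fmt(sprintf("unsupported image extension '.%s' (use .png, .tif or .tiff)", ext))
  }
  depth <- if (depth <= 8L) 8L else 16L
  bd <- if (is.null(bit_depth_hint)) depth else as.integer(bit_depth_hint)
  image2d(m, bit_depth = bd)
}

#' Write an image as 16-bit grayscale PNG or TIFF
#'
#' Intensities are rounded to the nearest integer and stored as 16-bit
#' samples; the container format is chosen from the file extension. Values
#' must already lie in `[0, 65535]` — out-of-range images are rejected so
#' that the caller applies an explicit range policy (see [usm_enhance()])
#' rather than being silently clipped.
#'
#' @param img an [image2d()] (or plain matrix) with values in `[0, 65535]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  m <- pixels(as_image2d(img))
  if (min(m) < 0 || max(m) > 65535)
    stop_range(sprintf(paste0("intensities [%.6g, %.6g] fall outside [0, 65535]; ",
                              "apply a range policy (clip or rescale) before writing"),
                       min(m), max(m)))
  m <- round(m)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    write_png16(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  } else {
    stop_fmt(sprintf("unsupported image extension '.%s' (use .png, .tif or .tiff)", ext))
  }
  invisible(path)
}

#' Read a raw JSRT-layout radiograph
#'
#' The JSRT chest-radiograph files are headerless 2048 x 2048 rasters of
#' 16-bit big-endian samples holding 12-bit gray scale data, stored row-major
#' from the top-left pixel. The returned image carries `bit_depth = 12` and
#' the dataset's pixel spacing of 0.175 mm x 0.171 mm.
#'
#' @param path path to a raw `.IMG` file of exactly `2048 * 2048 * 2` bytes.
#' @return an [image2d()] of size 2048 x 2048.
#' @seealso [write_jsrt_raw()]
#' @export
read_jsrt_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  n <- 2048L * 2048L
  expected <- n * 2
  actual <- file.size(path)
  if (actual != expected)
    stop_fmt(sprintf("'%s' is %d bytes; a raw JSRT image must be exactly %d (2048 x 2048 x 2)",
                     path, actual, expected))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  m <- matrix(v, nrow = 2048L, ncol = 2048L, byrow = TRUE)
  image2d(m, bit_depth = 12L, pixel_spacing_mm = c(0.175, 0.171))
}

#' Write an image in the raw JSRT layout
#'
#' Companion writer to [read_jsrt_raw()]: 16-bit big-endian samples, row-major
#' from the top-left, no header. Values must be integers in `[0, 65535]` and
#' the image must be 2048 x 2048.
#'
#' @param img an [image2d()] or matrix, 2048 x 2048, values in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jsrt_raw <- function(img, path) {
  m <- round(pixels(as_image2d(img)))
  if (!identical(dim(m), c(2048L, 2048L)))
    stop_dim(sprintf("raw JSRT images are 2048 x 2048 (got %d x %d)", nrow(m), ncol(m)))
  if (min(m) < 0 || max(m) > 65535)
    stop_range("intensities must lie in [0, 65535] for 16-bit storage")
  con <- file(path, "wb")
  on.exit(close(con))
  # row-major: emit the transpose column-by-column
  writeBin(as.integer(t(m)), con, size = 2L, endian = "big")
  invisible(path)
}

# ---- minimal 16-bit grayscale PNG encoder -----------------------------------
# No installed package writes 16-bit grayscale PNG (png::writePNG truncates to
# 8 bits), so the encoder is built here from the container primitives: one
# IHDR, one IDAT holding filter-0 scanlines deflated by memCompress (which
# emits the zlib stream PNG requires), and IEND. Round-trip against
# png::readPNG is covered in the test suite.

png_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 26L)
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(hdr) < 26L || !identical(hdr[1:8], sig))
    stop_fmt(sprintf("'%s' is not a PNG file", path))
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
          else bitwShiftR(c, 1L)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

u32_raw <- function(x) {
  # unsigned 32-bit value (double) -> 4 big-endian bytes
  x <- as.numeric(x) %% 2^32
  if (x >= 2^31) x <- x - 2^32
  writeBin(as.integer(x), raw(), size = 4L, endian = "big")
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_raw(length(data)), body,
    writeBin(crc32(body), raw(), size = 4L, endian = "big"))
}

write_png16 <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  v <- t(m)  # transpose: scanlines are image rows
  bytes <- matrix(raw(), nrow = 2L * w + 1L, ncol = h)
  bytes[1L, ] <- as.raw(0L)  # filter type 0 per scanline
  bytes[seq(2L, 2L * w, by = 2L), ] <- as.raw(v %/% 256)
  bytes[seq(3L, 2L * w + 1L, by = 2L), ] <- as.raw(v %% 256)
  ihdr <- c(u32_raw(w), u32_raw(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate, filter 0, no interlace
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(as.vector(bytes), "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
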