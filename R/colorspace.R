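#' Read a top-view pen frame as an RGB integer array
#'
#' Decodes a PNG or JPEG file into an `H x W x 3` integer array with values in
#' `[0, 255]`, channel order red-green-blue, row 0 at the top (returned 1-based
#' as usual in R).
#'
#' @param path Path to a PNG or JPEG file.
#' @return Integer array of dimension `H x W x 3`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores (x, y, channel) in [0,1]; transpose to (row, col, channel)
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  }
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
  out <- aperm(dat, c(2L, 1L, 3L))
  storage.mode(out) <- "double"
  array(as.integer(round(out * 255)), dim = dim(out))
}

#' Write an RGB integer array as PNG
#'
#' @param image `H x W x 3` integer array in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  validate_rgb_image(image)
  png::writePNG(array(image / 255, dim = dim(image)), target = path)
  invisible(path)
}

validate_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L || length(image) == 0L) {
    stop("`image` is empty", call. = FALSE)
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 255) {
    stop("`image` values must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

# sRGB gamma expansion to linear light, input in [0,1]
srgb_to_linear <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

# CIE f() used by the Lab transform
lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Extract a diagnostic chroma plane from an RGB image
#'
#' Computes one of the three chroma components this package segments with:
#' * `"Cb"` — blue-difference chroma of full-range BT.601 YCbCr,
#'   `Cb = 128 - 0.168736 R - 0.331264 G + 0.5 B` on 0-255 RGB. Yellow-brown
#'   plumage falls well below 128; achromatic litter sits at 128.
#' * `"b"` — the CIELAB yellow-blue opponent axis b*, computed through sRGB
#'   gamma expansion, the D65 XYZ transform and the CIE f() nonlinearity.
#'   Strongly positive for plumage, near zero for achromatic litter.
#' * `"Q"` — the NTSC YIQ quadrature chroma axis,
#'   `Q = 0.211456 R - 0.522591 G + 0.311135 B` on RGB normalized to `[0, 1]`;
#'   separates plumage from the similarly yellow feeders and drinkers.
#'
#' All conversions are carried out in double precision with no quantization,
#' so thresholds learned on these planes are not aliased to a grid.
#'
#' @param image `H x W x 3` integer array in `[0, 255]` (see [read_rgb_image()]).
#' @param channel One of `"Cb"`, `"b"`, `"Q"`.
#' @return An `H x W` numeric matrix with attribute `channel_id`.
#' @examples
#' gray <- array(128L, dim = c(2, 2, 3))
#' extract_component(gray, "Cb")[1, 1]  # 128: achromatic axis
#' @export
extract_component <- function(image, channel = c("Cb", "b", "Q")) {
  channel <- match.arg(channel)
  validate_rgb_image(image)
  d <- dim(image)
  r <- matrix(as.numeric(image[, , 1]), d[1], d[2])
  g <- matrix(as.numeric(image[, , 2]), d[1], d[2])
  b <- matrix(as.numeric(image[, , 3]), d[1], d[2])
  out <- switch(channel,
    Cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
    Q = (0.211456 * r - 0.522591 * g + 0.311135 * b) / 255,
    b = {
      rl <- srgb_to_linear(r / 255)
      gl <- srgb_to_linear(g / 255)
      bl <- srgb_to_linear(b / 255)
      # D65 reference white (sRGB primaries)
      y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
      z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
      200 * (lab_f(y) - lab_f(z / 1.088830))
    }
  )
  attr(out, "channel_id") <- channel
  out
}
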