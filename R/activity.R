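#' Accumulate per-frame masks into an occupancy map
#'
#' Sums a sequence of binary masks pixel-wise: `counts[p]` is the number of
#' frames in which pixel `p` was broiler foreground. With the one-frame-per-
#' minute cadence and one-hour analysis periods, counts run from 0 (never
#' occupied) to 60 (occupied the whole hour).
#'
#' @param masks List of `H x W` binary matrices (may be empty). An empty list
#'   needs `dim` to size the zero map.
#' @param dim `c(H, W)`, required only when `masks` is empty.
#' @return An `occupancy` object: list with `counts` (integer matrix) and
#'   `n_frames`.
#' @export
accumulate_masks <- function(masks, dim = NULL) {
  stopifnot(is.list(masks))
  if (length(masks) == 0L) {
    if (is.null(dim)) stop("`dim` is required for an empty mask list", call. = FALSE)
    return(new_occupancy(matrix(0L, dim[1], dim[2]), 0L))
  }
  d <- base::dim(masks[[1]])
  counts <- matrix(0L, d[1], d[2])
  for (m in masks) {
    validate_mask(m)
    if (!identical(base::dim(m), d)) {
      stop("all masks must share the same shape", call. = FALSE)
    }
    counts <- counts + m
  }
  new_occupancy(counts, length(masks))
}

new_occupancy <- function(counts, n_frames) {
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, n_frames = as.integer(n_frames)),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  cat(sprintf("Occupancy map: %d x %d pixels over %d frames (max count %d)\n",
              nrow(x$counts), ncol(x$counts), x$n_frames, max(x$counts, 0L)))
  invisible(x)
}

#' Band-ratio activity index of an occupancy map
#'
#' The activity index is the fraction of pixels whose occupancy count lies in
#' the inclusive band `[band_lo, band_hi]`. The default band 10-49 (with 60
#' frames per period) excludes both never-visited floor and perpetually
#' occupied areas where birds gather and lie for a long time, so it measures
#' genuine movement rather than resting density.
#'
#' @param occ An `occupancy` object from [accumulate_masks()].
#' @param band_lo,band_hi Inclusive band bounds (defaults 10 and 49).
#' @return One-row tibble: `index`, `band_lo`, `band_hi`, `n_pixels_in_band`,
#'   `total_pixels`, `n_frames`.
#' @export
activity_index <- function(occ, band_lo = 10L, band_hi = 49L) {
  stopifnot(inherits(occ, "occupancy"))
  band_lo <- as.integer(band_lo)
  band_hi <- as.integer(band_hi)
  if (band_lo > band_hi) stop("band_lo must be <= band_hi", call. = FALSE)
  if (band_lo < 0L) stop("band_lo must be >= 0", call. = FALSE)
  n_in <- sum(occ$counts >= band_lo & occ$counts <= band_hi)
  total <- length(occ$counts)
  tibble::tibble(index = n_in / total, band_lo = band_lo, band_hi = band_hi,
                 n_pixels_in_band = n_in, total_pixels = total,
                 n_frames = occ$n_frames)
}

# Fixed perceptual colormap for heat maps; 0..n_frames mapped over 256 colors.
heatmap_palette <- function(n = 256L) {
  grDevices::hcl.colors(n, palette = "viridis")
}

#' Render an occupancy heat map to PNG
#'
#' Writes the count map on a fixed `0..n_frames` color scale with a vertical
#' color bar on the right. Re-rendering the same accumulator writes identical
#' bytes.
#'
#' @param occ An `occupancy` object.
#' @param path Output PNG path.
#' @param bar_width Width of the color bar strip in pixels (default 12, plus a
#'   2-pixel white gutter).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(occ, path, bar_width = 12L) {
  stopifnot(inherits(occ, "occupancy"))
  pal <- heatmap_palette()
  top <- max(occ$n_frames, 1L)
  idx <- pmin(255L, as.integer(floor(occ$counts / top * 255)))  # 0..255
  cols <- grDevices::col2rgb(pal) / 255
  h <- nrow(occ$counts)
  w <- ncol(occ$counts)
  img <- array(1, dim = c(h, w + 2L + bar_width, 3))
  for (k in 1:3) {
    img[, seq_len(w), k] <- matrix(cols[k, idx + 1L], h, w)
  }
  # color bar: top row = top of scale
  bar_idx <- as.integer(round(seq(255, 0, length.out = h)))
  for (k in 1:3) {
    img[, w + 2L + seq_len(bar_width), k] <- matrix(cols[k, bar_idx + 1L],
                                                    h, bar_width)
  }
  png::writePNG(img, target = path)
  invisible(path)
}

#' Tidy an occupancy map to a long pixel table
#'
#' @param x An `occupancy` object.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `count`.
#' @method tidy occupancy
#' @export
tidy.occupancy <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$counts)), times = ncol(x$counts)),
    col = rep(seq_len(ncol(x$counts)), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occupancy heat map with ggplot2
#'
#' @param object An `occupancy` object.
#' @param band Optional length-2 integer vector; if given, the subtitle
#'   reports the band-ratio activity index for that band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot occupancy
#' @export
autoplot.occupancy <- function(object, band = NULL, ...) {
  df <- tidy(object)
  sub <- NULL
  if (!is.null(band)) {
    ai <- activity_index(object, band[1], band[2])
    sub <- sprintf("activity index [%d, %d] = %.3f", band[1], band[2], ai$index)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(object$n_frames, 1L)),
                                  name = "frames") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Flock occupancy",
                  subtitle = sub) +
    ggplot2::theme_minimal()
}
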