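#' Apply the three-channel color rule to a frame
#'
#' Produces the raw per-pixel broiler-body mask: a pixel is foreground iff its
#' Cb value is below `T_Cb` AND its b* value is above `T_b` (both reject the
#' near-achromatic litter, walls and pipes) AND its Q value is below `T_Q`
#' (rejects the similarly colored feeders and drinkers). Purely per-pixel and
#' deterministic.
#'
#' `eq2_verbatim = TRUE` flips the Cb and b inequalities (`Cb > T_Cb`,
#' `b < T_b`, `Q < T_Q`). That orientation contradicts the class sides the
#' thresholds are learned on and selects litter instead of plumage on the two
#' chroma-against-litter tests; it is kept only as an auditable switch.
#'
#' @param image `H x W x 3` integer array in `[0, 255]`.
#' @param thresholds A `threshold_set` from [learn_threshold_set()], or any
#'   list with numeric `T_b`, `T_Cb`, `T_Q`.
#' @param eq2_verbatim Use the inverted Cb/b orientation (default `FALSE`).
#' @return `H x W` integer matrix in `{0, 1}`; 1 = broiler body.
#' @export
apply_thresholds <- function(image, thresholds, eq2_verbatim = FALSE) {
  validate_rgb_image(image)
  stopifnot(is.list(thresholds),
            all(c("T_b", "T_Cb", "T_Q") %in% names(thresholds)))
  cb <- extract_component(image, "Cb")
  bb <- extract_component(image, "b")
  qq <- extract_component(image, "Q")
  keep <- if (isTRUE(eq2_verbatim)) {
    cb > thresholds$T_Cb & bb < thresholds$T_b & qq < thresholds$T_Q
  } else {
    cb < thresholds$T_Cb & bb > thresholds$T_b & qq < thresholds$T_Q
  }
  m <- matrix(0L, nrow(cb), ncol(cb))
  m[keep] <- 1L
  m
}

#' Morphological refinement parameters
#'
#' @param se_radius Disk structuring-element radius in pixels for the closing
#'   and opening stages (default 3).
#' @param min_object_area Connected components (8-connectivity) smaller than
#'   this many pixels are removed (default 50).
#' @param max_hole_area Background holes (4-connectivity, not touching the
#'   border) of at most this many pixels are filled (default 200).
#' @return A `morph_params` list.
#' @details Defaults are sized for the package's 384 x 216 working resolution;
#'   use [default_morph_params()] to rescale them to another frame size.
#' @export
morph_params <- function(se_radius = 3L, min_object_area = 50L,
                         max_hole_area = 200L) {
  se_radius <- as.integer(se_radius)
  min_object_area <- as.integer(min_object_area)
  max_hole_area <- as.integer(max_hole_area)
  stopifnot(se_radius >= 0L, min_object_area >= 0L, max_hole_area >= 0L)
  structure(list(se_radius = se_radius, min_object_area = min_object_area,
                 max_hole_area = max_hole_area),
            class = "morph_params")
}

#' Refinement defaults scaled to a frame size
#'
#' Linear measures (structuring-element radius) scale with the linear zoom
#' factor relative to the 384 x 216 reference resolution; areas scale with its
#' square.
#'
#' @param image_dim `c(H, W)` of the frames to be refined.
#' @return A `morph_params` list.
#' @export
default_morph_params <- function(image_dim = c(216L, 384L)) {
  s <- sqrt((image_dim[1] * image_dim[2]) / (216 * 384))
  morph_params(se_radius = max(1L, as.integer(round(3 * s))),
               min_object_area = max(1L, as.integer(round(50 * s^2))),
               max_hole_area = max(1L, as.integer(round(200 * s^2))))
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L))) {
    stop("`mask` must be a binary (0/1) matrix", call. = FALSE)
  }
  invisible(mask)
}

# Label 8-connected foreground components via the pixel adjacency graph.
# Returns an integer matrix of labels (0 = background).
label_components8 <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  fg <- which(mask == 1L)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  pos <- integer(h * w)
  pos[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]
    c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- pos[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(pos[fg[ok]][hit], pos[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  lab[fg] <- igraph::components(g)$membership
  lab
}

ebi_from_mask <- function(mask) t(mask)
ebi_to_mask <- function(x) {
  m <- t(EBImage::imageData(x))
  storage.mode(m) <- "integer"
  m
}

# Remove 8-connected foreground components smaller than min_area pixels.
remove_small_objects <- function(mask, min_area) {
  if (min_area <= 1L) return(mask)
  lab <- label_components8(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab)
  drop <- which(sizes < min_area)
  if (length(drop)) mask[lab %in% drop] <- 0L
  mask
}

# Fill 4-connected background holes (not touching the border) of area <= max_area.
fill_small_holes <- function(mask, max_area) {
  if (max_area <= 0L) return(mask)
  bg <- 1L - mask
  lab <- EBImage::bwlabel(ebi_from_mask(bg))  # 4-connectivity
  lab <- t(EBImage::imageData(lab))
  if (max(lab) == 0L) return(mask)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab)
  fill <- setdiff(which(sizes <= max_area), border_labs)
  if (length(fill)) mask[lab %in% fill] <- 1L
  mask
}

#' Morphologically refine a raw threshold mask
#'
#' Applies, in order: removal of small 8-connected components
#' (`< min_object_area` px), morphological closing with a disk of radius
#' `se_radius`, morphological opening with the same disk, and filling of
#' enclosed background holes of area `<= max_hole_area` px. A parameter of 0
#' (radius 0, area 0) turns the corresponding stage into the identity.
#'
#' @param mask `H x W` binary (0/1) matrix.
#' @param params A [morph_params()] list.
#' @return Refined binary matrix of the same shape.
#' @export
refine_mask <- function(mask, params = morph_params()) {
  validate_mask(mask)
  stopifnot(inherits(params, "morph_params") || is.list(params))
  out <- mask
  out <- remove_small_objects(out, params$min_object_area)
  if (params$se_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$se_radius + 1L, shape = "disc")
    out <- ebi_to_mask(EBImage::closing(ebi_from_mask(out), brush))
    out <- ebi_to_mask(EBImage::opening(ebi_from_mask(out), brush))
  }
  out <- fill_small_holes(out, params$max_hole_area)
  storage.mode(out) <- "integer"
  out
}

#' Read / write binary masks as single-channel PNG
#'
#' Masks are persisted with foreground = 255, background = 0.
#'
#' @param mask `H x W` binary matrix.
#' @param path PNG path.
#' @return `write_mask()`: `path` invisibly; `read_mask()`: a binary matrix.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  out <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  out
}
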