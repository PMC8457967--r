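#' Draw labeled pixel samples from rectangular patches
#'
#' Builds one class's training sample for threshold learning: the requested
#' chroma component is evaluated over the union of the given square patches and
#' `n_samples` pixel values are drawn uniformly without replacement, seeded for
#' reproducibility. This mirrors the field workflow of marking small
#' single-material patches (litter, broiler body, feeder) on a few calibration
#' frames and sampling pixels from them.
#'
#' @param image `H x W x 3` integer array in `[0, 255]`.
#' @param patch_origins Data frame (or tibble) with columns `row`, `col`: the
#'   1-based top-left corner of each `patch_size x patch_size` patch.
#' @param patch_size Side length of each square patch, pixels (default 20).
#' @param channel One of `"Cb"`, `"b"`, `"Q"` (see [extract_component()]).
#' @param class_label Material class of the patches: `"litter"`, `"body"` or
#'   `"feeder"`.
#' @param n_samples Number of pixel values to draw (default 100).
#' @param seed Integer seed for the draw; `NULL` uses the session RNG state.
#' @return A tibble with columns `value`, `channel`, `class` and `n_samples`
#'   rows.
#' @export
extract_patch_samples <- function(image, patch_origins, patch_size = 20L,
                                  channel = c("Cb", "b", "Q"),
                                  class_label = c("litter", "body", "feeder"),
                                  n_samples = 100L, seed = NULL) {
  channel <- match.arg(channel)
  class_label <- match.arg(class_label)
  validate_rgb_image(image)
  stopifnot(is.data.frame(patch_origins), all(c("row", "col") %in% names(patch_origins)))
  patch_size <- as.integer(patch_size)
  d <- dim(image)
  if (any(patch_origins$row < 1L) || any(patch_origins$col < 1L) ||
      any(patch_origins$row + patch_size - 1L > d[1]) ||
      any(patch_origins$col + patch_size - 1L > d[2])) {
    stop("patch out of image bounds", call. = FALSE)
  }
  plane <- extract_component(image, channel)
  offs <- expand.grid(dr = 0:(patch_size - 1L), dc = 0:(patch_size - 1L))
  idx <- unlist(purrr::map2(patch_origins$row, patch_origins$col, function(r0, c0) {
    (c0 + offs$dc - 1L) * d[1] + (r0 + offs$dr)
  }))
  idx <- unique(idx)  # overlapping patches contribute each pixel once
  if (n_samples > length(idx)) {
    stop("n_samples exceeds the number of available patch pixels (",
         length(idx), ")", call. = FALSE)
  }
  if (!is.null(seed)) {
    take <- withr::with_seed(as.integer(seed), sample(idx, n_samples))
  } else {
    take <- sample(idx, n_samples)
  }
  tibble::tibble(value = plane[take], channel = channel, class = class_label)
}

#' Learn one separating cut between two labeled sample sets
#'
#' Finds the cut value `T` maximizing the number of correctly classified
#' samples, `score(T) = #\{v in class_lo : v < T\} + #\{v in class_hi : v > T\}`.
#' Candidate cuts are the midpoints between consecutive distinct values of the
#' pooled sample, plus one candidate below the minimum and one above the
#' maximum. The score is piecewise constant between sample values, so this grid
#' is exhaustive. Ties among maximal candidates are broken deterministically:
#' the midpoint of the widest maximal gap wins, then the lowest-valued one
#' (the two outer candidates count as width zero).
#'
#' @param class_lo Numeric vector: samples of the class expected below the cut.
#' @param class_hi Numeric vector: samples of the class expected above the cut.
#' @return The cut value, a length-1 double with attribute `score` (the number
#'   of correctly classified samples at the cut).
#' @examples
#' learn_threshold(c(1, 2, 3), c(5, 6, 7))  # 4, the widest-gap midpoint
#' @export
learn_threshold <- function(class_lo, class_hi) {
  class_lo <- as.numeric(class_lo)
  class_hi <- as.numeric(class_hi)
  if (length(class_lo) < 1L || length(class_hi) < 1L) {
    stop("both sample sets must be nonempty", call. = FALSE)
  }
  if (!all(is.finite(class_lo)) || !all(is.finite(class_hi))) {
    stop("sample values must be finite", call. = FALSE)
  }
  v <- sort(unique(c(class_lo, class_hi)))
  if (length(v) == 1L) {
    cand <- c(v - 1, v + 1)
    width <- c(0, 0)
  } else {
    mids <- (v[-length(v)] + v[-1]) / 2
    cand <- c(v[1] - 1, mids, v[length(v)] + 1)
    width <- c(0, diff(v), 0)
  }
  score <- vapply(cand, function(t) {
    sum(class_lo < t) + sum(class_hi > t)
  }, numeric(1))
  best <- which(score == max(score))
  best <- best[order(-width[best], cand[best])][1]
  out <- cand[best]
  attr(out, "score") <- as.integer(score[best])
  out
}

#' Learn the full three-channel threshold set
#'
#' Learns the three cuts of the segmentation rule from a labeled sample table:
#' * `T_b` (CIELAB b*): litter below, broiler body above;
#' * `T_Cb` (YCbCr Cb): broiler body below, litter above;
#' * `T_Q` (YIQ Q): broiler body below, feeder/drinker above.
#'
#' @param samples Tibble with columns `value`, `channel` (`"Cb"`, `"b"`, `"Q"`)
#'   and `class` (`"litter"`, `"body"`, `"feeder"`), e.g. several
#'   [extract_patch_samples()] results row-bound together. Required pairs:
#'   litter+body for `b` and `Cb`, body+feeder for `Q`.
#' @return A `threshold_set` object: list with elements `T_b`, `T_Cb`, `T_Q`
#'   and a `scores` tibble.
#' @export
learn_threshold_set <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("value", "channel", "class") %in% names(samples)))
  pull_set <- function(ch, cl) {
    v <- samples$value[samples$channel == ch & samples$class == cl]
    if (length(v) < 1L) {
      stop("no samples for channel ", ch, ", class ", cl, call. = FALSE)
    }
    v
  }
  t_b <- learn_threshold(pull_set("b", "litter"), pull_set("b", "body"))
  t_cb <- learn_threshold(pull_set("Cb", "body"), pull_set("Cb", "litter"))
  t_q <- learn_threshold(pull_set("Q", "body"), pull_set("Q", "feeder"))
  structure(
    list(
      T_b = as.numeric(t_b), T_Cb = as.numeric(t_cb), T_Q = as.numeric(t_q),
      scores = tibble::tibble(
        channel = c("b", "Cb", "Q"),
        class_lo = c("litter", "body", "body"),
        class_hi = c("body", "litter", "feeder"),
        threshold = c(as.numeric(t_b), as.numeric(t_cb), as.numeric(t_q)),
        score = c(attr(t_b, "score"), attr(t_cb, "score"), attr(t_q, "score"))
      )
    ),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Color threshold set (broiler-body segmentation)\n")
  cat(sprintf("  T_b  = %8.3f  (body: b*  > T_b)\n", x$T_b))
  cat(sprintf("  T_Cb = %8.3f  (body: Cb  < T_Cb)\n", x$T_Cb))
  cat(sprintf("  T_Q  = %8.4f  (body: Q   < T_Q)\n", x$T_Q))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a learned threshold set
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return A tibble with one row per channel: `channel`, `class_lo`,
#'   `class_hi`, `threshold`, `score`.
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  x$scores
}
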