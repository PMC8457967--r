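# Shared small fixtures, built once per test run.

# single-color image helper
uniform_image <- function(rgb, h = 4L, w = 5L) {
  img <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) img[, , k] <- as.integer(rgb[k])
  img
}

# a small rendered scene with its truth mask and state, shared across files
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_flock(n_birds = 10L, n_frames = 1L, step_sigma = 0,
                            seed = 42L, size = c(108L, 192L))
      cache <<- list(frame = sim$frames[[1]], mask = sim$masks[[1]],
                     state = sim$state0)
    }
    cache
  }
})

# thresholds learned from patches on the tiny scene
tiny_thresholds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- tiny_scene()
      cache <<- learn_thresholds_from_scene(sc$state, sc$frame, sc$mask, seed = 1L)
    }
    cache
  }
})

# convenience: full patch-sample -> threshold-set path on a rendered scene
learn_thresholds_from_scene <- function(state, frame, mask, seed = 1L,
                                        patch_size = 5L, n_patches = 40L,
                                        n_samples = 100L) {
  patches <- list(
    litter = propose_patches(state, "litter", patch_size, n_patches,
                             seed, truth_mask = mask),
    body = propose_patches(state, "body", patch_size, n_patches,
                           seed + 1L, truth_mask = mask),
    feeder = propose_patches(state, "feeder", patch_size, n_patches,
                             seed + 2L, truth_mask = mask))
  spec <- list(litter = c("Cb", "b"), body = c("Cb", "b", "Q"), feeder = "Q")
  samples <- purrr::imap(spec, function(channels, cls) {
    purrr::map(channels, function(ch) {
      extract_patch_samples(frame, patches[[cls]], patch_size = patch_size,
                            channel = ch, class_label = cls,
                            n_samples = n_samples, seed = seed + 10L)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  learn_threshold_set(samples)
}

# brute-force oracle for the cut learner: scan a dense grid of candidates
brute_force_best_score <- function(lo, hi) {
  v <- sort(unique(c(lo, hi)))
  cand <- c(v[1] - 1, v + 1e-9, v - 1e-9,
            if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
            v[length(v)] + 1)
  max(vapply(cand, function(t) sum(lo < t) + sum(hi > t), numeric(1)))
}

# random binary mask with blobs plus salt noise
random_mask <- function(h = 40L, w = 50L, n_blobs = 3L, p_salt = 0.02) {
  m <- matrix(0L, h, w)
  for (i in seq_len(n_blobs)) {
    r <- sample(5:(h - 5), 1)
    c <- sample(5:(w - 5), 1)
    rad <- sample(2:4, 1)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    m[(rows - r)^2 + (cols - c)^2 <= rad^2] <- 1L
  }
  m[matrix(stats::runif(h * w) < p_salt, h, w)] <- 1L
  m
}

expect_binary_mask <- function(m, dims = NULL) {
  expect_true(is.matrix(m))
  expect_true(all(m %in% c(0L, 1L)))
  if (!is.null(dims)) expect_identical(dim(m), as.integer(dims))
}
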