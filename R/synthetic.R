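#' Default color palette of a synthetic pen scene
#'
#' Base RGB colors for each scene material plus a per-pixel Gaussian jitter
#' sigma (applied independently per channel at render time). The defaults
#' emulate a floor pen: black/white litter speckle, brown and buff plumage,
#' and feeder/drinker colors deliberately close to the plumage in the Cb and
#' b* chroma planes while separated on the Q axis — the configuration that
#' motivates using a third color model at all.
#'
#' @param litter_dark,litter_light,plumage_primary,plumage_secondary,feeder,drinker,wall
#'   Length-3 integer RGB vectors in `[0, 255]`.
#' @param jitter_sigma Per-channel Gaussian noise s.d. in RGB units
#'   (default 5).
#' @return A `scene_palette` list.
#' @export
scene_palette <- function(litter_dark = c(40, 38, 36),
                          litter_light = c(205, 205, 202),
                          plumage_primary = c(160, 110, 50),
                          plumage_secondary = c(215, 185, 120),
                          feeder = c(200, 90, 60),
                          drinker = c(190, 60, 50),
                          wall = c(235, 235, 235),
                          jitter_sigma = 5) {
  pal <- list(litter_dark = litter_dark, litter_light = litter_light,
              plumage_primary = plumage_primary,
              plumage_secondary = plumage_secondary,
              feeder = feeder, drinker = drinker, wall = wall,
              jitter_sigma = jitter_sigma)
  for (nm in setdiff(names(pal), "jitter_sigma")) {
    stopifnot(length(pal[[nm]]) == 3L, all(pal[[nm]] >= 0), all(pal[[nm]] <= 255))
  }
  stopifnot(jitter_sigma >= 0)
  structure(pal, class = "scene_palette")
}

#' Initial flock state for the scene generator
#'
#' Bird centers are drawn uniformly inside the arena (the pen minus the wall
#' border), headings uniformly on the circle. Default flock size 44 matches a
#' small floor pen stocked in the low-forties; default body semi-axes 13 x 8
#' pixels correspond to a ~20 cm bird at the 384 x 216 working resolution
#' (about 132 px/m for a 2.9 m pen side).
#'
#' @param n_birds Number of birds (default 44).
#' @param size `c(H, W)` frame size in pixels (default `c(216, 384)`).
#' @param axes Length-2 ellipse semi-axes (major, minor) in pixels.
#' @param wall_width Wall border width in pixels (default 6).
#' @param seed Integer seed.
#' @return A `flock_state` list: `n_birds`, `positions` (n x 2 matrix of
#'   (row, col)), `axes`, `headings`, `size`, `wall_width`.
#' @export
flock_state <- function(n_birds = 44L, size = c(216L, 384L),
                        axes = c(13, 8), wall_width = 6L, seed = 1L) {
  stopifnot(n_birds >= 0L, length(size) == 2L, length(axes) == 2L)
  if (2 * max(axes) >= min(size) - 2 * wall_width) {
    stop("bird larger than arena", call. = FALSE)
  }
  lo <- wall_width + max(axes) + 1
  hi_r <- size[1] - wall_width - max(axes)
  hi_c <- size[2] - wall_width - max(axes)
  withr::with_seed(as.integer(seed), {
    pos <- cbind(stats::runif(n_birds, lo, hi_r), stats::runif(n_birds, lo, hi_c))
    headings <- stats::runif(n_birds, 0, 2 * pi)
  })
  structure(list(n_birds = as.integer(n_birds), positions = pos, axes = axes,
                 headings = headings, size = as.integer(size),
                 wall_width = as.integer(wall_width)),
            class = "flock_state")
}

# Rasterize one filled rotated ellipse into a logical matrix.
rasterize_ellipse <- function(h, w, center, axes, heading) {
  r0 <- max(1L, floor(center[1] - max(axes))); r1 <- min(h, ceiling(center[1] + max(axes)))
  c0 <- max(1L, floor(center[2] - max(axes))); c1 <- min(w, ceiling(center[2] + max(axes)))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1
  cc <- c0:c1
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  u <- dr * cos(heading) + dc * sin(heading)
  v <- -dr * sin(heading) + dc * cos(heading)
  inside <- (u / axes[1])^2 + (v / axes[2])^2 <= 1
  list(rows = rr, cols = cc, inside = inside)
}

paint <- function(img, sel, color) {
  for (k in 1:3) {
    plane <- img[, , k]
    plane[sel] <- color[k]
    img[, , k] <- plane
  }
  img
}

#' Render one synthetic pen frame with ground truth
#'
#' Draws, in order: black/white litter speckle, the wall border, one feeder
#' disk and one drinker disk at fixed positions, then each bird as a rotated
#' ellipse textured with the two plumage colors (primary body, secondary
#' head-end cap). Per-pixel Gaussian jitter is added last and clipped to
#' `[0, 255]`. The returned truth mask marks exactly the bird pixels.
#'
#' @param state A [flock_state()].
#' @param palette A [scene_palette()].
#' @param seed Integer seed for speckle, texture and jitter.
#' @return List: `image` (`H x W x 3` integer array), `mask` (binary matrix).
#' @export
render_frame <- function(state, palette = scene_palette(), seed = 1L) {
  stopifnot(inherits(state, "flock_state"), inherits(palette, "scene_palette"))
  h <- state$size[1]
  w <- state$size[2]
  withr::with_seed(as.integer(seed), {
    img <- array(0, dim = c(h, w, 3))
    # litter speckle: dark/light patches at ~40/60 mix
    speck <- matrix(stats::runif(h * w) < 0.4, h, w)
    for (k in 1:3) {
      img[, , k] <- ifelse(speck, palette$litter_dark[k], palette$litter_light[k])
    }
    ww <- state$wall_width
    if (ww > 0L) {
      border <- matrix(FALSE, h, w)
      border[c(1:ww, (h - ww + 1):h), ] <- TRUE
      border[, c(1:ww, (w - ww + 1):w)] <- TRUE
      img <- paint(img, border, palette$wall)
    }
    # fixed feeder and drinker disks
    equip <- list(feeder = list(center = c(0.30 * h, 0.25 * w), r = 0.09 * min(h, w)),
                  drinker = list(center = c(0.70 * h, 0.75 * w), r = 0.07 * min(h, w)))
    for (nm in names(equip)) {
      e <- equip[[nm]]
      el <- rasterize_ellipse(h, w, e$center, c(e$r, e$r), 0)
      sel <- matrix(FALSE, h, w)
      sel[el$rows, el$cols][el$inside] <- TRUE
      img <- paint(img, sel, palette[[nm]])
    }
    mask <- matrix(0L, h, w)
    if (state$n_birds > 0L) {
      for (i in seq_len(state$n_birds)) {
        el <- rasterize_ellipse(h, w, state$positions[i, ], state$axes,
                                state$headings[i])
        if (is.null(el)) next
        sel <- matrix(FALSE, h, w)
        sel[el$rows, el$cols][el$inside] <- TRUE
        # head-end cap in the secondary plumage color
        u <- outer(el$rows - state$positions[i, 1], rep(1, length(el$cols))) *
          cos(state$headings[i]) +
          outer(rep(1, length(el$rows)), el$cols - state$positions[i, 2]) *
          sin(state$headings[i])
        cap <- matrix(FALSE, h, w)
        cap[el$rows, el$cols][el$inside & u > 0.5 * state$axes[1]] <- TRUE
        img <- paint(img, sel, palette$plumage_primary)
        img <- paint(img, cap, palette$plumage_secondary)
        mask[sel] <- 1L
      }
    }
    if (palette$jitter_sigma > 0) {
      img <- img + array(stats::rnorm(h * w * 3, 0, palette$jitter_sigma),
                         dim = c(h, w, 3))
    }
    img <- pmin(pmax(round(img), 0), 255)
  })
  storage.mode(img) <- "integer"
  list(image = img, mask = mask)
}

#' Simulate a moving flock over one analysis period
#'
#' Bird centers follow independent Gaussian random walks reflected at the
#' arena bounds; one frame is rendered per step (the one-frame-per-minute
#' cadence makes 60 frames a one-hour period). Returns the frames, the truth
#' masks and the truth occupancy count map (their pixel-wise sum).
#'
#' @param n_birds Number of birds (default 44).
#' @param n_frames Number of frames (default 60, one per minute for an hour).
#' @param step_sigma Per-frame s.d. of each center coordinate, pixels
#'   (default 6; a ~25 cm/min wander at the default scale).
#' @param seed Integer seed.
#' @param size `c(H, W)` frame size (default `c(216, 384)`).
#' @param palette A [scene_palette()].
#' @param axes Bird ellipse semi-axes.
#' @return List: `frames` (list of RGB arrays), `masks` (list of binary
#'   matrices), `occupancy` (an `occupancy` object), `state0` (initial
#'   [flock_state()]).
#' @export
simulate_flock <- function(n_birds = 44L, n_frames = 60L, step_sigma = 6,
                           seed = 1L, size = c(216L, 384L),
                           palette = scene_palette(), axes = c(13, 8)) {
  stopifnot(n_frames >= 0L, step_sigma >= 0)
  state <- flock_state(n_birds = n_birds, size = size, axes = axes, seed = seed)
  ww <- state$wall_width
  lo <- ww + max(axes) + 1
  hi <- c(size[1], size[2]) - ww - max(axes)
  reflect <- function(p, lo, hi) {
    # reflect into [lo, hi]
    span <- hi - lo
    q <- (p - lo) %% (2 * span)
    lo + ifelse(q > span, 2 * span - q, q)
  }
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  st <- state
  step_seeds <- withr::with_seed(as.integer(seed),
                                 sample.int(.Machine$integer.max, max(1L, n_frames)))
  for (t in seq_len(n_frames)) {
    fr <- render_frame(st, palette, seed = step_seeds[t])
    frames[[t]] <- fr$image
    masks[[t]] <- fr$mask
    if (st$n_birds > 0L && step_sigma > 0) {
      st$positions <- withr::with_seed(step_seeds[t] %/% 2L + t, {
        cbind(reflect(st$positions[, 1] + stats::rnorm(st$n_birds, 0, step_sigma),
                      lo, hi[1]),
              reflect(st$positions[, 2] + stats::rnorm(st$n_birds, 0, step_sigma),
                      lo, hi[2]))
      })
    }
  }
  occ <- accumulate_masks(masks, dim = size)
  list(frames = frames, masks = masks, occupancy = occ, state0 = state)
}

#' Propose labeled training patches from a synthetic scene
#'
#' Finds patch origins whose full `patch_size` square lies inside one material
#' class of a rendered scene (bird body, litter, or feeder/drinker), using the
#' generator's own geometry, and samples `n_patches` of them. This stands in
#' for an annotator marking single-material rectangles on calibration frames.
#'
#' @param state The [flock_state()] the frame was rendered from.
#' @param class_label `"body"`, `"litter"` or `"feeder"`.
#' @param patch_size Patch side, pixels (default 5; synthetic birds are small).
#' @param n_patches Number of origins to return (default 40).
#' @param seed Integer seed.
#' @param truth_mask The frame's truth mask (required for `"body"`/`"litter"`).
#' @return Tibble with columns `row`, `col`.
#' @export
propose_patches <- function(state, class_label = c("body", "litter", "feeder"),
                            patch_size = 5L, n_patches = 40L, seed = 1L,
                            truth_mask = NULL) {
  class_label <- match.arg(class_label)
  h <- state$size[1]
  w <- state$size[2]
  region <- switch(class_label,
    body = {
      stopifnot(!is.null(truth_mask))
      truth_mask == 1L
    },
    litter = {
      stopifnot(!is.null(truth_mask))
      reg <- truth_mask == 0L
      ww <- state$wall_width
      reg[c(1:(ww + 1), (h - ww):h), ] <- FALSE
      reg[, c(1:(ww + 1), (w - ww):w)] <- FALSE
      # exclude feeder/drinker neighborhoods
      fe <- c(0.30 * h, 0.25 * w); fr <- 0.09 * min(h, w) + patch_size
      dr <- c(0.70 * h, 0.75 * w); drr <- 0.07 * min(h, w) + patch_size
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      reg[(rows - fe[1])^2 + (cols - fe[2])^2 <= fr^2] <- FALSE
      reg[(rows - dr[1])^2 + (cols - dr[2])^2 <= drr^2] <- FALSE
      reg
    },
    feeder = {
      reg <- matrix(FALSE, h, w)
      fe <- c(0.30 * h, 0.25 * w); fr <- 0.09 * min(h, w)
      dr <- c(0.70 * h, 0.75 * w); drr <- 0.07 * min(h, w)
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      reg[(rows - fe[1])^2 + (cols - fe[2])^2 <= fr^2] <- TRUE
      reg[(rows - dr[1])^2 + (cols - dr[2])^2 <= drr^2] <- TRUE
      if (!is.null(truth_mask)) reg[truth_mask == 1L] <- FALSE
      reg
    })
  # origins whose full patch fits inside the region, via an integral image
  ps <- as.integer(patch_size)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1, -1] <- apply(apply(region * 1, 2, cumsum), 1, cumsum) |> t()
  nr <- h - ps + 1L
  nc <- w - ps + 1L
  win <- S[(1:nr) + ps, (1:nc) + ps, drop = FALSE] -
    S[1:nr, (1:nc) + ps, drop = FALSE] -
    S[(1:nr) + ps, 1:nc, drop = FALSE] +
    S[1:nr, 1:nc, drop = FALSE]
  full_idx <- which(win == ps * ps, arr.ind = TRUE)
  if (nrow(full_idx) == 0L) {
    stop("no full ", class_label, " patch of size ", ps, " found", call. = FALSE)
  }
  take <- withr::with_seed(as.integer(seed),
                           sample(nrow(full_idx), min(n_patches, nrow(full_idx))))
  tibble::tibble(row = as.integer(full_idx[take, 1]),
                 col = as.integer(full_idx[take, 2]))
}

#' Simulate paired per-period THI and ammonia series
#'
#' Draws `(THI, NH3)` pairs from a Gaussian copula with correlation `rho`,
#' with uniform marginals rescaled to the observed ranges of a winter broiler
#' chamber (THI 51-62, NH3 9-50 ppm). The population Kendall tau is the
#' Greiner relation `(2 / pi) * asin(rho)`. Temperature and humidity are
#' back-filled consistently: RH is drawn uniform on 60-80% and T solved from
#' the THI formula, so `thi == compute_thi(mean_temp, mean_rh)` holds exactly.
#'
#' @param n_periods Number of periods (>= 2).
#' @param rho Gaussian copula correlation in `(-1, 1)`.
#' @param seed Integer seed.
#' @return Tibble shaped like [aggregate_periods()] output: `date`, `period`,
#'   `mean_nh3`, `mean_temp`, `mean_rh`, `thi`, `n_readings`, `complete`.
#' @export
simulate_environment <- function(n_periods, rho, seed = 1L) {
  if (n_periods < 2L) stop("n_periods must be >= 2", call. = FALSE)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    z1 <- stats::rnorm(n_periods)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_periods)
    u1 <- stats::pnorm(z1)
    u2 <- stats::pnorm(z2)
    thi <- 51 + 11 * u1
    nh3 <- 9 + 41 * u2
    rh <- stats::runif(n_periods, 60, 80)
  })
  # invert THI = 1.8T + 32 - k(1.8T - 26), k = 0.55 - 0.0055 rh, for T given rh
  k <- 0.55 - 0.0055 * rh
  temp <- (thi - 32 - 26 * k) / (1.8 * (1 - k))
  periods <- c("06:00", "12:00", "18:00")
  tibble::tibble(
    date = as.Date("2020-01-01") + (seq_len(n_periods) - 1L) %/% 3L,
    period = periods[(seq_len(n_periods) - 1L) %% 3L + 1L],
    mean_nh3 = nh3,
    mean_temp = temp,
    mean_rh = rh,
    thi = thi,
    n_readings = 60L,
    complete = TRUE
  )
}
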