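#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run in one list. Paths may be `NULL`
#' when the corresponding stage is skipped (`no_images = TRUE` runs only the
#' environmental-statistics stage).
#'
#' @param frames_dir Directory of input frames plus a `manifest.csv`
#'   (`frame,path,mask_path,period,date`) mapping frames to (date, period).
#' @param sensors_csv Sensor log CSV (`timestamp,nh3_ppm,temp_c,rh_pct`), or a
#'   pre-aggregated per-period CSV with at least `date,period,thi,mean_nh3`.
#' @param out_dir Output directory (created if missing).
#' @param patches Named list of patch-origin data frames (`litter`, `body`,
#'   `feeder`), each with `row`/`col` columns, used to learn thresholds from
#'   the first frame; `NULL` in `no_images` mode.
#' @param patch_size Patch side length in pixels.
#' @param n_samples Pixel samples drawn per class and channel.
#' @param morph [morph_params()]; `NULL` means [default_morph_params()] at the
#'   frame size.
#' @param band Length-2 inclusive activity band (default `c(10, 49)`).
#' @param period_starts Period start hours (default `c(6, 12, 18)`).
#' @param tau_variant `"tau_b"` or `"tau_a"`.
#' @param seed Integer master seed.
#' @param eq2_verbatim Use the inverted threshold orientation (audit only).
#' @param no_images Skip all imagery stages and correlate from `sensors_csv`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(frames_dir = NULL, sensors_csv = NULL,
                            out_dir = tempfile("chromaflock_"),
                            patches = NULL, patch_size = 5L, n_samples = 100L,
                            morph = NULL, band = c(10L, 49L),
                            period_starts = c(6L, 12L, 18L),
                            tau_variant = c("tau_b", "tau_a"), seed = 1L,
                            eq2_verbatim = FALSE, no_images = FALSE) {
  tau_variant <- match.arg(tau_variant)
  stopifnot(length(band) == 2L, band[1] <= band[2])
  structure(list(frames_dir = frames_dir, sensors_csv = sensors_csv,
                 out_dir = out_dir, patches = patches,
                 patch_size = as.integer(patch_size),
                 n_samples = as.integer(n_samples), morph = morph,
                 band = as.integer(band), period_starts = as.integer(period_starts),
                 tau_variant = tau_variant, seed = as.integer(seed),
                 eq2_verbatim = isTRUE(eq2_verbatim),
                 no_images = isTRUE(no_images)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Every key of [pipeline_config()] may appear; unknown keys are an error.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read (highest precedence).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(pipeline_config, vals)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[chromaflock] %s: %s", stage, sprintf(...)))
}

read_frame_manifest <- function(frames_dir) {
  mpath <- file.path(frames_dir, "manifest.csv")
  if (!file.exists(mpath)) {
    stop("missing-inputs (segment): no manifest.csv in ", frames_dir, call. = FALSE)
  }
  readr::read_csv(mpath, col_types = readr::cols(
    frame = readr::col_character(), path = readr::col_character(),
    mask_path = readr::col_character(), period = readr::col_character(),
    date = readr::col_date()
  ))
}

#' Run the full activity-analysis pipeline
#'
#' Stages (each logged with its parameters): learn the three color thresholds
#' from labeled patches on the first frame; segment and refine every frame;
#' accumulate per-(date, period) occupancy maps and write heat-map PNGs plus
#' count CSVs; compute the band-ratio activity index per period; aggregate the
#' sensor log to per-period means with THI; join activity onto the period
#' summaries; and write a Kendall correlation report for activity x THI,
#' activity x NH3 and THI x NH3. In `no_images` mode only the
#' environment-side stages run, from either a raw sensor log or an already
#' aggregated per-period CSV.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries` (tibble), `report` (tibble),
#'   `thresholds` (or `NULL`), and the output paths written. Periods with
#'   fewer frames than expected are kept but flagged (`complete = FALSE`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- NULL
  act <- NULL

  if (!config$no_images) {
    if (is.null(config$frames_dir) || !dir.exists(config$frames_dir)) {
      stop("missing-inputs (segment): frames_dir not found", call. = FALSE)
    }
    manifest <- read_frame_manifest(config$frames_dir)
    pipeline_log("learn-thresholds", "patch_size=%d n_samples=%d seed=%d",
                 config$patch_size, config$n_samples, config$seed)
    if (is.null(config$patches)) {
      stop("missing-inputs (learn-thresholds): no patch specification",
           call. = FALSE)
    }
    first <- read_rgb_image(file.path(config$frames_dir, manifest$path[1]))
    spec <- list(litter = c("Cb", "b"), body = c("Cb", "b", "Q"), feeder = "Q")
    samples <- purrr::imap(spec, function(channels, cls) {
      purrr::map(channels, function(ch) {
        extract_patch_samples(first, config$patches[[cls]],
                              patch_size = config$patch_size, channel = ch,
                              class_label = cls, n_samples = config$n_samples,
                              seed = config$seed)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    thresholds <- learn_threshold_set(samples)
    readr::write_csv(tidy(thresholds), file.path(config$out_dir, "thresholds.csv"))

    morph <- config$morph %||% default_morph_params(dim(first)[1:2])
    pipeline_log("segment", "%d frames, se_radius=%d min_area=%d max_hole=%d",
                 nrow(manifest), morph$se_radius, morph$min_object_area,
                 morph$max_hole_area)
    mask_dir <- file.path(config$out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    manifest$out_mask <- file.path("masks", paste0(manifest$frame, "_mask.png"))
    masks <- purrr::map(seq_len(nrow(manifest)), function(i) {
      img <- read_rgb_image(file.path(config$frames_dir, manifest$path[i]))
      m <- refine_mask(apply_thresholds(img, thresholds, config$eq2_verbatim),
                       morph)
      write_mask(m, file.path(config$out_dir, manifest$out_mask[i]))
      m
    })

    pipeline_log("heatmap+activity", "band=[%d,%d]", config$band[1], config$band[2])
    groups <- split(seq_len(nrow(manifest)),
                    paste(manifest$date, manifest$period))
    act <- purrr::map(groups, function(ix) {
      occ <- accumulate_masks(masks[ix])
      tag <- sprintf("%s_%s", manifest$date[ix[1]],
                     gsub(":", "", manifest$period[ix[1]]))
      render_heatmap(occ, file.path(config$out_dir, paste0("heatmap_", tag, ".png")))
      readr::write_csv(tidy(occ),
                       file.path(config$out_dir, paste0("occupancy_", tag, ".csv")))
      ai <- activity_index(occ, config$band[1], config$band[2])
      tibble::tibble(date = manifest$date[ix[1]], period = manifest$period[ix[1]],
                     activity = ai$index, n_frames = occ$n_frames,
                     complete_period = occ$n_frames >= 60L)
    }) |> purrr::list_rbind()
    if (any(!act$complete_period)) {
      warning("periods with fewer than 60 frames are flagged, not rescaled",
              call. = FALSE)
    }
    readr::write_csv(act, file.path(config$out_dir, "activity.csv"))
  }

  if (is.null(config$sensors_csv) || !file.exists(config$sensors_csv)) {
    stop("missing-inputs (envstats): sensors_csv not found", call. = FALSE)
  }
  header <- names(readr::read_csv(config$sensors_csv, n_max = 0,
                                  col_types = readr::cols()))
  if ("timestamp" %in% header) {
    pipeline_log("envstats", "aggregating %s", config$sensors_csv)
    summaries <- aggregate_periods(read_sensor_csv(config$sensors_csv),
                                   period_starts = config$period_starts)
  } else {
    pipeline_log("envstats", "using pre-aggregated period means from %s",
                 config$sensors_csv)
    summaries <- readr::read_csv(config$sensors_csv, col_types = readr::cols(
      date = readr::col_date(), period = readr::col_character(),
      .default = readr::col_double()
    ))
  }
  if (!is.null(act)) {
    summaries <- dplyr::left_join(summaries, act, by = c("date", "period"))
  }
  readr::write_csv(summaries, file.path(config$out_dir, "period_summaries.csv"))

  pairs <- list(c("thi", "mean_nh3"))
  if ("activity" %in% names(summaries)) {
    pairs <- c(list(c("activity", "thi"), c("activity", "mean_nh3")), pairs)
  }
  report <- purrr::map(pairs, function(p) {
    tryCatch({
      res <- correlate_periods(summaries, p[1], p[2], variant = config$tau_variant)
      tibble::tibble(var_x = p[1], var_y = p[2], variant = config$tau_variant,
                     tau = res$tau, p_value = as.numeric(res$p_value), n = res$n)
    }, error = function(e) {
      warning("correlation ", p[1], " x ", p[2], " skipped: ",
              conditionMessage(e), call. = FALSE)
      tibble::tibble(var_x = p[1], var_y = p[2], variant = config$tau_variant,
                     tau = NA_real_, p_value = NA_real_, n = NA_integer_)
    })
  }) |> purrr::list_rbind()
  readr::write_csv(report, file.path(config$out_dir, "correlation_report.csv"))
  pipeline_log("correlate", "%d variable pairs, variant=%s",
               nrow(report), config$tau_variant)

  invisible(list(summaries = summaries, report = report,
                 thresholds = thresholds, out_dir = config$out_dir))
}

#' Write a simulated dataset to disk in the pipeline's input layout
#'
#' Renders `n_periods` synthetic one-hour periods (frames + truth masks +
#' manifest) and a matching per-period sensor log, so `run_pipeline()` can be
#' exercised end to end without farm data.
#'
#' @param out_dir Directory to create.
#' @param n_periods Number of periods (default 1).
#' @param n_frames Frames per period (default 60).
#' @param n_birds,step_sigma,size,palette Passed to [simulate_flock()].
#' @param seed Integer master seed.
#' @return Invisibly, a list with `frames_dir`, `sensors_csv` and the truth
#'   occupancy maps per period.
#' @export
write_simulated_dataset <- function(out_dir, n_periods = 1L, n_frames = 60L,
                                    n_birds = 44L, step_sigma = 6,
                                    size = c(216L, 384L),
                                    palette = scene_palette(), seed = 1L) {
  frames_dir <- file.path(out_dir, "frames")
  dir.create(frames_dir, showWarnings = FALSE, recursive = TRUE)
  periods <- c("06:00", "12:00", "18:00")
  rows <- list()
  truth <- list()
  sensors <- list()
  for (p in seq_len(n_periods)) {
    date <- as.Date("2020-01-01") + (p - 1L) %/% 3L
    period <- periods[(p - 1L) %% 3L + 1L]
    sim <- simulate_flock(n_birds = n_birds, n_frames = n_frames,
                          step_sigma = step_sigma, seed = seed + p,
                          size = size, palette = palette)
    for (t in seq_len(n_frames)) {
      frame_id <- sprintf("p%02d_f%02d", p, t)
      fpath <- paste0(frame_id, ".png")
      mpath <- paste0(frame_id, "_truth.png")
      write_rgb_image(sim$frames[[t]], file.path(frames_dir, fpath))
      write_mask(sim$masks[[t]], file.path(frames_dir, mpath))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        frame = frame_id, path = fpath, mask_path = mpath,
        period = period, date = date)
    }
    truth[[p]] <- sim$occupancy
    h0 <- as.integer(substr(period, 1, 2))
    ts <- as.POSIXct(paste(date, period), tz = "UTC") + 60 * (0:(n_frames - 1L))
    base_t <- withr::with_seed(seed + 100L + p, stats::runif(1, 10, 16))
    base_rh <- withr::with_seed(seed + 200L + p, stats::runif(1, 60, 80))
    base_nh3 <- withr::with_seed(seed + 300L + p, stats::runif(1, 9, 50))
    sensors[[p]] <- tibble::tibble(
      timestamp = ts,
      nh3_ppm = round(base_nh3 + withr::with_seed(seed + 400L + p,
                                                  stats::rnorm(n_frames, 0, 0.5)), 2),
      temp_c = round(base_t + withr::with_seed(seed + 500L + p,
                                               stats::rnorm(n_frames, 0, 0.1)), 2),
      rh_pct = round(pmin(100, pmax(0, base_rh + withr::with_seed(
        seed + 600L + p, stats::rnorm(n_frames, 0, 0.5)))), 2)
    )
  }
  manifest <- purrr::list_rbind(rows)
  readr::write_csv(manifest, file.path(frames_dir, "manifest.csv"))
  sensors_csv <- file.path(out_dir, "sensors.csv")
  readr::write_csv(purrr::list_rbind(sensors), sensors_csv)
  invisible(list(frames_dir = frames_dir, sensors_csv = sensors_csv,
                 truth_occupancy = truth))
}
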