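#' Temperature-humidity index (THI)
#'
#' `THI = 1.8 T + 32 - (0.55 - 0.0055 RH) (1.8 T - 26)`, with `T` the air
#' temperature in degrees Celsius and `RH` the relative humidity in percent.
#' The first term is the Fahrenheit conversion of the dry-bulb temperature; the
#' second discounts it by the humidity deficit, vanishing at saturation
#' (RH = 100) and at `1.8 T = 26` (T = 130/9 C, where THI = 58 regardless of
#' humidity). Vectorized over both arguments.
#'
#' @param temp_c Air temperature, degrees Celsius.
#' @param rh_pct Relative humidity, percent in `[0, 100]`.
#' @return THI, dimensionless.
#' @examples
#' compute_thi(20, 60)  # 65.8
#' @export
compute_thi <- function(temp_c, rh_pct) {
  if (any(!is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100))) {
    stop("rh_pct must lie in [0, 100]", call. = FALSE)
  }
  1.8 * temp_c + 32 - (0.55 - 0.0055 * rh_pct) * (1.8 * temp_c - 26)
}

#' Read an environmental sensor log
#'
#' Expects a CSV with header `timestamp,nh3_ppm,temp_c,rh_pct`, ISO-8601
#' timestamps, empty fields marking missing readings.
#'
#' @param path CSV path.
#' @return Tibble with columns `timestamp` (POSIXct, UTC), `nh3_ppm`,
#'   `temp_c`, `rh_pct`.
#' @export
read_sensor_csv <- function(path) {
  readr::read_csv(path,
                  col_types = readr::cols(
                    timestamp = readr::col_datetime(),
                    nh3_ppm = readr::col_double(),
                    temp_c = readr::col_double(),
                    rh_pct = readr::col_double()
                  ))
}

#' Aggregate sensor readings to per-period means with THI
#'
#' Averages each variable over clock-hour windows `[start, start + 1h)` on
#' each date, keeping only the requested period start hours. A (date, period)
#' cell with no reading for a required variable is dropped entirely, mirroring
#' the practice of analyzing only dates with complete records. THI is computed
#' from the period-mean temperature and humidity (mean-then-THI), not averaged
#' over per-reading THIs.
#'
#' @param readings Tibble as returned by [read_sensor_csv()].
#' @param period_starts Integer vector of period start hours
#'   (default `c(6, 12, 18)`).
#' @param require Character vector of variables that must be present for a
#'   period to be kept (default all three).
#' @return Tibble: `date`, `period` (e.g. `"06:00"`), `mean_nh3`, `mean_temp`,
#'   `mean_rh`, `thi`, `n_readings`, `complete` (TRUE when 60 readings were
#'   available).
#' @export
aggregate_periods <- function(readings, period_starts = c(6L, 12L, 18L),
                              require = c("nh3_ppm", "temp_c", "rh_pct")) {
  stopifnot(is.data.frame(readings))
  if (nrow(readings) == 0L) {
    return(tibble::tibble(date = as.Date(character()), period = character(),
                          mean_nh3 = double(), mean_temp = double(),
                          mean_rh = double(), thi = double(),
                          n_readings = integer(), complete = logical()))
  }
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  out <- readings |>
    dplyr::mutate(
      date = as.Date(.data$timestamp, tz = "UTC"),
      hour = as.integer(format(.data$timestamp, "%H", tz = "UTC"))
    ) |>
    dplyr::filter(.data$hour %in% period_starts) |>
    dplyr::group_by(.data$date, .data$hour) |>
    dplyr::summarise(
      mean_nh3 = mean_or_na(.data$nh3_ppm),
      mean_temp = mean_or_na(.data$temp_c),
      mean_rh = mean_or_na(.data$rh_pct),
      n_readings = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      period = sprintf("%02d:00", .data$hour),
      thi = compute_thi(.data$mean_temp, .data$mean_rh),
      complete = .data$n_readings >= 60L
    )
  need <- c(nh3_ppm = "mean_nh3", temp_c = "mean_temp", rh_pct = "mean_rh")[require]
  for (v in need) out <- out[!is.na(out[[v]]), ]
  out |>
    dplyr::arrange(.data$date, .data$hour) |>
    dplyr::select("date", "period", "mean_nh3", "mean_temp", "mean_rh",
                  "thi", "n_readings", "complete")
}

# Kendall concordance bookkeeping shared by tau and its p-values.
kendall_stats <- function(x, y) {
  n <- length(x)
  rx <- outer(x, x, function(a, b) sign(a - b))
  ry <- outer(y, y, function(a, b) sign(a - b))
  s <- sum(rx * ry) / 2  # C - D over unordered pairs
  tx <- table(x)
  ty <- table(y)
  list(n = n, S = s,
       n0 = n * (n - 1) / 2,
       n1 = sum(tx * (tx - 1) / 2),
       n2 = sum(ty * (ty - 1) / 2),
       tie_x = as.integer(tx), tie_y = as.integer(ty))
}

#' Kendall rank correlation
#'
#' Computes Kendall's tau between two paired series. `tau_a` is the raw
#' concordance ratio, the double sum of `sgn(x_i - x_j) sgn(y_i - y_j)` over
#' all ordered pairs divided by `n (n - 1)`; `tau_b` (the default reported
#' variant) divides the concordance excess `C - D` by the tie-corrected
#' geometric mean `sqrt((n0 - n1)(n0 - n2))`. The two coincide exactly when
#' both series are tie-free. The two-sided p-value stored on the result uses
#' the tie-corrected normal approximation; [kendall_pvalue()] recomputes it
#' with either method.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @param variant `"tau_b"` (default) or `"tau_a"`.
#' @return A `kendall_cor` object: list with `tau`, `variant`, `p_value`,
#'   `p_method`, `n`, `S` (concordant minus discordant pairs) and tie counts.
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4), variant = "tau_a")$tau  # 2/3
#' @export
kendall_tau <- function(x, y, variant = c("tau_b", "tau_a")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  ks <- kendall_stats(x, y)
  tau <- if (variant == "tau_a") {
    2 * ks$S / (ks$n * (ks$n - 1))
  } else {
    denom <- sqrt((ks$n0 - ks$n1) * (ks$n0 - ks$n2))
    if (denom == 0) stop("tau_b undefined: a series is constant", call. = FALSE)
    ks$S / denom
  }
  res <- structure(c(ks, list(tau = tau, variant = variant, x = x, y = y)),
                   class = "kendall_cor")
  res$p_value <- kendall_pvalue(res, method = "normal_approx")
  res$p_method <- "normal_approx"
  res
}

# Exact null distribution of the number of inversions of a random permutation
# of 1..n (Mahonian numbers), as a probability vector over 0..n(n-1)/2.
inversion_distribution <- function(n) {
  counts <- 1
  for (k in 2:n) {
    # polynomial multiply by (1 + q + ... + q^(k-1))
    new_len <- length(counts) + k - 1L
    acc <- numeric(new_len)
    for (sft in 0:(k - 1L)) {
      acc[(1:length(counts)) + sft] <- acc[(1:length(counts)) + sft] + counts
    }
    counts <- acc / k  # keep normalized to avoid overflow
  }
  counts
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Two-sided p-value for a Kendall correlation
#'
#' `method = "normal_approx"` uses the z statistic of the concordance excess
#' `S` with the standard tie-corrected null variance. `method = "exact"`
#' evaluates `P(|S| >= |S_obs|)` under the null of independent rankings: for
#' tie-free data via the exact inversion-number distribution (equivalent to
#' full enumeration, any n); with ties and `n <= 8` by full enumeration of the
#' `n!` pairings; for larger tied samples it falls back to a Monte-Carlo
#' permutation test with 1e5 resamples (flagged in the `p_method` attribute
#' and by a warning).
#'
#' @param result A `kendall_cor` from [kendall_tau()].
#' @param method `"normal_approx"` or `"exact"`.
#' @param n_resamples Resamples for the Monte-Carlo fallback (default 1e5).
#' @param seed Seed for the Monte-Carlo fallback.
#' @return Two-sided p-value in `(0, 1]`, with attribute `p_method`.
#' @export
kendall_pvalue <- function(result, method = c("normal_approx", "exact"),
                           n_resamples = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(result, "kendall_cor"))
  n <- result$n
  if (method == "normal_approx") {
    tx <- result$tie_x
    ty <- result$tie_y
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    if (var_s <= 0) return(structure(1, p_method = "normal_approx"))
    p <- 2 * stats::pnorm(-abs(result$S) / sqrt(var_s))
    return(structure(min(1, p), p_method = "normal_approx"))
  }
  tie_free <- result$n1 == 0 && result$n2 == 0
  if (tie_free) {
    # S = n0 - 2 * inversions for tie-free data
    dist <- inversion_distribution(n)
    inv <- 0:(length(dist) - 1L)
    s_vals <- result$n0 - 2 * inv
    p <- sum(dist[abs(s_vals) >= abs(result$S) - 1e-9])
    return(structure(min(1, p), p_method = "exact_enumeration"))
  }
  if (n <= 8L) {
    perms <- all_permutations(n)
    s_obs <- abs(result$S)
    hits <- apply(perms, 1, function(p) {
      abs(kendall_stats(result$x, result$y[p])$S) >= s_obs - 1e-9
    })
    return(structure(mean(hits), p_method = "exact_enumeration"))
  }
  warning("exact p-value with ties and n > 8: falling back to ",
          "Monte-Carlo permutation", call. = FALSE)
  p <- withr::with_seed(as.integer(seed), {
    s_obs <- abs(result$S)
    hits <- vapply(seq_len(n_resamples), function(i) {
      abs(kendall_stats(result$x, sample(result$y))$S) >= s_obs - 1e-9
    }, logical(1))
    (sum(hits) + 1) / (n_resamples + 1)
  })
  structure(p, p_method = "permutation")
}

#' @export
print.kendall_cor <- function(x, ...) {
  cat(sprintf("Kendall rank correlation (%s)\n", x$variant))
  cat(sprintf("  tau = %.4f, n = %d, two-sided p = %.4g (%s)\n",
              x$tau, x$n, x$p_value, x$p_method))
  invisible(x)
}

#' Tidy a Kendall correlation result
#'
#' @param x A `kendall_cor`.
#' @param ... Unused.
#' @return One-row tibble: `tau`, `variant`, `p_value`, `p_method`, `n`.
#' @method tidy kendall_cor
#' @export
tidy.kendall_cor <- function(x, ...) {
  tibble::tibble(tau = x$tau, variant = x$variant, p_value = as.numeric(x$p_value),
                 p_method = x$p_method, n = x$n)
}

#' One-line summary of a Kendall correlation result
#'
#' @param x A `kendall_cor`.
#' @param ... Unused.
#' @return One-row tibble: `tau`, `p_value`, `n`, `S`, `n_tied_x`, `n_tied_y`.
#' @method glance kendall_cor
#' @export
glance.kendall_cor <- function(x, ...) {
  tibble::tibble(tau = x$tau, p_value = as.numeric(x$p_value), n = x$n,
                 S = x$S, n_tied_x = x$n1, n_tied_y = x$n2)
}

#' Kendall correlation between two per-period variables
#'
#' Pairs two columns of a period-summary table in (date, period) order,
#' dropping periods where either is missing (listwise deletion), and delegates
#' to [kendall_tau()].
#'
#' @param summaries Tibble with columns `date`, `period` and the two variables
#'   (e.g. from [aggregate_periods()], optionally with an `activity` column).
#' @param var_x,var_y Column names of the paired variables (strings), e.g.
#'   `"thi"`, `"mean_nh3"`, `"activity"`.
#' @param variant `"tau_b"` (default) or `"tau_a"`.
#' @return A `kendall_cor` object (the paired `n` is recorded on it).
#' @export
correlate_periods <- function(summaries, var_x, var_y,
                              variant = c("tau_b", "tau_a")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(summaries),
            all(c(var_x, var_y) %in% names(summaries)))
  df <- summaries
  if (all(c("date", "period") %in% names(df))) {
    df <- df[order(df$date, df$period), ]
  }
  keep <- !is.na(df[[var_x]]) & !is.na(df[[var_y]])
  df <- df[keep, ]
  if (nrow(df) < 2L) {
    stop("fewer than 2 complete (", var_x, ", ", var_y, ") pairs", call. = FALSE)
  }
  res <- kendall_tau(df[[var_x]], df[[var_y]], variant = variant)
  res$var_x <- var_x
  res$var_y <- var_y
  res
}

#' Per-period environmental record of the study chamber
#'
#' The published per-period means for the monitored broiler chamber:
#' ammonia concentration (ppm) and THI for three daily one-hour periods
#' (06:00, 12:00, 18:00) over eight complete-record dates between
#' 2019-12-22 and 2020-01-03 (24 periods). Temperature and humidity were not
#' published individually, only their THI.
#'
#' @return Tibble: `date`, `period`, `mean_nh3`, `thi` (24 rows).
#' @export
chamber_period_data <- function() {
  path <- system.file("extdata", "chamber_env_periods.csv",
                      package = "chromaflock", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(),
    period = readr::col_character(),
    mean_nh3 = readr::col_double(),
    thi = readr::col_double()
  ))
}
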