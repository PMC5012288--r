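#' Two-point specific growth rate
#'
#' `mu = ln(n2/n1) / ((t2 - t1)/24)` in per-day units, with times in hours.
#' Negative values (decline) are allowed.
#'
#' @param n1,n2 densities (OD or cells/mL), strictly positive.
#' @param t1,t2 times in hours, `t2 > t1`.
#' @return Specific growth rate in d^-1.
#' @examples
#' specific_growth_rate(1e4, 2e4, 0, 24) # one doubling per day, ln 2
#' @export
specific_growth_rate <- function(n1, n2, t1, t2) {
  if (any(c(n1, n2) <= 0)) stopf("densities must be strictly positive")
  if (any(t2 <= t1)) stopf("t2 must exceed t1")
  log(n2 / n1) / ((t2 - t1) / 24)
}

#' Generation (doubling) time from a specific growth rate
#'
#' `T = 24 ln 2 / mu` hours for `mu` in d^-1.
#'
#' @param mu specific growth rate in d^-1; must be positive (a culture that
#'   is not growing has no doubling time).
#' @return Generation time in hours.
#' @examples
#' generation_time(log(2)) # exactly 24 h
#' @export
generation_time <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stopf("generation time is undefined for mu <= 0 (no doubling)")
  24 * log(2) / mu
}

#' Fit the exponential window of a growth curve
#'
#' Scans every contiguous window of at least `min_points` observations
#' spanning at most `max_window_days` days, fits `ln(density) ~ time` by
#' least squares in each, and keeps the window with the highest r-squared;
#' ties are broken in favour of the larger window, then the earlier start.
#' The specific growth rate is the slope converted to d^-1.
#'
#' A curve that is constant everywhere (all windows degenerate) yields
#' `mu = 0` with `r_squared = 0`.
#'
#' @param times numeric vector of times in hours, strictly increasing.
#' @param densities numeric vector of matching strictly positive densities.
#' @param min_points minimum window size (default 3).
#' @param max_window_days maximum window span in days (default 3, matching
#'   the typical duration of exponential growth in batch culture).
#' @param strain_id optional label carried into the result.
#' @return Object of class `growth_fit`: list with `mu` (d^-1),
#'   `generation_time_h`, `window` (integer index range used), `r_squared`,
#'   `n_points`, `strain_id`.
#' @examples
#' t <- seq(0, 168, by = 24)
#' fit_exponential_window(t, 1e4 * exp(0.9 * t / 24))
#' @export
fit_exponential_window <- function(times, densities, min_points = 3,
                                   max_window_days = 3, strain_id = NA) {
  n <- length(times)
  if (n != length(densities)) stopf("times and densities differ in length")
  if (n < 3) stopf("need at least 3 observations")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(densities <= 0)) stopf("densities must be strictly positive")
  if (min_points < 2) stopf("min_points must be at least 2")
  y <- log(densities)
  span_h <- max_window_days * 24
  best <- NULL
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      if (times[j] - times[i] > span_h + 1e-9) break
      tt <- times[i:j]
      yy <- y[i:j]
      fit <- stats::lm.fit(cbind(1, tt), yy)
      slope <- fit$coefficients[2]
      ss_tot <- sum((yy - mean(yy))^2)
      r2 <- if (ss_tot <= 0) NA_real_ else 1 - sum(fit$residuals^2) / ss_tot
      cand <- list(i = i, j = j, slope = slope, r2 = r2)
      if (better_window(cand, best)) best <- cand
    }
  }
  if (is.null(best) || is.na(best$r2)) {
    # fully degenerate: constant density
    res <- list(mu = 0, generation_time_h = NA_real_, window = c(1L, n),
                r_squared = 0, n_points = n, strain_id = strain_id)
  } else {
    mu <- unname(best$slope) * 24
    res <- list(mu = mu,
                generation_time_h = if (mu > 0) generation_time(mu)
                                    else NA_real_,
                window = c(best$i, best$j),
                r_squared = unname(best$r2),
                n_points = best$j - best$i + 1L,
                strain_id = strain_id)
  }
  class(res) <- "growth_fit"
  res
}

# Window preference: higher r2, then more points, then earlier start.
better_window <- function(cand, best) {
  if (is.na(cand$r2)) return(FALSE)
  if (is.null(best) || is.na(best$r2)) return(TRUE)
  eps <- 1e-12
  if (cand$r2 > best$r2 + eps) return(TRUE)
  if (cand$r2 < best$r2 - eps) return(FALSE)
  n_c <- cand$j - cand$i
  n_b <- best$j - best$i
  if (n_c != n_b) return(n_c > n_b)
  cand$i < best$i
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Growth fit%s: mu = %.4f d^-1, T = %s h, window points %d..%d (n=%d), r^2 = %.4f\n",
    if (!is.na(x$strain_id)) paste0(" [", x$strain_id, "]") else "",
    x$mu,
    if (is.na(x$generation_time_h)) "NA" else
      sprintf("%.2f", x$generation_time_h),
    x$window[1], x$window[2], x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, generation_time_h = object$generation_time_h)
}

#' Read a long-format growth table
#'
#' Expected columns: `strain`, `time_h`, `value` and optionally `measure`
#' (one of `od550`, `cell_count`, `fluorescence`).
#'
#' @param path CSV/TSV file.
#' @return data.frame with the validated columns.
#' @export
read_growth_table <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  need <- c("strain", "time_h", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  if (!"measure" %in% names(df)) df$measure <- "od550"
  df
}

#' Fit growth curves for every strain in a long table
#'
#' When a strain has readings under more than one measure, `measure`
#' selects which feeds the fit (optical density by default).
#'
#' @param df long data.frame as returned by [read_growth_table()].
#' @param measure preferred measure when several are present.
#' @param ... passed to [fit_exponential_window()].
#' @return data.frame with one row per strain: `strain`, `mu`,
#'   `generation_time_h`, `r_squared`, `window_start`, `window_end`,
#'   `n_points`.
#' @export
fit_growth_table <- function(df, measure = "od550", ...) {
  res <- lapply(split(df, df$strain), function(d) {
    if (length(unique(d$measure)) > 1L && measure %in% d$measure)
      d <- d[d$measure == measure, ]
    d <- d[order(d$time_h), ]
    f <- fit_exponential_window(d$time_h, d$value,
                                strain_id = d$strain[1], ...)
    data.frame(strain = d$strain[1], mu = f$mu,
               generation_time_h = f$generation_time_h,
               r_squared = f$r_squared,
               window_start = f$window[1], window_end = f$window[2],
               n_points = f$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
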