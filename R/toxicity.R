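#' Percent inhibition and percent of control
#'
#' The inhibition statistic of a static growth-response bioassay:
#' `%I = (C - X)/C * 100`, where `C` is the mean control growth rate and
#' `X` the mean growth rate at a test concentration. Stimulation (X > C)
#' yields a negative value, which is returned as-is. The complementary
#' normalisation is `percent_of_control = X/C * 100`; the two always sum
#' to 100.
#'
#' @param c_mean mean control growth rate (d^-1), strictly positive.
#' @param x_mean mean treated growth rate (d^-1).
#' @return Percentage.
#' @examples
#' percent_inhibition(0.8, 0.4) # 50
#' @export
percent_inhibition <- function(c_mean, x_mean) {
  if (any(!is.finite(c_mean)) || any(c_mean <= 0))
    stopf("control mean growth rate must be positive (control failed)")
  (c_mean - x_mean) / c_mean * 100
}

#' @rdname percent_inhibition
#' @export
percent_of_control <- function(c_mean, x_mean) {
  if (any(!is.finite(c_mean)) || any(c_mean <= 0))
    stopf("control mean growth rate must be positive (control failed)")
  x_mean / c_mean * 100
}

#' Analyse a copper dose-response panel
#'
#' For each concentration, fits a growth rate per replicate fluorescence
#' series (exponential-window fit restricted to the assay window, 0-72 h
#' by default), averages replicates, and reports percent-of-control, `%I`
#' and a no-growth flag. No growth is declared when the mean rate is <= 0
#' or mean final fluorescence does not exceed the initial; a no-growth
#' concentration is reported at `%I = 100`.
#'
#' @param panel data.frame with columns `concentration` (mg/L, control is
#'   0), `replicate`, `time_h`, `fluorescence`.
#' @param growth_window_h upper time bound used in the rate fits.
#' @param ... passed to [fit_exponential_window()].
#' @return Object of class `inhibition_result`: data.frame with one row
#'   per concentration (`concentration`, `mean_rate`, `percent_of_control`,
#'   `percent_inhibition`, `no_growth`, `n_reps`), plus attribute
#'   `replicate_rates` (list of per-replicate rate vectors keyed by
#'   concentration).
#' @export
analyze_panel <- function(panel, growth_window_h = 72, ...) {
  need <- c("concentration", "replicate", "time_h", "fluorescence")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stopf("panel is missing column(s): %s", paste(miss, collapse = ", "))
  if (!any(panel$concentration == 0))
    stopf("panel has no control (concentration 0) series")
  panel <- panel[panel$time_h <= growth_window_h + 1e-9, ]
  conc <- sort(unique(panel$concentration))
  rep_rates <- list()
  final_vs_initial <- numeric(0)
  for (cc in conc) {
    d <- panel[panel$concentration == cc, ]
    rates <- vapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_h), ]
      fit_exponential_window(r$time_h, r$fluorescence, ...)$mu
    }, numeric(1))
    rep_rates[[as.character(cc)]] <- rates
    fv <- vapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_h), ]
      r$fluorescence[nrow(r)] - r$fluorescence[1]
    }, numeric(1))
    final_vs_initial[as.character(cc)] <- mean(fv)
  }
  c_mean <- mean(rep_rates[["0"]])
  if (!is.finite(c_mean) || c_mean <= 0)
    stopf("control mean growth rate must be positive (control failed)")
  rows <- lapply(as.character(conc), function(k) {
    x_mean <- mean(rep_rates[[k]])
    ng <- x_mean <= 0 || final_vs_initial[[k]] <= 0
    data.frame(concentration = as.numeric(k),
               mean_rate = x_mean,
               percent_of_control = if (ng) 0
                 else percent_of_control(c_mean, x_mean),
               percent_inhibition = if (ng) 100
                 else percent_inhibition(c_mean, x_mean),
               no_growth = ng,
               n_reps = length(rep_rates[[k]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicate_rates") <- rep_rates
  attr(out, "control_mean") <- c_mean
  class(out) <- c("inhibition_result", "data.frame")
  out
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("Copper bioassay: control mean rate %.3f d^-1\n",
              attr(x, "control_mean")))
  shown <- data.frame(conc_mg_L = x$concentration,
                      rate = round(x$mean_rate, 3),
                      pct_control = round(x$percent_of_control, 1),
                      pct_inhibition = round(x$percent_inhibition, 1),
                      no_growth = x$no_growth)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Compare replicate growth rates between two strains
#'
#' Two-sample, two-tailed Student's t-test with pooled variance. Two
#' groups that are both constant with equal means return `t = 0, p = 1`
#' by convention.
#'
#' @param a,b numeric vectors of replicate growth rates (>= 2 each).
#' @return List with `t`, `df`, `p`.
#' @examples
#' compare_to_reference(c(1.0, 1.1, 1.2), c(0.4, 0.5, 0.6))
#' @export
compare_to_reference <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stopf("need at least 2 replicates per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Read a bioassay fluorescence table
#'
#' Expected columns: `strain`, `concentration_mg_l` (or `concentration`),
#' `replicate`, `time_h`, `fluorescence`.
#'
#' @param path CSV/TSV file.
#' @return data.frame with column `concentration` normalised.
#' @export
read_bioassay_table <- function(path) {
  df <- read_delim_auto(path)
  names(df) <- tolower(names(df))
  if ("concentration_mg_l" %in% names(df))
    names(df)[names(df) == "concentration_mg_l"] <- "concentration"
  need <- c("strain", "concentration", "replicate", "time_h", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  df
}
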