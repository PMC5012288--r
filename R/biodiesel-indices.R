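#' Biodiesel-quality indices from a FAME profile
#'
#' The six screening indices are computed from the compositional profile
#' alone, writing `N_i` for the wt% of species `i`, `M_i` for its
#' methyl-ester mass ([methyl_ester_mass()]) and `D_i` for its double-bond
#' count:
#'
#' * saponification value `SV = sum 560 N_i / M_i` (mg KOH/g),
#' * iodine value `IV = sum 254 D_i N_i / M_i` (g I2/100 g),
#' * cetane number, either component-weighted
#'   `CN = sum (N_i/100) (-7.8 + 0.302 M_i - 20 D_i)` (default) or the
#'   aggregate form `CN = 46.3 + 5458/SV - 0.225 IV`,
#' * degree of unsaturation `DU = MUFA + 2 PUFA` (wt%),
#' * long-chain saturation factor
#'   `LCSF = 0.1 N(C16:0) + 0.5 N(C18:0) + N(C20:0) + 1.5 N(C22:0) + 2 N(C24:0)`,
#' * cold filter plugging point `CFPP = 3.1417 LCSF - 16.477` (deg C).
#'
#' @param profile named numeric vector of wt% abundances summing to 100.
#' @param cn_method `"component_weighted"` or `"aggregate_sv_iv"`.
#' @return An object of class `biodiesel_indices`: a list with elements
#'   `sv`, `iv`, `cn`, `du`, `lcsf`, `cfpp`, `cn_method` and `screen` (see
#'   [astm_screen()]).
#' @examples
#' biodiesel_indices(c("C16:0" = 40, "C18:1" = 40, "C18:2" = 20))
#' @export
biodiesel_indices <- function(profile,
                              cn_method = c("component_weighted",
                                            "aggregate_sv_iv")) {
  cn_method <- match.arg(cn_method)
  check_profile(profile)
  sv <- saponification_value(profile)
  iv <- iodine_value(profile)
  cn <- cetane_number(profile, method = cn_method)
  res <- list(sv = sv, iv = iv, cn = cn,
              du = degree_of_unsaturation(profile),
              lcsf = long_chain_saturation_factor(profile),
              cn_method = cn_method)
  res$cfpp <- cold_filter_plugging_point(res$lcsf)
  res$screen <- astm_screen(res)
  class(res) <- "biodiesel_indices"
  res
}

check_profile <- function(profile) {
  if (length(profile) == 0L || is.null(names(profile)))
    stopf("profile must be a non-empty named numeric vector of wt%%")
  if (any(!is.finite(profile)) || any(profile < 0))
    stopf("profile abundances must be finite and non-negative")
  invisible(profile)
}

#' @rdname biodiesel_indices
#' @export
saponification_value <- function(profile) {
  check_profile(profile)
  sum(560 * profile / methyl_ester_mass(names(profile)))
}

#' @rdname biodiesel_indices
#' @export
iodine_value <- function(profile) {
  check_profile(profile)
  sp <- parse_fatty_acid(names(profile))
  sum(254 * sp$double_bonds * profile / methyl_ester_mass(sp))
}

#' @rdname biodiesel_indices
#' @param method cetane-number variant, as for `cn_method`.
#' @export
cetane_number <- function(profile, method = c("component_weighted",
                                              "aggregate_sv_iv")) {
  method <- match.arg(method)
  check_profile(profile)
  if (method == "component_weighted") {
    sp <- parse_fatty_acid(names(profile))
    m <- methyl_ester_mass(sp)
    sum((profile / 100) * (-7.8 + 0.302 * m - 20 * sp$double_bonds))
  } else {
    46.3 + 5458 / saponification_value(profile) -
      0.225 * iodine_value(profile)
  }
}

#' @rdname biodiesel_indices
#' @export
degree_of_unsaturation <- function(profile) {
  cf <- class_fractions(profile)
  unname(cf[["mufa"]] + 2 * cf[["pufa"]])
}

# LCSF weights per saturated long-chain species.
.lcsf_weights <- c("C16:0" = 0.1, "C18:0" = 0.5, "C20:0" = 1,
                   "C22:0" = 1.5, "C24:0" = 2)

#' @rdname biodiesel_indices
#' @export
long_chain_saturation_factor <- function(profile) {
  if (length(profile) == 0L) return(0)
  canon <- parse_fatty_acid(names(profile))$label
  # geometry/omega qualifiers never occur on saturated species, but strip
  # to the bare CX:Y form for the lookup regardless
  bare <- sub("\\(.*$", "", canon)
  w <- .lcsf_weights[bare]
  w[is.na(w)] <- 0
  sum(w * profile)
}

#' @rdname biodiesel_indices
#' @param lcsf long-chain saturation factor in wt%.
#' @export
cold_filter_plugging_point <- function(lcsf) {
  3.1417 * lcsf - 16.477
}

#' ASTM cetane/iodine biodiesel screen
#'
#' Pass criteria: cetane number at least 47 and iodine value at most
#' 120 g I2/100 g (thresholds inclusive). Comparisons always use unrounded
#' values.
#'
#' @param indices a `biodiesel_indices` object, or any list with numeric
#'   elements `cn` and `iv`.
#' @param cn_min,iv_max screen thresholds.
#' @return List with logical `cn_pass`, `iv_pass`, `overall_pass`.
#' @export
astm_screen <- function(indices, cn_min = 47, iv_max = 120) {
  cn_pass <- indices$cn >= cn_min
  iv_pass <- indices$iv <= iv_max
  list(cn_pass = cn_pass, iv_pass = iv_pass,
       overall_pass = cn_pass && iv_pass)
}

#' @export
print.biodiesel_indices <- function(x, ...) {
  cat("Biodiesel-quality indices (cetane method:", x$cn_method, ")\n")
  cat(sprintf("  SV   %7.1f mg KOH/g\n", x$sv))
  cat(sprintf("  IV   %7.1f g I2/100 g   [%s]\n", x$iv,
              if (x$screen$iv_pass) "<= 120 pass" else "> 120 fail"))
  cat(sprintf("  CN   %7.1f              [%s]\n", x$cn,
              if (x$screen$cn_pass) ">= 47 pass" else "< 47 fail"))
  cat(sprintf("  DU   %7.1f wt%%\n", x$du))
  cat(sprintf("  LCSF %7.2f wt%%\n", x$lcsf))
  cat(sprintf("  CFPP %7.0f degC (%.2f unrounded)\n",
              round_half_away(x$cfpp), x$cfpp))
  invisible(x)
}

#' Feedstock screening report
#'
#' Combines per-strain biodiesel indices with growth fits into a ranked
#' screening table: ASTM pass flags, a fast-grower flag (`mu >= fast_mu`),
#' and global counts. Strains missing either input are listed in an
#' `exclusions` attribute rather than silently dropped. Rows are ranked by
#' overall ASTM pass (passing first), then by decreasing growth rate.
#'
#' @param profiles strains x species wt% matrix (rows sum to 100), e.g.
#'   from [normalize_profiles()].
#' @param growth data.frame with columns `strain` and `mu` (d^-1), e.g.
#'   from [fit_growth_table()]; may be `NULL` for an indices-only report.
#' @param cn_method passed to [biodiesel_indices()].
#' @param fast_mu fast-grower threshold in d^-1.
#' @return Object of class `screening_report`: a data.frame with one row
#'   per strain and attributes `counts` (named vector) and `exclusions`.
#' @export
screen_table <- function(profiles, growth = NULL,
                         cn_method = "component_weighted", fast_mu = 1.0) {
  strains <- rownames(profiles) %||% character(0)
  if (length(strains) == 0L) {
    out <- data.frame(strain = character(0), mu = numeric(0),
                      generation_time_h = numeric(0), cn = numeric(0),
                      iv = numeric(0), du = numeric(0), lcsf = numeric(0),
                      sv = numeric(0), cfpp = numeric(0),
                      cn_pass = logical(0), iv_pass = logical(0),
                      overall_pass = logical(0), fast_grower = logical(0))
    attr(out, "counts") <- c(n_strains = 0, n_cn_pass = 0, n_iv_pass = 0,
                             n_overall_pass = 0, n_fast = 0)
    attr(out, "exclusions") <- character(0)
    attr(out, "cn_method") <- cn_method
    class(out) <- c("screening_report", "data.frame")
    return(out)
  }
  growth_strains <- if (is.null(growth)) character(0) else growth$strain
  excl <- character(0)
  if (!is.null(growth)) {
    only_g <- setdiff(growth_strains, strains)
    only_p <- setdiff(strains, growth_strains)
    excl <- c(
      if (length(only_g)) paste0(only_g, ": no FAME profile"),
      if (length(only_p)) paste0(only_p, ": no growth fit"))
    strains <- intersect(strains, growth_strains)
  }
  rows <- lapply(strains, function(s) {
    prof <- profiles[s, ]
    prof <- prof[prof > 0]
    idx <- biodiesel_indices(prof, cn_method = cn_method)
    mu <- if (is.null(growth)) NA_real_ else growth$mu[match(s, growth$strain)]
    data.frame(strain = s, mu = mu,
               generation_time_h = if (!is.na(mu) && mu > 0)
                 generation_time(mu) else NA_real_,
               cn = idx$cn, iv = idx$iv, du = idx$du, lcsf = idx$lcsf,
               sv = idx$sv, cfpp = idx$cfpp,
               cn_pass = idx$screen$cn_pass, iv_pass = idx$screen$iv_pass,
               overall_pass = idx$screen$overall_pass,
               fast_grower = !is.na(mu) && mu >= fast_mu,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$overall_pass, -ifelse(is.na(out$mu), -Inf, out$mu))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    n_strains = nrow(out),
    n_cn_pass = sum(out$cn_pass),
    n_iv_pass = sum(out$iv_pass),
    n_overall_pass = sum(out$overall_pass),
    n_fast = sum(out$fast_grower, na.rm = TRUE))
  attr(out, "exclusions") <- excl
  attr(out, "cn_method") <- cn_method
  class(out) <- c("screening_report", "data.frame")
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf(
    "Feedstock screen: %d strain(s); CN pass %d, IV pass %d, both %d, fast growers %d\n",
    cnt["n_strains"], cnt["n_cn_pass"], cnt["n_iv_pass"],
    cnt["n_overall_pass"], cnt["n_fast"]))
  if (nrow(x)) {
    shown <- data.frame(
      strain = x$strain,
      mu = round(x$mu, 2),
      T_h = round(x$generation_time_h, 1),
      CN = signif(x$cn, 3), IV = signif(x$iv, 3),
      DU = signif(x$du, 3), LCSF = signif(x$lcsf, 3),
      SV = signif(x$sv, 3), CFPP = round_half_away(x$cfpp),
      pass = ifelse(x$overall_pass, "yes", "no"),
      fast = ifelse(x$fast_grower, "yes", "no"))
    print(utils::head(shown, 20), row.names = FALSE)
    if (nrow(x) > 20) cat("  ...", nrow(x) - 20, "more row(s)\n")
  }
  excl <- attr(x, "exclusions")
  if (length(excl)) cat("Exclusions:\n ", paste(excl, collapse = "\n  "), "\n")
  invisible(x)
}
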