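#' Reference screening datasets
#'
#' Small reference tables from a screening survey of 43 microalgal strains
#' isolated from urban stormwater ponds, a municipal wastewater-treatment
#' system and nearby natural waters, shipped with the package as worked
#' inputs:
#'
#' * `ref_growth_rates()` — specific growth rate (d^-1) and generation
#'   time (h) for all 43 isolates under standardised batch conditions.
#' * `ref_biodiesel_indices()` — the six biodiesel-quality indices (CN,
#'   IV, DU, LCSF, SV, CFPP) for the 34 axenic isolates whose FAME
#'   profiles were measured by GC-MS.
#' * `ref_copper_inhibition()` — average percent inhibition at 0.01 and
#'   0.1 mg/L copper for the six bioassay test strains, with the copper
#'   concentration of each strain's source habitat.
#'
#' @return A data.frame.
#' @name reference_data
NULL

ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "phycoscreen")
  if (path == "") stopf("reference file %s not found", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_data
#' @export
ref_growth_rates <- function() ref_csv("ref_growth_rates.csv")

#' @rdname reference_data
#' @export
ref_biodiesel_indices <- function() ref_csv("ref_biodiesel_indices.csv")

#' @rdname reference_data
#' @export
ref_copper_inhibition <- function() ref_csv("ref_copper_inhibition.csv")
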