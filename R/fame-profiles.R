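#' Normalise a GC-MS peak table into a compositional FAME profile
#'
#' Removes the internal-standard peak (nonadecanoate, C19:0, by default),
#' drops peaks whose label does not parse as fatty-acid shorthand (with a
#' warning reporting the excluded fraction), and rescales the remaining
#' areas to weight percent of total identified FAME (sum 100).
#'
#' @param peaks named numeric vector of peak areas or concentrations; names
#'   are fatty-acid shorthand labels.
#' @param internal_standard label of the internal-standard species removed
#'   before normalisation (default `"C19:0"`).
#' @return Named numeric vector of wt% abundances summing to 100, names in
#'   canonical shorthand, with attribute `excluded_fraction` (fraction of
#'   total signal carried by unidentified peaks).
#' @examples
#' normalize_profile(c("C16:0" = 1, "C18:1" = 3))
#' @export
normalize_profile <- function(peaks, internal_standard = "C19:0") {
  if (is.null(names(peaks)) || any(!nzchar(names(peaks))))
    stopf("peaks must be a named numeric vector")
  if (any(!is.finite(peaks)) || any(peaks < 0))
    stopf("peak values must be finite and non-negative")
  parsed_ok <- vapply(names(peaks), function(nm) {
    !inherits(try(parse_one_fatty_acid(nm), silent = TRUE), "try-error")
  }, logical(1))
  total <- sum(peaks)
  excluded <- sum(peaks[!parsed_ok])
  if (any(!parsed_ok))
    warning(sprintf(
      "excluding %d unidentified peak(s) (%s): %.1f%% of total signal",
      sum(!parsed_ok), paste(names(peaks)[!parsed_ok], collapse = ", "),
      if (total > 0) 100 * excluded / total else 0), call. = FALSE)
  peaks <- peaks[parsed_ok]
  canon <- vapply(names(peaks), function(nm) parse_one_fatty_acid(nm)$label,
                  character(1))
  names(peaks) <- canon
  is_std <- canon == parse_one_fatty_acid(internal_standard)$label
  peaks <- peaks[!is_std]
  if (length(peaks) == 0L || sum(peaks) <= 0)
    stopf("no positive non-internal-standard peaks to normalise")
  # collapse duplicate canonical labels
  peaks <- tapply(peaks, names(peaks), sum)
  out <- 100 * as.numeric(peaks) / sum(peaks)
  names(out) <- names(peaks)
  attr(out, "excluded_fraction") <- if (total > 0) excluded / total else 0
  out
}

#' Saturated / monounsaturated / polyunsaturated class fractions
#'
#' Partitions a compositional profile's wt% by double-bond count: 0 (SFA),
#' exactly 1 (MUFA), 2 or more (PUFA). The three fractions conserve the
#' profile total.
#'
#' @param profile named numeric vector of wt% abundances (names are
#'   fatty-acid shorthand labels).
#' @return Named numeric vector `c(sfa = , mufa = , pufa = )` in wt%.
#' @export
class_fractions <- function(profile) {
  if (length(profile) == 0L) return(c(sfa = 0, mufa = 0, pufa = 0))
  sp <- parse_fatty_acid(names(profile))
  d <- sp$double_bonds
  c(sfa = sum(profile[d == 0]),
    mufa = sum(profile[d == 1]),
    pufa = sum(profile[d >= 2]))
}

#' Read a FAME composition table
#'
#' Accepts either long format (columns `strain`, `species`, `value`) or wide
#' format (a `strain` column plus one column per fatty-acid species); the
#' layout is auto-detected from the header.
#'
#' @param path CSV or TSV file (delimiter auto-detected from the extension;
#'   `.tsv`/`.txt` are read as tab-separated).
#' @return Numeric matrix, strains in rows, species in columns (raw values,
#'   not yet normalised).
#' @seealso [normalize_profile()], [normalize_profiles()]
#' @export
read_fame_table <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1] <- tolower(names(df)[1])
  cols <- tolower(names(df))
  if (all(c("strain", "species", "value") %in% cols)) {
    names(df) <- cols
    m <- tapply(df$value, list(df$strain, df$species), sum, default = 0)
    m <- as.matrix(m)
  } else {
    strain_col <- which(cols == "strain")
    if (length(strain_col) != 1L)
      stopf("%s: expected columns strain/species/value or a 'strain' column plus species columns; found: %s",
            path, paste(names(df), collapse = ", "))
    m <- as.matrix(df[, -strain_col, drop = FALSE])
    rownames(m) <- as.character(df[[strain_col]])
  }
  storage.mode(m) <- "double"
  m
}

#' Normalise every row of a raw peak matrix
#'
#' @param peak_matrix strains x species matrix of raw peak values.
#' @param internal_standard passed to [normalize_profile()].
#' @return strains x species matrix of wt% with rows summing to 100
#'   (internal-standard column removed).
#' @export
normalize_profiles <- function(peak_matrix, internal_standard = "C19:0") {
  rows <- lapply(rownames(peak_matrix), function(s) {
    normalize_profile(peak_matrix[s, ], internal_standard = internal_standard)
  })
  species <- sort(unique(unlist(lapply(rows, names))))
  out <- matrix(0, nrow = length(rows), ncol = length(species),
                dimnames = list(rownames(peak_matrix), species))
  for (i in seq_along(rows)) out[i, names(rows[[i]])] <- rows[[i]]
  out
}

#' Write a profile matrix as a long-format CSV
#'
#' @param profiles strains x species numeric matrix.
#' @param path output CSV path.
#' @export
write_fame_table <- function(profiles, path) {
  df <- data.frame(
    strain = rep(rownames(profiles), times = ncol(profiles)),
    species = rep(colnames(profiles), each = nrow(profiles)),
    value = as.vector(profiles))
  df <- df[df$value != 0 | TRUE, ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
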