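#' Parse fatty-acid shorthand notation
#'
#' Parses labels of the form `C<X>:<Y>` with an optional omega qualifier
#' `(n-<z>)` and an optional `cis`/`trans` geometry suffix, e.g. `"C16:0"`,
#' `"C16:4(n-3)"`, `"C18:1cis"`. `X` is the number of acyl carbons and `Y`
#' the number of carbon-carbon double bonds.
#'
#' @param x character vector of shorthand labels.
#' @return A data.frame with one row per label and columns `label`
#'   (canonical form), `carbons`, `double_bonds`, `omega` (integer or `NA`)
#'   and `geometry` (`"cis"`, `"trans"` or `"unspecified"`).
#' @examples
#' parse_fatty_acid(c("C16:0", "C16:4(n-3)", "C18:1cis"))
#' @export
parse_fatty_acid <- function(x) {
  out <- lapply(x, parse_one_fatty_acid)
  df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

parse_one_fatty_acid <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stopf("fatty-acid label must be a single string")
  txt <- trimws(s)
  fail <- function(pos, why) {
    stopf("cannot parse fatty-acid label '%s' at position %d: %s", s, pos, why)
  }
  n <- nchar(txt)
  if (n == 0L) fail(1L, "empty string")
  if (toupper(substr(txt, 1, 1)) != "C") fail(1L, "expected 'C'")
  i <- 2L
  take_int <- function(i, what) {
    j <- i
    while (j <= n && grepl("[0-9]", substr(txt, j, j))) j <- j + 1L
    if (j == i) fail(i, paste("expected", what))
    list(value = as.integer(substr(txt, i, j - 1L)), next_pos = j)
  }
  carb <- take_int(i, "carbon count")
  i <- carb$next_pos
  if (i > n || substr(txt, i, i) != ":") fail(i, "expected ':'")
  db <- take_int(i + 1L, "double-bond count")
  i <- db$next_pos
  omega <- NA_integer_
  if (i <= n && substr(txt, i, i) == "(" &&
      grepl("^\\([nN]-", substr(txt, i, min(n, i + 2L)))) {
    om <- take_int(i + 3L, "omega position")
    i <- om$next_pos
    if (i > n || substr(txt, i, i) != ")") fail(i, "expected ')'")
    omega <- om$value
    i <- i + 1L
  }
  geometry <- "unspecified"
  if (i <= n) {
    rest <- tolower(substr(txt, i, n))
    rest <- sub("^[-( ]+", "", rest)
    rest <- sub("[)]$", "", rest)
    if (rest %in% c("cis", "c")) geometry <- "cis"
    else if (rest %in% c("trans", "t")) geometry <- "trans"
    else fail(i, sprintf("unexpected trailing text '%s'", substr(txt, i, n)))
  }
  carbons <- carb$value
  double_bonds <- db$value
  if (carbons < 1L) fail(2L, "carbon count must be positive")
  if (double_bonds > floor(carbons / 2))
    stopf("invalid species '%s': %d double bonds exceed floor(%d/2)",
          s, double_bonds, carbons)
  list(label = format_fatty_acid(carbons, double_bonds, omega, geometry),
       carbons = carbons, double_bonds = double_bonds,
       omega = omega, geometry = geometry)
}

#' Canonical fatty-acid shorthand label
#'
#' @param carbons acyl carbon count.
#' @param double_bonds number of double bonds.
#' @param omega optional omega position (`NA` to omit).
#' @param geometry `"cis"`, `"trans"` or `"unspecified"` (omitted).
#' @return Canonical label string, e.g. `"C16:4(n-3)"`.
#' @export
format_fatty_acid <- function(carbons, double_bonds, omega = NA,
                              geometry = "unspecified") {
  lab <- sprintf("C%d:%d", carbons, double_bonds)
  if (!is.na(omega)) lab <- sprintf("%s(n-%d)", lab, as.integer(omega))
  if (geometry %in% c("cis", "trans")) lab <- paste0(lab, geometry)
  lab
}

# Monoisotopic-free average atomic masses.
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999)

#' Molecular mass of a fatty-acid methyl ester
#'
#' For an acyl chain with `X` carbons and `Y` double bonds, the methyl ester
#' has formula C(X+1) H(2X+2-2Y) O2. Geometry and omega position do not
#' affect the mass.
#'
#' @param species character vector of shorthand labels, or a data.frame from
#'   [parse_fatty_acid()].
#' @return Numeric vector of masses in Da.
#' @examples
#' methyl_ester_mass("C16:0") # methyl palmitate, ~270.46
#' @export
methyl_ester_mass <- function(species) {
  sp <- if (is.data.frame(species)) species else parse_fatty_acid(species)
  x <- sp$carbons
  y <- sp$double_bonds
  (x + 1) * .atomic_mass[["C"]] +
    (2 * x + 2 - 2 * y) * .atomic_mass[["H"]] +
    2 * .atomic_mass[["O"]]
}
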