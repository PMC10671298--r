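# Lightest-isotope masses (Da), CODATA/IUPAC 2021 rounded to 8 dp. Recorded
# here (and exposed via isotope_masses()) so reported m/z values are
# reproducible to the constant.
.isotope_masses <- c(
  C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
  S = 31.97207117, Na = 22.98976928, K = 38.96370649
)
.electron_mass <- 0.00054858

#' Monoisotopic element masses used by the package
#' @return Named numeric vector of lightest-isotope masses in Da.
#' @export
isotope_masses <- function() .isotope_masses

#' Parse an elemental formula
#'
#' Parses Hill-style `Element[count]` tokens (count 1 implicit) over the
#' supported element set C, H, N, O, S, Na, K.
#'
#' @param text Formula string, e.g. `"C12H12N2O6S2"`.
#' @return Named integer vector of element counts, class `elemental_formula`.
#' @examples
#' parse_formula("C12H13N2O6S2")
#' @export
parse_formula <- function(text) {
  if (inherits(text, "elemental_formula")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s", "", text)
  if (!nzchar(s)) abort("empty elemental formula")
  tokens <- stringr::str_match_all(s, "([A-Z][a-z]?)([0-9]*)")[[1]]
  if (sum(nchar(tokens[, 1])) != nchar(s)) {
    abort(paste0("malformed elemental formula: '", text, "'"))
  }
  bad <- setdiff(tokens[, 2], names(.isotope_masses))
  if (length(bad) > 0L) {
    abort(paste0("unsupported element '", bad[1], "' in formula '", text, "'"))
  }
  counts <- as.integer(ifelse(tokens[, 3] == "", "1", tokens[, 3]))
  out <- tapply(counts, tokens[, 2], sum)
  out <- setNames(as.integer(out), names(out))
  if (sum(out) == 0L) abort("formula has no atoms")
  structure(out[order(names(out))], class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ",
    paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = ""),
    "  (", sprintf("%.8f", monoisotopic_mass(x)), " Da)\n",
    sep = ""
  )
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times lightest-isotope masses (the carbon-12 scale,
#' so `"C"` is exactly 12 Da).
#'
#' @param formula An `elemental_formula` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.01056468
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(unclass(f) * .isotope_masses[names(f)])
}

# what each adduct adds to the neutral molecule (all singly positively charged)
.adduct_added <- list(
  "M+H" = c(H = 1L),
  "M+Na" = c(Na = 1L),
  "M+K" = c(K = 1L),
  "M+NH4" = c(N = 1L, H = 4L)
)

#' Theoretical adduct-ion m/z
#'
#' Monoisotopic m/z of a singly charged positive adduct ion: the neutral
#' monoisotopic mass plus the adduct atoms, minus one electron mass
#' (0.00054858 Da) — the standard HRMS-ESI convention. Values are returned at
#' full precision; HRMS identities are conventionally quoted to 4 decimal
#' places (`round(x, 4)`).
#'
#' @param neutral Neutral-molecule formula (string or `elemental_formula`).
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M+K"`, `"M+NH4"`.
#' @return m/z in Th.
#' @examples
#' round(adduct_mz("C12H12N2O6S2", "M+H"), 4) # 345.0210
#' round(adduct_mz("C20H30N4O6", "M+Na"), 4) # 445.2058
#' @export
adduct_mz <- function(neutral, adduct = c("M+H", "M+Na", "M+K", "M+NH4")) {
  adduct <- match.arg(adduct)
  added <- .adduct_added[[adduct]]
  monoisotopic_mass(neutral) + sum(added * .isotope_masses[names(added)]) -
    .electron_mass
}

#' Packaged HRMS identity registry
#'
#' The compound registry of the bis(isoxazole) series (1d, 3a-3j): neutral
#' elemental formula, the adduct under which each HRMS identity was recorded,
#' and the published calculated/found m/z values. `known_discrepant` flags
#' entries whose published "calculated" value is inconsistent with the stated
#' formula or with the single-electron-subtraction convention (wrong formula
#' printed, copy-paste of a neighbouring value, or a rounding slip); these are
#' excluded from golden identity checks. The `note` column says why.
#'
#' @param path Path to the registry TSV (default: packaged copy).
#' @return Tibble with columns `compound_id`, `neutral_formula`, `adduct`,
#'   `mz_calc_printed`, `mz_found_printed`, `known_discrepant`, `note`.
#' @export
hrms_registry <- function(path = system.file("extdata", "hrms_registry.tsv",
                                             package = "lbdgeo")) {
  readr::read_tsv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    neutral_formula = readr::col_character(),
    adduct = readr::col_character(),
    mz_calc_printed = readr::col_double(),
    mz_found_printed = readr::col_double(),
    known_discrepant = readr::col_logical(),
    note = readr::col_character()
  ))
}

#' Validate HRMS identities against the registry
#'
#' Recomputes every registry entry's theoretical adduct-ion m/z from its
#' neutral formula and compares it with the published calculated value.
#'
#' @param registry Registry tibble, as from [hrms_registry()].
#' @param tol_mz Match tolerance in Th (default 5e-4, i.e. agreement at the
#'   4-decimal reporting precision).
#' @return The registry with added columns `mz_calc` (recomputed, full
#'   precision) and `matches_printed`.
#' @examples
#' val <- validate_hrms()
#' dplyr::filter(val, !known_discrepant)
#' @export
validate_hrms <- function(registry = hrms_registry(), tol_mz = 5e-4) {
  registry |>
    dplyr::mutate(
      mz_calc = purrr::map2_dbl(.data$neutral_formula, .data$adduct, adduct_mz),
      matches_printed = abs(.data$mz_calc - .data$mz_calc_printed) <= tol_mz
    )
}
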