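#' Load a concentration-response table
#'
#' Reads the packaged (or a user-supplied) transcription of the
#' patch-clamp activity table: one row per compound, one column per modulator
#' concentration, cells of the form `"amplitude ± sd"` (current amplitude as
#' percent of the kainate-evoked control), with `"–"` (or `"-"`) marking
#' concentrations that were not tested. Reference rows (cyclothiazide `CTZ`
#' and the earlier bivalent reference compound `I`) are flagged so they can
#' be excluded from feature matrices.
#'
#' @param path Path to the TSV. Default: the packaged transcription.
#' @return Long tibble with columns `compound_id`, `n_neurons`,
#'   `is_reference`, `conc_M` (molar), `amplitude_pct`, `sd_pct`, sorted by
#'   compound and increasing concentration.
#' @examples
#' act <- load_table3()
#' dplyr::filter(act, compound_id == "3j")
#' @export
load_table3 <- function(path = system.file("extdata", "activity_table3.tsv",
                                           package = "lbdgeo")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) {
    return(tibble::tibble(
      compound_id = character(), n_neurons = integer(), is_reference = logical(),
      conc_M = numeric(), amplitude_pct = numeric(), sd_pct = numeric()
    ))
  }
  conc_cols <- setdiff(names(raw), c("compound", "n_neurons", "is_reference"))
  long <- tidyr::pivot_longer(raw, dplyr::all_of(conc_cols),
    names_to = "conc_M", values_to = "cell")
  long$conc_M <- as.numeric(long$conc_M)
  if (any(is.na(long$conc_M))) {
    abort("activity table: concentration column names must be numeric (molar)")
  }

  cell <- trimws(long$cell)
  missing_cell <- is.na(cell) | cell %in% c("", "-", "–", "—")
  m <- stringr::str_match(cell, "^([0-9]+(?:\\.[0-9]+)?)\\s*(?:±|\\+/-)\\s*([0-9]+(?:\\.[0-9]+)?)$")
  bad <- which(!missing_cell & is.na(m[, 1]))
  if (length(bad) > 0L) {
    abort(paste0("malformed activity cell for compound '", long$compound[bad[1]],
      "' at concentration ", long$conc_M[bad[1]], ": '", cell[bad[1]], "'"))
  }

  out <- tibble::tibble(
    compound_id = long$compound,
    n_neurons = as.integer(long$n_neurons),
    is_reference = tolower(long$is_reference) %in% c("true", "1", "yes"),
    conc_M = long$conc_M,
    amplitude_pct = as.numeric(m[, 2]),
    sd_pct = as.numeric(m[, 3])
  )
  out <- out[!missing_cell, , drop = FALSE]
  if (any(out$amplitude_pct <= 0)) abort("activity table: amplitudes must be positive")
  dplyr::arrange(out, .data$compound_id, .data$conc_M)
}

#' Maximum potentiation or inhibition per compound
#'
#' For each compound, finds the concentration point whose amplitude deviates
#' most from the 100% control level and reports the signed effect
#' `amplitude - 100` (positive = potentiation, negative = inhibition) and the
#' concentration at which it occurs. Ties are broken toward the lower
#' concentration.
#'
#' @param activity Long activity tibble from [load_table3()].
#' @return Tibble with columns `compound_id`, `max_effect_pct`, `conc_at_max`.
#' @examples
#' max_potentiation(load_table3()) # 3j: +77 at 1e-10 M
#' @export
max_potentiation <- function(activity) {
  if (nrow(activity) == 0L) abort("max_potentiation(): no concentration points")
  activity |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::arrange(dplyr::desc(abs(.data$amplitude_pct - 100)), .data$conc_M,
      .by_group = TRUE) |>
    dplyr::summarise(
      max_effect_pct = dplyr::first(.data$amplitude_pct) - 100,
      conc_at_max = dplyr::first(.data$conc_M),
      .groups = "drop"
    )
}

#' Classify compounds as PAM, NAM or inactive
#'
#' A compound is a positive allosteric modulator (`"PAM"`) when its maximum
#' signed effect reaches `+threshold_pct`, a negative modulator (`"NAM"`)
#' when it reaches `-threshold_pct`, and `"NA"` (no activity, the standard
#' annotation) otherwise. The 10% default separates the weakest potentiator
#' in the series (max +22%) from the flat, inactive profiles.
#'
#' @param activity Long activity tibble from [load_table3()].
#' @param threshold_pct Classification threshold in percent (default 10).
#' @return Tibble with `compound_id`, `is_reference`, `activity_class`
#'   (character: `"PAM"`, `"NAM"` or `"NA"`), `max_effect_pct`, `conc_at_max`.
#' @export
classify_modulators <- function(activity, threshold_pct = 10) {
  refs <- dplyr::distinct(activity, .data$compound_id, .data$is_reference)
  max_potentiation(activity) |>
    dplyr::left_join(refs, by = "compound_id") |>
    dplyr::mutate(
      activity_class = dplyr::case_when(
        .data$max_effect_pct >= threshold_pct ~ "PAM",
        .data$max_effect_pct <= -threshold_pct ~ "NAM",
        TRUE ~ "NA"
      )
    ) |>
    dplyr::select("compound_id", "is_reference", "activity_class",
      "max_effect_pct", "conc_at_max")
}
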