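#' Partition total energy expenditure into its components
#'
#' Splits daily total energy expenditure (TEE) into resting metabolic rate
#' (RMR, measured), diet-induced thermogenesis (DIT, a fixed fraction of
#' TEE — 10% by default) and physical activity energy expenditure
#' (PAEE = TEE - RMR - DIT), and computes the physical activity level
#' (PAL = TEE/RMR). The identity `rmr + dit + paee == tee` holds by
#' construction. A negative derived PAEE (possible when measured RMR
#' exceeds 90% of a low day's TEE) is flagged in `paee_negative`, not
#' rejected.
#'
#' @param tee Total energy expenditure, kcal/day (vector).
#' @param rmr Resting metabolic rate, kcal/day (vector, recycled).
#' @param dit_fraction Fraction of TEE attributed to diet-induced
#'   thermogenesis; default 0.10.
#' @return A tibble with columns `tee`, `rmr`, `dit`, `paee`, `pal`,
#'   `paee_negative`.
#' @export
#' @examples
#' derive_components(2103, 1481)
derive_components <- function(tee, rmr, dit_fraction = 0.10) {
  if (any(tee <= 0, na.rm = TRUE) || any(rmr <= 0, na.rm = TRUE)) {
    abort("tee and rmr must be positive", class = "ebvar_domain_error")
  }
  if (dit_fraction < 0 || dit_fraction >= 1) {
    abort("dit_fraction must lie in [0, 1)", class = "ebvar_domain_error")
  }
  dit <- dit_fraction * tee
  paee <- tee - rmr - dit
  tibble::tibble(
    tee = tee, rmr = rmr, dit = dit, paee = paee,
    pal = tee / rmr,
    paee_negative = paee < 0
  )
}

#' Component shares of total energy expenditure
#'
#' Expresses each expenditure component as a percentage of TEE. The three
#' shares sum to 100 exactly.
#'
#' @param partition A tibble from [derive_components()].
#' @return A tibble with `rmr_pct`, `dit_pct`, `paee_pct`.
#' @export
#' @examples
#' derive_components(2103, 1481) |> component_shares()
component_shares <- function(partition) {
  stopifnot(all(c("tee", "rmr", "dit", "paee") %in% names(partition)))
  tibble::tibble(
    rmr_pct = 100 * partition$rmr / partition$tee,
    dit_pct = 100 * partition$dit / partition$tee,
    paee_pct = 100 * partition$paee / partition$tee
  )
}

#' Attach derived expenditure components to daily records
#'
#' Joins measured RMR from the subject table onto each subject-day, derives
#' the expenditure partition from that day's TEE, and fills the `paee_kcal`
#' and `pal` outcome columns (adding them if absent).
#'
#' @param records Daily-record tibble with a `tee_kcal` column.
#' @param subjects Subject tibble with `subject_id` and `rmr_kcal`.
#' @param dit_fraction Passed to [derive_components()].
#' @return `records` with `paee_kcal`, `pal`, `dit_kcal` columns derived
#'   from TEE and RMR.
#' @export
add_energy_components <- function(records, subjects, dit_fraction = 0.10) {
  stopifnot("tee_kcal" %in% names(records))
  joined <- dplyr::left_join(
    records, dplyr::select(subjects, "subject_id", "rmr_kcal"),
    by = "subject_id"
  )
  if (anyNA(joined$rmr_kcal)) {
    abort("Some subjects in the daily table have no RMR in the subject table",
          class = "ebvar_integrity_error")
  }
  part <- derive_components(joined$tee_kcal, joined$rmr_kcal, dit_fraction)
  records$paee_kcal <- part$paee
  records$pal <- part$pal
  records$dit_kcal <- part$dit
  records
}
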