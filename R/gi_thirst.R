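#' Gut absorption fluxes
#'
#' Gastric emptying and intestinal uptake are lumped into a single
#' first-order stage: water and sodium leave the gut lumen for plasma in
#' proportion to the unabsorbed amounts, with a default absorption half-time
#' of 12 min, so everything ingested is eventually absorbed.
#'
#' @param Gut_w Unabsorbed gut water (L), non-negative.
#' @param Gut_Na Unabsorbed gut sodium (mmol), non-negative.
#' @param params Model parameters (uses `k_abs`).
#' @return List with `flux_w` (L/min) and `flux_na` (mmol/min) to plasma.
#' @examples
#' gut_absorption(1, 0)$flux_w  # ~0.0578 L/min at a 12 min half-time
#' @export
gut_absorption <- function(Gut_w, Gut_Na, params = default_params()) {
  stopifnot(Gut_w >= 0, Gut_Na >= 0)
  list(flux_w = params$k_abs * Gut_w, flux_na = params$k_abs * Gut_Na)
}

#' Thirst drive
#'
#' Dimensionless drive that is zero below the osmotic thirst threshold
#' (set a few mOsm/kg above the vasopressin threshold, as in human
#' psychophysics) and grows linearly with serum osmolarity above it and with
#' any extracellular volume deficit.
#'
#' @param serum_osm Serum osmolarity (mOsm/kg).
#' @param volume_deficit Extracellular volume deficit (L), non-negative
#'   contribution only.
#' @param params Model parameters.
#' @return Non-negative drive (dimensionless).
#' @export
thirst_drive <- function(serum_osm, volume_deficit = 0,
                         params = default_params()) {
  pmax(0, params$thirst_osm_gain * (serum_osm - params$thirst_thr)) +
    pmax(0, params$thirst_vol_gain * volume_deficit)
}

#' Ad-libitum drinking rate
#'
#' Drinking happens only while an ad-libitum window is open: the rate is a
#' saturating function of the thirst drive, capped at a burst maximum and
#' damped by two satiation signals — gastric distension (instantaneous gut
#' fill) and a pre-absorptive quench driven by the oropharyngeal
#' recent-ingestion integrator, which keeps drinking front-loaded at the
#' start of a window the way humans gulp then stop before osmolality has
#' changed.
#'
#' @param drive Thirst drive from [thirst_drive()].
#' @param ad_lib_open Logical, whether water is available.
#' @param gut_fill Current gut water content (L).
#' @param params Model parameters.
#' @param oro Oropharyngeal recent-ingestion state (0 = nothing drunk
#'   recently).
#' @return Drinking rate (mL/min).
#' @export
drinking_rate <- function(drive, ad_lib_open, gut_fill,
                          params = default_params(), oro = 0) {
  if (!ad_lib_open || drive <= 0) return(0)
  satiation <- 1 / (1 + (gut_fill / params$gut_satiation)^2)
  quench <- exp(-params$thirst_quench * oro)
  params$drink_rate_max * drive / (drive + params$K_drive) * satiation * quench
}

#' Apply an instantaneous-start intake event to a fluid state
#'
#' Utility mirroring what the engine does continuously: an oral load adds its
#' full volume and sodium to the gut (and its water to cumulative intake),
#' an IV infusion adds directly to plasma water and extracellular sodium.
#' Within the engine the same amounts are delivered at a constant rate over
#' the event duration.
#'
#' @param event An event row from [build_protocol()] (or a list with `kind`,
#'   `volume_ml`, `na_mmol_per_l`).
#' @param state A [fluid_state()].
#' @return The updated `osmo_fluid_state`.
#' @export
apply_intake_event <- function(event, state) {
  kind <- event$kind
  vol_l <- event$volume_ml / 1000
  na_mmol <- vol_l * event$na_mmol_per_l
  stopifnot(vol_l >= 0, na_mmol >= 0)
  if (kind == "oral_load") {
    state$Gut_w <- state$Gut_w + vol_l
    state$Gut_Na <- state$Gut_Na + na_mmol
    state$CWI <- state$CWI + vol_l
  } else if (kind == "iv_infusion") {
    state$V_pl <- state$V_pl + vol_l
    state$Na_ec <- state$Na_ec + na_mmol
  } else {
    stop("apply_intake_event: not an intake event kind: ", kind)
  }
  state
}
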