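#' Osmotic water flux into the intracellular space
#'
#' Water crosses the cell membrane down its osmotic gradient: when the
#' extracellular fluid is hypertonic relative to the cell interior, water
#' leaves the cells (negative flux); the flux is antisymmetric in its
#' arguments.
#'
#' @param icf_osm,ecf_osm Intracellular and extracellular osmolarity
#'   (mOsm/kg), both positive.
#' @param k_osm Osmotic water conductance (L/min per mOsm/kg).
#' @return Water flux into the ICF (L/min).
#' @examples
#' osmotic_flux(288, 298, 0.01)  # -0.1: water exits the cells
#' @export
osmotic_flux <- function(icf_osm, ecf_osm, k_osm) {
  stopifnot(icf_osm > 0, ecf_osm > 0, k_osm >= 0)
  k_osm * (icf_osm - ecf_osm)
}

#' Plasma colloid osmotic (oncotic) pressure
#'
#' Cubic protein-concentration curve (Landis-Pappenheimer shape) rescaled so
#' that 7 g/dL maps to the packaged anchor of 25 mmHg. Zero at zero protein,
#' monotone increasing and convex.
#'
#' @param prot_conc Plasma protein concentration (g/dL), non-negative.
#' @param params Model parameters.
#' @return Oncotic pressure (mmHg).
#' @export
oncotic_pressure <- function(prot_conc, params = default_params()) {
  stopifnot(all(prot_conc >= 0))
  params$onc_scale *
    (2.1 * prot_conc + 0.16 * prot_conc^2 + 0.009 * prot_conc^3)
}

#' Starling transcapillary filtration
#'
#' Net capillary-to-interstitium water flux from the balance of hydrostatic
#' and oncotic pressures: `K_f * ((P_c - P_i) - sigma * (pi_c - pi_i))`.
#'
#' @param P_c,P_i Capillary and interstitial hydrostatic pressures (mmHg).
#' @param pi_c,pi_i Plasma and interstitial oncotic pressures (mmHg).
#' @param K_f Filtration coefficient (mL/min/mmHg), non-negative.
#' @param sigma Protein reflection coefficient in `[0, 1]`.
#' @return Filtration rate (mL/min), positive out of the capillary.
#' @examples
#' starling_flux(17, -3, 25, 5, K_f = 0.5, sigma = 1)  # balanced: 0
#' @export
starling_flux <- function(P_c, P_i, pi_c, pi_i, K_f, sigma) {
  stopifnot(K_f >= 0, sigma >= 0, sigma <= 1)
  K_f * ((P_c - P_i) - sigma * (pi_c - pi_i))
}

#' Lymphatic return flow
#'
#' Lymph drains interstitial fluid back to plasma. Valves prevent backflow,
#' so the flow is zero at or below the interstitial-pressure threshold, rises
#' linearly with pressure above it, and saturates at `lymph_max`.
#'
#' @param P_i Interstitial hydrostatic pressure (mmHg).
#' @param params Model parameters (uses `lymph_thr`, `lymph_sens`,
#'   `lymph_max`).
#' @return Lymph flow (mL/min), always non-negative.
#' @export
lymph_flow <- function(P_i, params = default_params()) {
  pmin(params$lymph_max, params$lymph_sens * pmax(0, P_i - params$lymph_thr))
}

# raw vascular resistance multipliers (1 at zero hormone); hemodynamics()
# normalises their baseline product away so MAP is anchored at map0
tpr_multiplier <- function(avp, angii, params) {
  avp_m <- avp_effects(avp, params)$vascular_mult
  angii_m <- 1 + params$angii_vasc_gain * (angii - 1)
  avp_m * max(0.2, angii_m)
}

#' Minimal hemodynamics: pressures from blood volume and hormones
#'
#' Cardiac output is eliminated as an explicit variable: mean arterial
#' pressure is an affine, increasing function of blood volume scaled by the
#' total-peripheral-resistance multiplier (vasopressin and angiotensin II
#' pressor effects, normalised to 1 at baseline hormones). Capillary and
#' right-atrial pressures are affine in MAP and blood volume; interstitial
#' pressure is affine in interstitial volume (compliance).
#'
#' @param blood_volume Blood volume (L), positive.
#' @param hormones Named list or vector with at least `avp` (pg/mL) and
#'   `angii` (relative).
#' @param params Model parameters.
#' @param v_is Interstitial volume (L); defaults to the baseline volume.
#' @return A list of class `osmo_pressures`: `map_mmHg`, `P_c`, `P_i`,
#'   `P_ra`, `tpr_mult`.
#' @examples
#' hemodynamics(5.1, list(avp = 2.5, angii = 1))$map_mmHg  # 93 at baseline
#' @export
hemodynamics <- function(blood_volume, hormones, params = default_params(),
                         v_is = params$V_is0) {
  stopifnot(blood_volume > 0)
  tpr <- tpr_multiplier(hormones$avp, hormones$angii, params) / params$tpr_base
  map <- (params$map0 + params$k_bv * (blood_volume - params$BV0)) * tpr
  structure(
    list(
      map_mmHg = map,
      P_c = params$P_c0 + params$pc_map * (map - params$map0) +
        params$pc_bv * (blood_volume - params$BV0),
      P_i = params$P_i0 + (v_is - params$V_is0) / params$C_is,
      P_ra = params$p_ra0 + params$k_ra * (blood_volume - params$BV0),
      tpr_mult = tpr
    ),
    class = c("osmo_pressures", "list")
  )
}

#' Baroreceptor signals
#'
#' Arterial (carotid) and cardiac (atrial) stretch-receptor activities as
#' sigmoids of mean arterial and right-atrial pressure, each normalised to 1
#' at the baseline operating point and bounded in (0, 2). Activity falls when
#' pressure falls; the vasopressin secretion model amplifies secretion when
#' the combined activity is below 1 (hypovolemia/hypotension stimulates
#' release, the standard reflex sign).
#'
#' @param pressures An `osmo_pressures` list from [hemodynamics()].
#' @param params Model parameters.
#' @return A list with elements `arterial` and `cardiac`.
#' @export
baro_signals <- function(pressures, params = default_params()) {
  list(
    arterial = 2 / (1 + exp(-params$baro_s_art *
                              (pressures$map_mmHg - params$map0))),
    cardiac = 2 / (1 + exp(-params$baro_s_card *
                             (pressures$P_ra - params$p_ra0)))
  )
}
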