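#' Vasopressin secretion rate
#'
#' Osmotically driven release from the neurohypophyseal store: a small
#' non-osmotic floor plus a linear supra-threshold osmotic term, multiplied
#' by a baroreceptor modulation that amplifies secretion when the combined
#' arterial/cardiac signal is below baseline (hypovolemia or hypotension
#' stimulates release) and damps it above. Secretion is limited when the
#' store runs low and is zero from an empty store.
#'
#' @param serum_osm Serum osmolarity (mOsm/kg).
#' @param baro List with `arterial` and `cardiac` signals
#'   (see [baro_signals()]).
#' @param store Neurohypophyseal store (pg), non-negative.
#' @param params Model parameters.
#' @return Secretion rate (pg/min).
#' @export
avp_secretion <- function(serum_osm, baro, store, params = default_params()) {
  stopifnot(store >= 0)
  combined <- params$baro_w * baro$arterial + (1 - params$baro_w) * baro$cardiac
  baro_mult <- max(0.1, 1 + params$baro_gain * (1 - combined))
  sfac <- min(1, store / params$store_ref)
  drive <- params$avp_sec_floor +
    params$osm_gain * max(0, serum_osm - params$osm_threshold)
  sfac * baro_mult * drive
}

#' First-order hormone plasma kinetics
#'
#' `d(conc)/dt = secretion/V_d - (ln 2 / half_life) * conc`; with secretion
#' stopped, concentration halves every `half_life` minutes.
#'
#' @param conc Plasma concentration (pg/mL).
#' @param secretion_rate Secretion into plasma (pg/min).
#' @param distribution_volume Distribution volume (mL).
#' @param half_life Circulating half-life (min), positive.
#' @return Time derivative of concentration (pg/mL/min).
#' @examples
#' hormone_kinetics(2.5, 0, 3000, 20)  # pure exponential decay
#' @export
hormone_kinetics <- function(conc, secretion_rate, distribution_volume,
                             half_life) {
  stopifnot(half_life > 0, distribution_volume > 0)
  secretion_rate / distribution_volume - (log(2) / half_life) * conc
}

#' Atrial natriuretic peptide secretion
#'
#' Relative secretion rate, monotone increasing in right atrial pressure
#' (atrial stretch) and equal to 1 at the baseline operating point. The gain
#' is calibrated on the acute-water-load protocol so peak circulating ANP
#' rises 33\% over baseline.
#'
#' @param P_ra Right atrial pressure (mmHg).
#' @param params Model parameters.
#' @return Relative secretion rate (dimensionless, non-negative).
#' @export
anp_secretion <- function(P_ra, params = default_params()) {
  pmax(0, 1 + params$anp_gain * (P_ra - params$p_ra0))
}

#' Renin-angiotensin-aldosterone cascade derivatives
#'
#' Renin secretion falls with renal perfusion pressure and with macula densa
#' sodium delivery; plasma renin activity relaxes to its secretion drive with
#' a fast time constant, angiotensin II tracks renin activity quickly, and
#' aldosterone tracks angiotensin II over hours. All three are expressed
#' relative to baseline and relax to 1 at baseline inputs.
#'
#' @param map_mmHg Mean arterial pressure (mmHg).
#' @param na_md Macula densa sodium delivery (mmol/min,
#'   per-nephron-normalised).
#' @param baro Baroreceptor signals (accepted for interface completeness;
#'   the packaged gains route the reflex through perfusion pressure).
#' @param state Named vector/list with `pra`, `angii`, `aldo`.
#' @param params Model parameters.
#' @return Named list of derivatives `d_pra`, `d_angii`, `d_aldo` (per min).
#' @export
raas_cascade <- function(map_mmHg, na_md, baro, state,
                         params = default_params()) {
  r_sec <- max(0, 1 - params$renin_map_gain * (map_mmHg - params$map0) -
                 params$renin_md_gain * (na_md - params$na_md0))
  list(
    d_pra = (r_sec - state$pra) / params$tau_renin,
    d_angii = (state$pra - state$angii) / params$tau_angii,
    d_aldo = (state$angii - state$aldo) / params$tau_aldo
  )
}

#' Vasopressin end-organ effects
#'
#' Collecting-duct water permeability is a Hill function of plasma AVP
#' (aquaporin-2 recruitment), rising from `perm_min` at zero hormone and
#' saturating at `perm_max`; the Hill constant is calibrated so baseline AVP
#' reproduces the baseline urine flow. The vascular (pressor) effect is a
#' second Hill curve with a supraphysiologic EC50, so the resistance
#' multiplier is only mildly above 1 at baseline concentrations.
#'
#' @param avp Plasma vasopressin (pg/mL), non-negative.
#' @param params Model parameters.
#' @return List with `vascular_mult` (>= 1) and `cd_perm` (fraction in
#'   `[perm_min, perm_max]`).
#' @examples
#' avp_effects(0)$cd_perm    # perm_min: no hormone, maximally dilute urine
#' avp_effects(1e6)$cd_perm  # saturates at perm_max
#' @export
avp_effects <- function(avp, params = default_params()) {
  stopifnot(all(avp >= 0))
  n <- params$K_avp_cd_n
  h <- avp^n / (avp^n + params$K_avp_cd^n)
  list(
    vascular_mult = 1 + params$vasc_max * avp^2 / (avp^2 + params$K_vasc^2),
    cd_perm = params$perm_min + (params$perm_max - params$perm_min) * h
  )
}

# neurohypophyseal store replenishment: synthesis slows as the store refills
avp_synthesis <- function(store, params) {
  params$synth_max * max(0, 1 - store / params$store_max)
}
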