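#' Define a virtual subject
#'
#' A subject fixes the anthropometry from which all compartment sizes are
#' derived: total body water is `body_mass * tbw_fraction`, of which
#' `icf_fraction` is intracellular; the extracellular remainder is split
#' between interstitium and plasma by the `plasma_frac_of_ecf` model
#' parameter. The kidney of the whole model is a single nephron whose output
#' is scaled by `nephron_multiplier` (1 = the full complement of filtering
#' nephrons of the calibrated subject).
#'
#' @param body_mass Body mass in kg. The packaged protocols use 74 kg.
#' @param tbw_fraction Total body water as a fraction of body mass.
#' @param icf_fraction Fraction of total body water that is intracellular.
#' @param nephron_multiplier Relative number of filtering nephrons
#'   (dimensionless, 1 = calibrated baseline).
#' @param param_overrides Named list of model parameter overrides, merged
#'   into [default_params()] before derived calibration constants are
#'   computed.
#' @return An object of class `osmo_subject`.
#' @examples
#' s <- default_subject()
#' s$body_mass
#' @export
default_subject <- function(body_mass = 74, tbw_fraction = 0.60,
                            icf_fraction = 2 / 3, nephron_multiplier = 1,
                            param_overrides = list()) {
  stopifnot(
    "body_mass must be > 0" = body_mass > 0,
    "tbw_fraction must be in (0, 1)" = tbw_fraction > 0 && tbw_fraction < 1,
    "icf_fraction must be in (0, 1)" = icf_fraction > 0 && icf_fraction < 1,
    "nephron_multiplier must be > 0" = nephron_multiplier > 0
  )
  structure(
    list(
      body_mass = body_mass,
      tbw_fraction = tbw_fraction,
      icf_fraction = icf_fraction,
      nephron_multiplier = nephron_multiplier,
      param_overrides = param_overrides
    ),
    class = "osmo_subject"
  )
}

#' @export
print.osmo_subject <- function(x, ...) {
  cat(sprintf(
    "<osmo_subject> %.1f kg, TBW %.1f L (ICF %.1f L), nephrons x%.2f\n",
    x$body_mass, x$body_mass * x$tbw_fraction,
    x$body_mass * x$tbw_fraction * x$icf_fraction, x$nephron_multiplier
  ))
  invisible(x)
}

# Primitive defaults. Anything the model pins by calibration is
# computed from these anchors in default_params() so the baseline state is an
# exact fixed point of the differential system.
osmo_primitives <- function() {
  list(
    ## -- compartment geometry (fractions of subject-derived volumes) --
    plasma_frac_of_ecf = 3 / 14.8,  # 3 L plasma water for a 74 kg subject
    rbc_to_plasma      = 0.70,      # V_rbc / V_pl -> baseline hct 0.412

    ## -- baseline concentrations / anchors --
    serum_na0   = 140,    # mmol/L
    serum_osm0  = 288,    # mOsm/kg; offset over 2*[Na] covers urea/glucose
    prot_conc0  = 7,      # g/dL
    avp0        = 2.5,    # pg/mL (baseline plasma vasopressin)

    ## -- osmotic & capillary exchange --
    k_osm      = 0.01,    # L/min per mOsm/kg, transmembrane water conductance
    K_f        = 2,       # mL/min/mmHg capillary filtration coefficient
    sigma      = 0.95,    # protein reflection coefficient
    pi_i       = 5,       # mmHg interstitial oncotic pressure (static)
    onc_anchor = 25,      # mmHg plasma oncotic pressure at 7 g/dL
    P_c0       = 17,      # mmHg baseline capillary hydrostatic pressure
    P_i0       = -3,      # mmHg baseline interstitial pressure
    lymph_thr  = -5,      # mmHg, valve opening threshold
    lymph_max  = 30,      # mL/min lymph saturation
    C_is       = 1,       # L/mmHg interstitial compliance
    pc_map     = 0.1,     # dP_c / dMAP
    pc_bv      = 2,       # mmHg per L blood volume

    ## -- hemodynamics & baroreceptors --
    map0        = 93,     # mmHg baseline mean arterial pressure
    p_ra0       = 0,      # mmHg baseline right atrial pressure
    k_bv        = 15,     # mmHg MAP per L blood volume (volume loading curve)
    k_ra        = 3,      # mmHg P_ra per L blood volume
    baro_s_art  = 0.04,   # arterial sigmoid slope, per mmHg
    baro_s_card = 0.30,   # cardiac sigmoid slope, per mmHg
    baro_w      = 0.5,    # arterial weight in the combined baro signal

    ## -- kidney --
    GFR0      = 125,      # mL/min baseline glomerular filtration
    RBF0      = 600,      # mL/min baseline renal blood flow
    P_glom0   = 53,       # mmHg baseline glomerular capillary pressure
    P_bow     = 18,       # mmHg Bowman's space pressure
    P_rv      = 4,        # mmHg renal venous pressure
    g_myo     = 0.025,    # afferent myogenic gain, per mmHg MAP
    myo_min   = 0.5,
    myo_max   = 2,
    tgf_min   = 0.5,      # afferent resistance multiplier bounds
    tgf_max   = 2,
    tgf_slope = 2,        # per mmol/min macula densa sodium delivery
    f_PT      = 0.67,     # proximal fractional reabsorption (water and Na)
    f_LH_na   = 0.25,     # loop of Henle: fraction of filtered Na reabsorbed
    f_LH_w    = 0.15,     # loop of Henle: fraction of filtered water
    urine0    = 0.58,     # mL/min calibrated baseline urine flow
    aldo_coef = 0.05,     # distal Na reabsorption gain on aldosterone
    anp_coef  = 0.80,     # distal Na reabsorption reduction per unit ANP rise
    osm_obligate = 0.13,  # mOsm/min obligate non-sodium osmolar excretion
    U_min     = 50,       # mOsm/kg minimal urine osmolarity
    U_max     = 1200,     # mOsm/kg maximal urine osmolarity
    urine_dilution = "physiologic",  # or "hummod": caps dilution at 324

    ## -- vasopressin --
    avp_half_life = 20,   # min, midpoint of the circulating 10-35 min range
    osm_threshold = 280,  # mOsm/kg osmotic secretion set point
    avp_sec_floor = 5,    # pg/min non-osmotic basal secretion
    baro_gain     = 2,    # secretion amplification per unit baro deficit
    store_max     = 2e6,  # pg neurohypophyseal store capacity
    store_ref     = 1e5,  # pg, store level below which secretion is limited
    synth_mult    = 5,    # synth_max as a multiple of baseline secretion
    K_avp_cd_n    = 2,    # Hill coefficient, collecting-duct permeability
    perm_min      = 0,
    perm_max      = 1,
    K_vasc        = 20,   # pg/mL EC50 of the vascular (pressor) effect
    vasc_max      = 0.3,  # max fractional resistance rise from AVP
    oro_on        = TRUE, # pre-absorptive (oropharyngeal) secretion brake
    oro_gain      = 3,    # per L drunk
    tau_oro       = 60,   # min

    ## -- ANP --
    tau_anp  = 12,        # min
    anp_gain = 0.1832726, # per mmHg P_ra; calibrated on the acute water load
                          # so peak plasma ANP rises 33% over baseline

    ## -- renin-angiotensin-aldosterone --
    tau_renin     = 15,   # min
    tau_angii     = 5,    # min
    tau_aldo      = 240,  # min (aldosterone responds over hours)
    renin_map_gain = 0.02, # per mmHg below baseline renal perfusion
    renin_md_gain  = 0.5,  # per mmol/min macula densa Na below baseline
    angii_eff_gain = 0.7,  # efferent resistance gain on angiotensin II
    angii_vasc_gain = 0.5, # systemic resistance gain on angiotensin II

    ## -- GI & thirst --
    gut_half_time = 12,   # min, lumped gastric emptying + absorption
    insensible    = 0.625, # mL/min skin + respiratory water loss
    na_intake_basal = 0.1, # mmol/min maintenance sodium intake
    thirst_thr    = 291,  # mOsm/kg osmotic thirst threshold
    thirst_osm_gain = 1,  # drive units per mOsm/kg
    thirst_vol_gain = 2,  # drive units per L extracellular deficit
    K_drive       = 3,    # half-saturation of the drinking-rate curve
    drink_rate_max = 200, # mL/min burst drinking rate
    gut_satiation = 0.5,  # L gut fill halving the drinking rate
    thirst_quench = 2     # pre-absorptive thirst quench per unit oro state
  )
}

#' Model parameters with derived calibration constants
#'
#' Builds the full parameter set for a subject. Primitive constants (gains,
#' set points, fractions; see the vignette for units and rationale) may be
#' overridden via `overrides` or `subject$param_overrides`; all derived
#' calibration constants (compartment volumes, glomerular resistances,
#' secretion gains, the collecting-duct Hill constant, basal intake) are then
#' recomputed so the calibrated baseline remains an exact fixed point.
#'
#' @param subject An [default_subject()] object.
#' @param overrides Named list of primitive parameter overrides.
#' @return An object of class `osmo_params` (a named list).
#' @examples
#' p <- default_params()
#' c(p$GFR0, p$urine0, p$osm_offset)
#' @export
default_params <- function(subject = default_subject(), overrides = list()) {
  p <- osmo_primitives()
  ov <- c(subject$param_overrides, overrides)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) {
      stop("unknown parameter override(s): ", paste(unknown, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  stopifnot(
    "sigma must be in [0, 1]" = p$sigma >= 0 && p$sigma <= 1,
    "avp_half_life must lie in the circulating 10-35 min range" =
      p$avp_half_life >= 10 && p$avp_half_life <= 35
  )
  if (identical(p$urine_dilution, "hummod")) {
    # legacy preset: urine cannot be diluted below the 324 mOsm/kg floor the
    # parent model printed after an acute water load
    p$U_min <- 324
  }

  ## ---- subject-derived compartment geometry ----
  p$subject <- subject
  p$nephron_mult <- subject$nephron_multiplier
  tbw <- subject$body_mass * subject$tbw_fraction
  p$V_ic0 <- tbw * subject$icf_fraction
  ecf <- tbw - p$V_ic0
  p$V_pl0 <- ecf * p$plasma_frac_of_ecf
  p$V_is0 <- ecf - p$V_pl0
  p$V_rbc <- p$rbc_to_plasma * p$V_pl0
  p$BV0 <- p$V_pl0 + p$V_rbc
  p$osm_offset <- p$serum_osm0 - 2 * p$serum_na0  # fixed non-Na osmoles
  p$Na_ec0 <- p$serum_na0 * (p$V_pl0 + p$V_is0)
  p$Osm_ic <- p$serum_osm0 * p$V_ic0   # fixed intracellular osmole content
  p$Prot_pl0 <- p$prot_conc0 * 10 * p$V_pl0  # g (g/dL -> g/L -> g)

  ## ---- oncotic curve: Landis-Pappenheimer shape scaled to the anchor ----
  raw7 <- 2.1 * 7 + 0.16 * 49 + 0.009 * 343
  p$onc_scale <- p$onc_anchor / raw7

  ## ---- capillary/lymph balance at baseline ----
  pi_c0 <- p$onc_anchor
  p$starling0 <- p$K_f * ((p$P_c0 - p$P_i0) - p$sigma * (pi_c0 - p$pi_i))
  p$lymph0 <- p$starling0 - p$insensible  # interstitial water balance
  if (p$lymph0 <= 0) stop("baseline lymph flow must be positive; check K_f/sigma")
  p$lymph_sens <- p$lymph0 / (p$P_i0 - p$lymph_thr)

  ## ---- glomerular network anchored at GFR0 ----
  p$R_aff0 <- (p$map0 - p$P_glom0) / p$RBF0
  p$R_eff0 <- (p$P_glom0 - p$P_rv) / (p$RBF0 - p$GFR0)
  p$Kf_glom <- p$GFR0 / (p$P_glom0 - p$P_bow - pi_c0)

  ## ---- tubule calibration ----
  frac_md <- 1 - p$f_PT - p$f_LH_na         # Na fraction reaching macula densa
  p$na_md0 <- frac_md * p$GFR0 * p$serum_na0 / 1000   # mmol/min
  p$tgf_half <- p$na_md0 +
    log((p$tgf_max - p$tgf_min) / (1 - p$tgf_min) - 1) / p$tgf_slope
  p$urine_na0 <- p$na_intake_basal           # sodium balance at baseline
  p$f_dist0 <- 1 - p$urine_na0 / p$na_md0    # distal fractional reabsorption
  e_osm0 <- 2 * p$urine_na0 + p$osm_obligate
  p$urine_osm0 <- 1000 * e_osm0 / p$urine0   # ~569 mOsm/kg
  cd0 <- (p$urine_osm0 - p$U_min) / (p$U_max - p$U_min)
  if (cd0 <= 0 || cd0 >= 1) stop("baseline urine osmolarity outside [U_min, U_max]")
  # Hill constant such that cd_perm(avp0) reproduces baseline urine flow
  p$K_avp_cd <- p$avp0 * ((1 - cd0) / cd0)^(1 / p$K_avp_cd_n)

  ## ---- vasopressin calibration ----
  p$k_avp <- log(2) / p$avp_half_life
  p$Vd0 <- 1000 * p$V_pl0                       # mL distribution volume
  p$S_avp0 <- p$k_avp * p$avp0 * p$Vd0          # pg/min baseline secretion
  p$osm_gain <- (p$S_avp0 - p$avp_sec_floor) /
    (p$serum_osm0 - p$osm_threshold)
  p$synth_max <- p$synth_mult * p$S_avp0
  p$store0 <- if (p$synth_max > p$S_avp0) {
    p$store_max * (1 - p$S_avp0 / p$synth_max)
  } else 0
  # systemic resistance normalisation so baseline MAP is exactly map0
  p$tpr_base <- 1 + p$vasc_max * p$avp0^2 / (p$avp0^2 + p$K_vasc^2)

  ## ---- water balance ----
  p$water_intake_basal <- p$insensible + p$urine0  # mL/min maintenance sipping
  p$k_abs <- log(2) / p$gut_half_time

  structure(p, class = c("osmo_params", "list"))
}

#' @export
print.osmo_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<osmo_params> subject %.0f kg | baseline: osm %g mOsm/kg, Na %g mmol/L,",
      " AVP %g pg/mL,\n  GFR %g mL/min, urine %g mL/min @ %.0f mOsm/kg,",
      " MAP %g mmHg (%d parameters)\n"
    ),
    x$subject$body_mass, x$serum_osm0, x$serum_na0, x$avp0,
    x$GFR0 * x$nephron_mult, x$urine0 * x$nephron_mult, x$urine_osm0,
    x$map0, length(unclass(x))
  ))
  invisible(x)
}
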