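#' Glomerular hemodynamics of the scaled single nephron
#'
#' The afferent arteriole / glomerulus / efferent arteriole complex is an
#' ohmic two-resistor network with no compliance between arterial and renal
#' venous pressure. Afferent resistance carries the tubuloglomerular-feedback
#' multiplier and an intrinsic myogenic response to arterial pressure (which
#' buffers filtration against MAP swings); efferent resistance carries the
#' angiotensin II multiplier. Filtration is `Kf_glom * (P_glom - P_bowman -
#' pi_glom)`, floored at zero, with glomerular oncotic pressure taken from
#' plasma protein concentration. Nephron count scales the resistances down
#' and the filtration coefficient up, so all flows are proportional to
#' `nephron_mult` at fixed signals.
#'
#' @param map_mmHg Mean arterial pressure (mmHg), positive.
#' @param tgf_mult Tubuloglomerular feedback multiplier on afferent
#'   resistance (dimensionless, positive).
#' @param angii_mult Angiotensin II multiplier on efferent resistance.
#' @param prot_conc Plasma protein concentration (g/dL).
#' @param params Model parameters.
#' @return A list of class `osmo_glom`: `R_aff`, `R_eff` (mmHg.min/mL),
#'   `P_glom` (mmHg), `GFR`, `RBF` (mL/min), `FF` (filtration fraction).
#' @examples
#' glomerular_hemodynamics(93, 1, 1, 7)$GFR  # 125 at baseline
#' @export
glomerular_hemodynamics <- function(map_mmHg, tgf_mult, angii_mult, prot_conc,
                                    params = default_params()) {
  stopifnot(map_mmHg > 0, tgf_mult > 0, angii_mult > 0)
  nm <- params$nephron_mult
  myo <- min(params$myo_max,
             max(params$myo_min, 1 + params$g_myo * (map_mmHg - params$map0)))
  R_a <- params$R_aff0 * tgf_mult * myo / nm
  R_e <- params$R_eff0 * angii_mult / nm
  Kf <- params$Kf_glom * nm
  pi_g <- oncotic_pressure(prot_conc, params)
  B <- params$P_bow + pi_g
  # P_glom solves: (MAP - P)/R_a - (P - P_rv)/R_e = Kf * max(0, P - B)
  denom <- 1 / R_a + 1 / R_e
  P_open <- (map_mmHg / R_a + params$P_rv / R_e + Kf * B) / (denom + Kf)
  if (P_open > B) {
    P_g <- P_open
    gfr <- Kf * (P_g - B)
  } else {
    P_g <- (map_mmHg / R_a + params$P_rv / R_e) / denom
    gfr <- 0
  }
  rbf <- (map_mmHg - P_g) / R_a
  structure(
    list(R_aff = R_a, R_eff = R_e, P_glom = P_g, GFR = gfr, RBF = rbf,
         FF = if (rbf > 0) gfr / rbf else 0),
    class = c("osmo_glom", "list")
  )
}

#' Tubuloglomerular feedback multiplier
#'
#' Macula densa sensing of per-nephron distal sodium delivery: a monotone
#' increasing sigmoid equal to 1 at the calibrated baseline delivery, bounded
#' in `[tgf_min, tgf_max]`. High distal sodium delivery constricts the
#' afferent arteriole (multiplier above 1), zero delivery dilates it to
#' `tgf_min`.
#'
#' @param na_md Sodium delivery at the macula densa (mmol/min,
#'   per-nephron-normalised), non-negative.
#' @param params Model parameters.
#' @return Dimensionless afferent resistance multiplier.
#' @export
tgf_multiplier <- function(na_md, params = default_params()) {
  stopifnot(all(na_md >= 0))
  params$tgf_min + (params$tgf_max - params$tgf_min) /
    (1 + exp(-params$tgf_slope * (na_md - params$tgf_half)))
}

# distal fractional sodium reabsorption under aldosterone/ANP modulation
distal_reabs_fraction <- function(aldo, anp, params) {
  min(0.998, max(0, params$f_dist0 + params$aldo_coef * (aldo - 1) -
                   params$anp_coef * (anp - 1)))
}

#' Segmental tubule transport
#'
#' Staged mass balance along the nephron. The proximal tubule reabsorbs a
#' fixed fraction of filtered water and sodium (glomerulotubular balance);
#' the loop of Henle reabsorbs a larger sodium than water fraction, producing
#' a dilute inflow at the macula densa and reporting distal sodium delivery;
#' the distal tubule's sodium reabsorption is scaled up by aldosterone and
#' down by ANP; the collecting duct reabsorbs water toward an
#' AVP-permeability-controlled target osmolarity bounded by the medullary
#' gradient, with urine osmolarity clamped to `[U_min, U_max]`. A constant
#' obligate non-sodium osmolar excretion (urea etc.), proportional to
#' filtration, keeps dehydrated urine flowing at maximal concentration.
#'
#' @param glom An `osmo_glom` list from [glomerular_hemodynamics()].
#' @param serum_na Serum sodium (mmol/L).
#' @param hormones Named list with `avp` (pg/mL), `anp`, `aldo` (relative).
#' @param params Model parameters.
#' @return A list of class `osmo_renal`: `urine_flow` (mL/min), `urine_na`
#'   (mmol/min), `urine_osm` (mOsm/kg), `na_md` (mmol/min), plus `GFR` and
#'   the per-stage reabsorption ledger used by the conservation assertions.
#' @export
tubule_transport <- function(glom, serum_na, hormones,
                             params = default_params()) {
  stopifnot(glom$GFR >= 0)
  gfr <- glom$GFR
  filt_w <- gfr                              # mL/min
  filt_na <- gfr * serum_na / 1000           # mmol/min

  pt_w <- params$f_PT * filt_w
  pt_na <- params$f_PT * filt_na
  lh_w <- params$f_LH_w * filt_w
  lh_na <- params$f_LH_na * filt_na
  w_cd <- filt_w - pt_w - lh_w               # water entering distal/CD
  na_md <- filt_na - pt_na - lh_na           # macula densa Na delivery

  f_dist <- distal_reabs_fraction(hormones$aldo, hormones$anp, params)
  dt_na <- f_dist * na_md
  urine_na <- na_md - dt_na

  gfr0 <- params$GFR0 * params$nephron_mult
  e_osm <- 2 * urine_na +
    params$osm_obligate * params$nephron_mult * (if (gfr0 > 0) gfr / gfr0 else 0)
  cd_perm <- avp_effects(hormones$avp, params)$cd_perm
  u_target <- params$U_min + cd_perm * (params$U_max - params$U_min)
  urine_flow <- if (e_osm > 0) min(1000 * e_osm / u_target, w_cd) else 0
  cd_w <- w_cd - urine_flow
  urine_osm <- if (urine_flow > 0) {
    min(params$U_max, max(params$U_min, 1000 * e_osm / urine_flow))
  } else params$U_max

  stages <- c(pt_w = pt_w, pt_na = pt_na, lh_w = lh_w, lh_na = lh_na,
              dt_na = dt_na, cd_w = cd_w)
  if (any(stages < -1e-9) || urine_flow < 0 || urine_na < -1e-12) {
    stop("tubule internal consistency: negative stage outflow/reabsorption (",
         paste(names(stages)[stages < -1e-9], collapse = ", "), ")")
  }

  structure(
    list(urine_flow = urine_flow, urine_na = urine_na, urine_osm = urine_osm,
         na_md = na_md, GFR = gfr, cd_perm = cd_perm, stages = stages),
    class = c("osmo_renal", "list")
  )
}

#' One renal evaluation with the TGF loop closed
#'
#' Composes [glomerular_hemodynamics()], [tgf_multiplier()] and
#' [tubule_transport()], closing the tubuloglomerular feedback loop by damped
#' fixed-point iteration on the afferent multiplier (tolerance `1e-6`, at
#' most 50 iterations). The macula densa senses per-nephron sodium delivery,
#' so whole-kidney outputs scale with the nephron multiplier.
#'
#' @param serum_na Serum sodium (mmol/L).
#' @param prot_conc Plasma protein concentration (g/dL).
#' @param map_mmHg Mean arterial pressure (mmHg).
#' @param hormones Named list with `avp`, `anp`, `aldo`, `angii`.
#' @param params Model parameters.
#' @param tgf_init Starting guess for the TGF multiplier (warm start).
#' @return An `osmo_renal` list (see [tubule_transport()]) with `tgf_mult`,
#'   `glom` and the iteration count appended.
#' @examples
#' p <- default_params()
#' renal_step(140, 7, 93, list(avp = 2.5, anp = 1, aldo = 1, angii = 1), p)
#' @export
renal_step <- function(serum_na, prot_conc, map_mmHg, hormones,
                       params = default_params(), tgf_init = 1) {
  nm <- params$nephron_mult
  angii_mult <- max(0.2, 1 + params$angii_eff_gain * (hormones$angii - 1))
  x <- tgf_init
  glom <- NULL
  converged <- FALSE
  for (it in seq_len(50)) {
    glom <- glomerular_hemodynamics(map_mmHg, x, angii_mult, prot_conc, params)
    na_md <- (1 - params$f_PT - params$f_LH_na) * glom$GFR * serum_na / 1000
    x_new <- tgf_multiplier(na_md / nm, params)
    if (abs(x_new - x) < 1e-6) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x + 0.5 * (x_new - x)
  }
  if (!converged) {
    stop(sprintf(
      "TGF fixed point did not converge in 50 iterations (MAP %.2f, [Na] %.2f, last multiplier %.6f)",
      map_mmHg, serum_na, x
    ))
  }
  glom <- glomerular_hemodynamics(map_mmHg, x, angii_mult, prot_conc, params)
  out <- tubule_transport(glom, serum_na, hormones, params)
  out$tgf_mult <- x
  out$iterations <- it
  out$glom <- glom
  out
}
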