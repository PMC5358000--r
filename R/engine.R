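# state vector layout (indices into y)
.osmo_state_names <- c(
  "V_ic", "V_is", "V_pl", "Na_ec", "Prot_pl", "Gut_w", "Gut_Na",
  "avp", "avp_store", "anp", "pra", "angii", "aldo", "oro",
  # boundary-flux ledger, integrated with the same scheme as the state
  "bladder_v", "urine_na_cum", "cwi", "insens", "ivi", "iv_na", "oral_na"
)
.osmo_dynamic_idx <- 1:14   # states entering the steady-state test

#' Analytic calibrated baseline state
#'
#' The parameter derivations in [default_params()] make this state an exact
#' fixed point of the model with the basal maintenance intake running;
#' [find_baseline()] verifies that by integration.
#'
#' @param params Model parameters.
#' @return Named numeric state vector.
#' @export
baseline_state <- function(params = default_params()) {
  y <- c(
    V_ic = params$V_ic0, V_is = params$V_is0, V_pl = params$V_pl0,
    Na_ec = params$Na_ec0, Prot_pl = params$Prot_pl0,
    Gut_w = params$water_intake_basal / 1000 / params$k_abs,
    Gut_Na = params$na_intake_basal / params$k_abs,
    avp = params$avp0, avp_store = params$store0,
    anp = 1, pra = 1, angii = 1, aldo = 1, oro = 0,
    bladder_v = 0, urine_na_cum = 0, cwi = 0, insens = 0, ivi = 0,
    iv_na = 0, oral_na = 0
  )
  stopifnot(identical(names(y), .osmo_state_names))
  y
}

# piecewise-constant boundary-condition rates; half-open event windows
# [t_start, t_start + duration)
make_forcing <- function(protocol, params) {
  ev <- protocol$events
  mk <- function(kind) {
    e <- ev[ev$kind == kind, ]
    list(t0 = e$t_start, t1 = e$t_start + e$duration,
         w = e$volume_ml / 1000 / e$duration,                 # L/min
         na = e$volume_ml / 1000 * e$na_mmol_per_l / e$duration) # mmol/min
  }
  oral <- mk("oral_load")
  iv <- mk("iv_infusion")
  opens <- ev$t_start[ev$kind == "ad_lib_open"]
  closes <- ev$t_start[ev$kind == "ad_lib_close"]
  basal_w <- if (protocol$controlled_intake) 0 else
    params$water_intake_basal / 1000
  basal_na <- if (protocol$controlled_intake) 0 else params$na_intake_basal
  function(t) {
    io <- oral$t0 <= t & t < oral$t1
    ii <- iv$t0 <= t & t < iv$t1
    list(
      oral_w_events = sum(oral$w[io]),
      oral_na = sum(oral$na[io]) + basal_na,
      basal_w = basal_w,
      iv_w = sum(iv$w[ii]),
      iv_na = sum(iv$na[ii]),
      adlib = any(opens <= t & t < closes)
    )
  }
}

# full model right-hand side; returns derivatives plus the instantaneous
# observables recorded in the output. `cache` carries the TGF warm start.
# Boundary rates are piecewise-constant on the aligned step grid, so every
# Runge-Kutta stage of a step evaluates the forcing at the step's left
# endpoint `t_rate` (exact for grid-aligned event windows, and it keeps an
# event's mass out of the step that merely ends where the event begins).
model_rhs <- function(t, y, p, forcing, cache, t_rate = t) {
  v_ic <- y[[1L]]; v_is <- y[[2L]]; v_pl <- y[[3L]]
  na_ec <- y[[4L]]; prot <- y[[5L]]; gut_w <- y[[6L]]; gut_na <- y[[7L]]
  avp <- y[[8L]]; store <- y[[9L]]; anp <- y[[10L]]
  pra <- y[[11L]]; angii <- y[[12L]]; aldo <- y[[13L]]; oro <- y[[14L]]

  for (i in 1:3) {
    if (y[[i]] <= 0) {
      stop(sprintf("integration error at t = %.4f min: %s = %.6g (must stay positive)",
                   t, .osmo_state_names[i], y[[i]]))
    }
  }

  obs <- derive_observables_num(v_ic, v_is, v_pl, p$V_rbc, na_ec,
                                p$Osm_ic, prot, p$osm_offset)
  press <- hemodynamics(obs$blood_volume, list(avp = avp, angii = angii),
                        p, v_is)
  baro <- baro_signals(press, p)
  renal <- renal_step(obs$serum_na, obs$prot_conc, press$map_mmHg,
                      list(avp = avp, anp = anp, aldo = aldo, angii = angii),
                      p, tgf_init = cache$tgf)
  cache$tgf <- renal$tgf_mult

  f <- forcing(t_rate)
  deficit <- max(0, (p$V_pl0 + p$V_is0) - (v_pl + v_is))
  drive <- thirst_drive(obs$serum_osm, deficit, p)
  drink <- drinking_rate(drive, f$adlib, gut_w, p, oro)  # mL/min
  oral_w_total <- f$oral_w_events + f$basal_w + drink / 1000  # L/min

  gab <- gut_absorption(gut_w, gut_na, p)
  pi_c <- oncotic_pressure(obs$prot_conc, p)
  jv <- starling_flux(press$P_c, press$P_i, pi_c, p$pi_i, p$K_f, p$sigma)
  ly <- lymph_flow(press$P_i, p)
  j_ic <- osmotic_flux(obs$icf_osm, obs$serum_osm, p$k_osm)

  S <- avp_secretion(obs$serum_osm, baro, store, p)
  S_eff <- if (p$oro_on) S * exp(-oro) else S
  d_oro <- if (p$oro_on) {
    p$oro_gain * (f$oral_w_events + drink / 1000) - oro / p$tau_oro
  } else 0
  raas <- raas_cascade(press$map_mmHg, renal$na_md / p$nephron_mult, baro,
                       list(pra = pra, angii = angii, aldo = aldo), p)
  uf_l <- renal$urine_flow / 1000

  dy <- c(
    j_ic,
    (jv - ly - p$insensible) / 1000 - j_ic,
    gab$flux_w + f$iv_w + (ly - jv) / 1000 - uf_l,
    gab$flux_na + f$iv_na - renal$urine_na,
    0,
    oral_w_total - gab$flux_w,
    f$oral_na - gab$flux_na,
    hormone_kinetics(avp, S_eff, 1000 * v_pl, p$avp_half_life),
    avp_synthesis(store, p) - S_eff,
    (anp_secretion(press$P_ra, p) - anp) / p$tau_anp,
    raas$d_pra, raas$d_angii, raas$d_aldo,
    d_oro,
    uf_l, renal$urine_na, oral_w_total, p$insensible / 1000,
    f$iv_w, f$iv_na, f$oral_na
  )
  list(
    dy = dy,
    aux = c(serum_osm = obs$serum_osm, serum_na = obs$serum_na,
            hct = obs$hct, prot_conc = obs$prot_conc,
            blood_volume = obs$blood_volume, icf_osm = obs$icf_osm,
            map_mmHg = press$map_mmHg, p_c = press$P_c, p_i = press$P_i,
            p_ra = press$P_ra,
            gfr = renal$GFR, urine_flow = renal$urine_flow,
            urine_na = renal$urine_na, urine_osm = renal$urine_osm,
            na_md = renal$na_md, tgf_mult = renal$tgf_mult,
            cd_perm = renal$cd_perm,
            avp_secretion = S_eff, thirst = drive, drink_rate = drink)
  )
}

# classical fixed-step 4th-order Runge-Kutta over [0, t_end] from y0,
# recording state + observables at the requested times (all must sit on the
# dt grid so runs at dt and dt/2 see identical event boundaries)
integrate_core <- function(y0, t_end, dt, params, forcing,
                           record_times, t_offset = 0) {
  stopifnot(dt > 0)
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-9) stop("dt must divide t_end")
  rec_idx <- round(record_times / dt)
  if (any(abs(rec_idx * dt - record_times) > 1e-9)) {
    stop("dt must divide every record/sample time")
  }
  rec <- logical(n_steps + 1)
  rec[rec_idx + 1] <- TRUE
  n_rec <- sum(rec)

  cache <- new.env(parent = emptyenv())
  cache$tgf <- 1
  y <- y0
  n_aux <- 20L
  out <- matrix(NA_real_, n_rec, 1 + length(y0) + n_aux)
  row <- 0L
  h2 <- dt / 2
  h6 <- dt / 6
  for (i in 0:n_steps) {
    t <- t_offset + i * dt
    k1 <- model_rhs(t, y, params, forcing, cache)
    if (rec[i + 1]) {
      row <- row + 1L
      out[row, ] <- c(t, y, k1$aux)
    }
    if (i == n_steps) break
    k2 <- model_rhs(t + h2, y + h2 * k1$dy, params, forcing, cache, t)
    k3 <- model_rhs(t + h2, y + h2 * k2$dy, params, forcing, cache, t)
    k4 <- model_rhs(t + dt, y + dt * k3$dy, params, forcing, cache, t)
    y <- y + h6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
  }
  colnames(out) <- c("time_min", .osmo_state_names,
                     names(model_rhs(t_offset, y0, params, forcing,
                                     cache)$aux))
  list(data = tibble::as_tibble(out), y = stats::setNames(y, names(y0)),
       derivs_end = model_rhs(t_offset + t_end, y, params, forcing,
                              cache)$dy)
}

# empty-schedule protocol with maintenance intake on, used for equilibration
basal_protocol <- function(subject, t_end) {
  new_protocol("baseline", subject,
               protocol_event("oral_load", 0, 0, 0, 1)[0, ],
               t_end, numeric(0), controlled_intake = FALSE,
               description = "basal maintenance intake, no interventions")
}

#' Find the model's steady-state baseline
#'
#' Starts from the analytically calibrated state ([baseline_state()]) and
#' integrates with basal intake equal to basal losses until the largest
#' relative state derivative falls below `tol` (checked every `chunk`
#' minutes, failing at `t_max`). The returned operating point satisfies
#' osmotic equilibrium, Starling-lymph balance and the calibrated baseline
#' urine flow, and is the initial condition for every protocol simulation.
#'
#' @param subject Virtual subject.
#' @param params Model parameters.
#' @param tol Relative steady-state tolerance on d(state)/dt (per min).
#' @param t_max Maximum equilibration time (min).
#' @param dt Integration step (min).
#' @param chunk Interval between convergence checks (min).
#' @return An object of class `osmo_baseline`: `state` (named vector),
#'   `observables`, `pressures`, `renal`, `converged`, `residual`,
#'   `t_elapsed`.
#' @examples
#' bl <- find_baseline()
#' bl$renal$urine_flow  # 0.58 mL/min by calibration
#' @export
find_baseline <- function(subject = default_subject(),
                          params = default_params(subject),
                          tol = 1e-6, t_max = 4320, dt = 0.25, chunk = 240) {
  proto <- basal_protocol(subject, t_max)
  forcing <- make_forcing(proto, params)
  cache <- new.env(parent = emptyenv())
  cache$tgf <- 1
  y <- baseline_state(params)
  t_elapsed <- 0

  residual <- function(y) {
    d <- model_rhs(t_elapsed, y, params, forcing, cache)$dy
    max(abs(d[.osmo_dynamic_idx]) / (abs(y[.osmo_dynamic_idx]) + 1))
  }
  res <- residual(y)
  while (res >= tol && t_elapsed < t_max) {
    run <- integrate_core(y, chunk, dt, params, forcing,
                          record_times = numeric(0), t_offset = t_elapsed)
    y <- run$y
    t_elapsed <- t_elapsed + chunk
    res <- residual(y)
  }
  if (res >= tol) {
    stop(sprintf(
      "baseline search did not converge by t_max = %g min (residual %.3g, tol %g)",
      t_max, res, tol
    ))
  }
  obs <- derive_observables_num(y[["V_ic"]], y[["V_is"]], y[["V_pl"]],
                                params$V_rbc, y[["Na_ec"]], params$Osm_ic,
                                y[["Prot_pl"]], params$osm_offset)
  press <- hemodynamics(obs$blood_volume,
                        list(avp = y[["avp"]], angii = y[["angii"]]),
                        params, y[["V_is"]])
  renal <- renal_step(obs$serum_na, obs$prot_conc, press$map_mmHg,
                      list(avp = y[["avp"]], anp = y[["anp"]],
                           aldo = y[["aldo"]], angii = y[["angii"]]),
                      params)
  structure(
    list(state = y, observables = tibble::as_tibble(obs), pressures = press,
         renal = renal, params = params, converged = TRUE, residual = res,
         t_elapsed = t_elapsed),
    class = c("osmo_baseline", "list")
  )
}

#' @export
print.osmo_baseline <- function(x, ...) {
  cat(sprintf(
    paste0("<osmo_baseline> converged (residual %.2g) after %g min\n",
           "  serum osm %.1f mOsm/kg, [Na] %.1f mmol/L, hct %.3f, ",
           "urine %.3f mL/min @ %.0f mOsm/kg\n"),
    x$residual, x$t_elapsed, x$observables$serum_osm, x$observables$serum_na,
    x$observables$hct, x$renal$urine_flow, x$renal$urine_osm
  ))
  invisible(x)
}

#' Simulate a protocol
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration of the coupled
#' fluid/kidney/endocrine/thirst model with the protocol's events applied at
#' their scheduled times as constant-rate boundary fluxes. Identical inputs
#' give bit-identical output. The run starts from the model baseline (found
#' once per call unless `init` is supplied) and records the state, the
#' derived observables and the boundary-flux ledger on a regular grid plus
#' the protocol's sample times.
#'
#' @param protocol An `osmo_protocol` from [build_protocol()] or
#'   [read_protocol_yaml()].
#' @param params Model parameters (defaults to the protocol subject's).
#' @param dt Integration step (min); must divide all event and sample times.
#' @param record_dt Output grid spacing (min).
#' @param init Optional initial state (named vector or `osmo_baseline`);
#'   default is `find_baseline(...)$state`.
#' @return An object of class `osmo_sim`; the trajectory tibble is in
#'   `$data` (see [data_dictionary()] for columns).
#' @examples
#' \donttest{
#' sim <- simulate_protocol(build_protocol("A"), dt = 0.1)
#' max(sim$data$urine_flow)
#' }
#' @export
simulate_protocol <- function(protocol, params = default_params(protocol$subject),
                              dt = 0.05, record_dt = 1, init = NULL) {
  stopifnot(inherits(protocol, "osmo_protocol"))
  if (is.null(init)) init <- find_baseline(protocol$subject, params)
  y0 <- if (inherits(init, "osmo_baseline")) init$state else init
  stopifnot(identical(names(y0), .osmo_state_names))
  record_times <- sort(unique(c(seq(0, protocol$t_end, by = record_dt),
                                protocol$sample_times, protocol$t_end)))
  forcing <- make_forcing(protocol, params)
  run <- integrate_core(y0, protocol$t_end, dt, params, forcing, record_times)
  structure(
    list(data = run$data, protocol = protocol, params = params, dt = dt,
         final_state = run$y),
    class = c("osmo_sim", "list")
  )
}
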