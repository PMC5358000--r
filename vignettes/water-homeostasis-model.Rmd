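---
title: "A reduced-order model of short-term water and sodium homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of short-term water and sodium homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmosim)
```

osmosim simulates the acute regulation of body water and sodium in an adult
human: the hormonal and renal response to drinking, water deprivation, salt
loads and hypertonic infusion over minutes to a day and a half. This
vignette is the package's account of the model itself — the equations, the
assumptions behind them, the parameters that matter and why they have the
values they do, and what the packaged tests do and do not establish.

## Compartments and observables

Body water is divided into three spaces: intracellular (`V_ic`),
interstitial (`V_is`) and plasma (`V_pl`). For the default 74 kg subject,
total body water is 60% of mass (44.4 L), two thirds intracellular; plasma
water is 3.0 L and red-cell volume a constant 2.1 L, giving a baseline
hematocrit of 0.412.

Two deliberate simplifications shape the state space:

* **One extracellular sodium pool.** Exchangeable sodium `Na_ec` is
  distributed over plasma + interstitial water, so serum sodium is
  `Na_ec / (V_pl + V_is)`. No transmembrane sodium flux is modelled.
* **Fixed intracellular osmoles.** The intracellular osmole content
  (potassium and its anions, lumped) is constant, so cell volume responds
  to extracellular tonicity only. Serum osmolality is `2[Na] + 8`
  mOsm/kg — the constant offset stands in for urea and glucose, which none
  of the packaged protocols perturb — calibrated so 140 mmol/L maps to
  288 mOsm/kg. mOsm/kg and mOsm/L are treated as interchangeable (plasma
  water is ≈1 kg/L).

Because red-cell volume is fixed, hematocrit moves only with plasma volume,
which is exactly how the dehydration studies used it: a proxy for how much
of an ingested or infused volume stays intravascular.

## Water exchange

Transmembrane water flow is proportional to the osmotic gradient,
`J_ic = k_osm (Osm_ic − Osm_ec)` with `k_osm = 0.01` L/min per mOsm/kg.
That conductance gives an osmotic equilibration time constant of ~3 min for
the whole cell mass, consistent with the near-immediate cell–ECF
equilibration seen after tonicity steps.

Capillary exchange follows Starling forces at a single capillary bed
(`J_v = K_f[(P_c − P_i) − σ(π_c − π_i)]`, `K_f = 2` mL/min/mmHg,
`σ = 0.95`); all packaged protocols are non-orthostatic, so no multi-level
gravitational calculation is needed. Plasma oncotic pressure uses the
classic cubic protein curve rescaled to 25 mmHg at 7 g/dL; plasma protein
mass is constant, so protein concentration (and `π_c`) moves inversely with
plasma volume. Lymph is a one-way, saturating valve: zero at or below an
interstitial pressure threshold (−5 mmHg), linear above it, capped at
30 mL/min. Interstitial pressure is affine in interstitial volume
(compliance 1 L/mmHg). At baseline, filtration (2 mL/min) exceeds lymph
return (1.375 mL/min) by exactly the insensible loss (0.625 mL/min ≈
0.9 L/day), which the model takes from the interstitium — resting, indoor
subjects; no sweating.

Hemodynamics are minimal by design. Cardiac output is eliminated: mean
arterial pressure is an affine, increasing function of blood volume
(15 mmHg/L around the 93 mmHg anchor) times a resistance multiplier
carrying the vasopressin and angiotensin II pressor effects, normalised to
1 at baseline hormone levels. Capillary and right-atrial pressures are
affine in MAP and blood volume (P_ra: 3 mmHg/L around 0 mmHg). The only
protocol that measured heart rate found no change, so nothing
finer-grained is warranted. Arterial and cardiac baroreceptor activities
are sigmoids of MAP and P_ra, equal to 1 at baseline and bounded in (0,2);
activity *falls* when pressure falls. One point deserves flagging: the
source literature for this model family describes AVP release with
"increased activity of the cardiac baroreceptors due to hypervolemia",
which inverts standard physiology. osmosim uses the standard sign —
hypovolemia/hypotension (combined baro signal below 1) amplifies AVP
secretion.

## The kidney

The kidney is one nephron scaled by `nephron_multiplier` (resistances
divided by it, filtration coefficient multiplied by it, so all flows scale
linearly at fixed signals). The afferent/glomerulus/efferent complex is an
ohmic network with no compliance: given MAP and renal venous pressure
(4 mmHg), glomerular pressure solves the two-resistor balance with
filtration `GFR = K_f,g (P_glom − P_bow − π_glom)+`. Anchors: GFR
125 mL/min, renal blood flow 600 mL/min, P_glom 53 mmHg, Bowman 18 mmHg at
baseline. Negative net filtration pressure simply stops filtration, it is
not an error.

Afferent resistance carries two controllers. An intrinsic myogenic response
multiplies it by `1 + (MAP − 93)/40`, clamped to [0.5, 2]; the gain
`1/(MAP0 − P_glom0)` makes autoregulation *exact* within the clamp (an
algebraic identity of the resistor network), so a ±20 mmHg MAP excursion
leaves GFR essentially unchanged and the renin signal, not filtration,
transmits perfusion pressure. Tubuloglomerular feedback multiplies it by a
sigmoid of per-nephron macula-densa sodium delivery (1 at the baseline
1.4 mmol/min, bounds [0.5, 2]); the feedback loop is closed algebraically
at every integrator stage by damped fixed-point iteration (tolerance 1e-6,
≤50 iterations, warm-started from the previous stage — typically 1–3
iterations).

Tubular transport is deliberately coarse — constant fractional
reabsorption where hormones do not act, hormone-scaled fractions where
they do:

* Proximal tubule: 67% of filtered water and sodium (glomerulotubular
  balance).
* Loop of Henle: 25% of filtered sodium but only 15% of filtered water —
  this asymmetry is what creates dilute distal fluid and the capacity for
  free-water excretion.
* Distal nephron sodium: fractional reabsorption `f_dist` (baseline
  0.9286, fixed by sodium balance: baseline excretion equals the
  0.1 mmol/min maintenance intake), scaled up by aldosterone (+0.05 per
  unit) and down by ANP (−0.80 per unit). The ANP coefficient is the
  model's natriuretic lever; it is calibrated (see below).
* Collecting duct: water is reabsorbed toward a target urine osmolality
  `U = U_min + cd_perm·(U_max − U_min)` with `U_min = 50`,
  `U_max = 1200` mOsm/kg (a static medullary gradient — no washout
  dynamics, defensible for ≤36 h runs). `cd_perm` is a Hill function of
  plasma AVP (coefficient 2) whose constant is derived so that baseline
  AVP (2.5 pg/mL) reproduces the baseline urine flow of **0.58 mL/min**
  exactly. Urine flow is osmolar excretion divided by the target
  osmolality, capped by distal water delivery.

Osmolar excretion is twice sodium excretion plus an obligate non-sodium
component of 0.13 mOsm/min (urea etc., scaled with GFR). This constant is
what keeps a dehydrated subject making ~0.11 mL/min of maximally
concentrated urine instead of shutting off; together with the baseline
sodium excretion it fixes baseline urine osmolality at ~569 mOsm/kg.
Water and sodium are conserved across every tubule stage and asserted at
every evaluation.

A configuration switch `urine_dilution = "hummod"` raises the dilution
floor to 324 mOsm/kg, mimicking the known under-dilution of the parent
integrative model after a water load; the default ("physiologic") dilutes
to 50 mOsm/kg.

## Endocrine control

**Vasopressin.** Synthesis fills a neurohypophyseal store (capacity 2×10⁶
pg, synthesis slowing as the store fills); secretion empties it at

`S = (store factor) × (5 + 32.5·(Osm − 280)+) × baro_mult  pg/min`,

i.e. a small non-osmotic floor plus a linear supra-threshold osmotic drive,
multiplied by the baroreceptor term `1 + 2(1 − combined signal)`. The
osmotic gain is derived from the steady-state condition that 288 mOsm/kg
maintains 2.5 pg/mL given first-order clearance with a 20-min half-life
(the midpoint of the 10–35 min circulating range) in a plasma distribution
volume. Store dynamics matter only at the margins: 36 h of dehydration
drains less than half the store, so secretion never fails.

Effects: collecting-duct permeability is the Hill curve above; the pressor
effect is a second Hill curve with EC50 at a supraphysiologic 20 pg/mL, so
the resistance multiplier is <1.005 at baseline — vasopressin only becomes
a pressor at high concentrations, as in vivo.

**The pre-absorptive (oropharyngeal) brake.** The model includes, on by
default, a transient suppression of AVP secretion triggered by the act of
drinking: a state `oro` integrates drunk volume (gain 3 per L, decay time
constant 60 min) and secretion is multiplied by `exp(−oro)`. The reason is
visible in the rehydration data this class of model is validated against:
after 24–36 h of water deprivation, plasma AVP collapses within 5–15
minutes of drinking, long before significant absorption, and stays low
through the 60-min sample while osmolality is still several mOsm/kg above
baseline. With the osmotic set point pinned at 280 mOsm/kg and a linear
gain, dilution plus baroreceptor unloading arithmetically cannot halve AVP
within the hour — a ~1 L drink against a ~2 L deficit only brings the
osmotic drive to ~60% of its peak. Pre-absorptive suppression of
vasopressin by drinking is a well-documented human reflex, and the 60-min
persistence is read off the same experiments. The same integrator quenches
thirst multiplicatively (`exp(−2·oro)`) in the drinking-rate law, giving
the characteristic gulp-then-stop pattern of ad-libitum rehydration;
gastric-distension satiation alone produces an unrealistic steady sipping
plateau balanced against absorption.

**ANP** relaxes (τ = 12 min) toward `1 + 0.1832726·P_ra`. The gain is
calibrated — by secant iteration on the acute water-load protocol at the
default step — so that peak plasma ANP rises exactly 33% over baseline
during that protocol, the model family's published excursion. ANP's only
effect is distal natriuresis; the ANP coefficient 0.80 was chosen
beforehand so that, with ANP and suppressed AVP acting together, the water
load produces at least the published 20-fold diuresis despite the
macula-densa sodium ceiling (see Limitations).

**Renin–angiotensin–aldosterone.** Renin secretion falls with perfusion
pressure (0.02/mmHg) and macula-densa sodium delivery (0.5 per mmol/min);
plasma renin activity, angiotensin II and aldosterone are a cascade of
first-order lags (15, 5 and 240 min). Angiotensin II constricts the
efferent arteriole (gain 0.7) and contributes to systemic resistance;
aldosterone scales distal sodium reabsorption. The gains are small by
design: none of the source protocols saw significant renin changes, and
the model keeps |PRA − 1| < 0.3 — a one-standard-deviation band judged
from typical between-subject PRA variability (~30% CV) — in every packaged
protocol.

## Intake, protocols, integration

Oral loads enter a lumped gut compartment absorbed first-order with a
12-min half-time (gastric emptying and intestinal uptake folded together —
the only aggregate the validation record constrains); infusions enter
plasma directly. Cumulative water intake counts oral water only. Thirst is
zero below 291 mOsm/kg and linear above, plus 2 per litre of extracellular
deficit; drinking during an open ad-libitum window is
`200·drive/(drive+3)·satiation(gut)·quench(oro)` mL/min.

A basal maintenance intake (water 1.205 mL/min = insensible + baseline
urine; sodium 0.1 mmol/min) closes the baseline mass balance. It runs
during baseline finding and during the one protocol performed "from the
basal state" (the water load); the controlled-intake studies (deprivation
and infusion protocols) suspend it for the whole run — deprivation is
modelled purely as absence of intake, and food water is zero during all
protocol windows, matching the fasting designs.

The six packaged protocols (A–F plus the sham-drink variant B1) encode the
published designs exactly: doses per kilogram of the 74 kg subject,
constant-rate delivery, the 80 mmol NaCl pill in the twelfth hour of the
24-h deprivations, 5% NaCl mapped to 855 mmol/L (50 g/L ÷ 58.44 g/mol),
and the infusion rate written as 0.06 mL/kg/min for 120 min (the
alternative printed form "0.7 mL/kg" lacks a time dimension and cannot be
reconciled; the rate form is used). "Overnight fast" is 10 h without
intake.

Integration is classical fixed-step RK4, default `dt = 0.05` min, chosen
for bit-reproducibility and trivially exact event alignment (all event
times and durations sit on the step grid; every stage of a step reads the
piecewise-constant boundary rates at the step's left endpoint, which is
exact for grid-aligned windows). The boundary fluxes are integrated as
additional state with the same scheme, so the conservation audit —
Δ(total body water) against intake − output, likewise sodium — closes to
machine precision rather than to discretisation error. The baseline finder
starts from the analytically calibrated state; because every derived
parameter is computed from the anchors, that state is an exact fixed point
and the search verifies rather than hunts.

Problem sizes used by the packaged tests: the acute protocol runs at the
default 0.05-min step (and 0.025 for the step-refinement check, which
bounds the discretisation error of every sampled output below 0.1%); the
24–36 h protocols run at 0.25 min, far inside the stability region of the
model's ≥5-min time constants.

## Numerical and design choices

* **Baseline values** for osmolality (288), sodium (140), AVP
  (2.5 pg/mL), MAP (93 mmHg) and hematocrit (0.412) are calibration
  choices anchored to conventional clinical values; the validation
  studies report baselines only graphically, and their AVP baselines
  differ severalfold from each other.
* **Derived-parameter policy**: anything that must make the baseline a
  fixed point (osmotic gain, Hill constant, distal fraction, glomerular
  resistances, lymph sensitivity, basal intake) is computed from the
  anchors at parameter-construction time, never stored as a second
  potentially inconsistent constant. Overriding a primitive recomputes
  the derived set.
* **Calibrated-then-frozen gains**: the ANP stretch gain (0.1832726/mmHg)
  is the one parameter fitted to a published protocol outcome (+33% peak),
  by secant iteration, then frozen.
* **Ties and degenerate inputs**: zero filtration yields zero urine (not
  an error); an empty hormone store yields zero secretion; z-scores landing
  exactly on a bin boundary belong to the middle bin (with a 1e-9 guard so
  floating-point rounding cannot flip a constructed boundary case).
* **Determinism**: no randomness anywhere in the model; repeated runs are
  byte-identical.

## The validation harness

Experimental reference tables (`protocol, variable, units, time_min, mean,
sd, sem, n`) are compared point-by-point: SEM is converted to SD
(`sd = sem·√n`), the z-score is `|model − mean|/sd` with the model value
linearly interpolated in time, points are binned as Z<1, 1≤Z≤2, Z>2, and
RMSE is reported per protocol/variable. The package ships **no digitized
experimental time series** — those exist only as figures in the source
studies, and packaging numbers read off plots would manufacture ground
truth. Instead it ships the schema, a synthetic fixture generator
(`make_reference_fixture`) that displaces the model by a chosen number of
SDs so every tally is known analytically, and the handful of printed
scalars as calibration anchors. Consequently the published headline tally
of that model family (most points within one experimental SD) is *not* a
reproducible target here, and the packaged tests make no such claim.

## What the tests show — and what they do not

The synthetic protocols exercise the model under the published study
conditions: dose sizes, timings and the 74 kg subject are the experimental
ones. Passing tests establish internal correctness (conservation,
convergence, determinism, calibration anchors) and qualitative fidelity
(deprivation concentrates and raises AVP monotonically; drinking suppresses
AVP by more than half within the hour; hypertonic drinks suppress less than
water; drinking after hypertonic infusion lowers final sodium; renin stays
quiet). They do not establish quantitative agreement with the experimental
time courses, which would require the figure data.

## Known limitations

* The distal sodium ceiling (macula-densa delivery ~1.4 mmol/min) means
  peak natriuresis cannot exceed ~1.4 mmol/min; the parent model's
  combination of a 20-fold diuresis with only a 25% fall in urinary sodium
  concentration implies ~1.5 mmol/min and is unreachable — this model's
  urinary sodium concentration falls much further (~80%) during water
  diuresis.
* No potassium, acid–base, urea or glucose dynamics; no erythropoiesis or
  red-cell osmotic volume change; no sweating or exercise; single
  gravitational level; pulseless circulation.
* Parameters are calibrated for the 74 kg reference subject. Other body
  masses scale the compartments and doses, but the absolute exchange and
  hemodynamic coefficients are not re-derived allometrically.
* The medullary gradient is static; urine-concentration dynamics over days
  (washout and rebuild) are out of scope.
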