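Package: osmosim
Title: Whole-Body Water and Sodium Homeostasis Simulator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation simulator of
    short-term human water and sodium homeostasis. Body fluid is split into
    intracellular, interstitial and plasma compartments coupled by osmosis,
    Starling capillary filtration and valve-gated lymph flow; the kidney is a
    single nephron scaled by nephron count, with ohmic glomerular
    hemodynamics, tubuloglomerular feedback and hormone-scaled segmental
    transport; circulating vasopressin, atrial natriuretic peptide and the
    renin-angiotensin-aldosterone cascade close the endocrine loops, and a
    thirst model drives ad-libitum drinking through a first-order gut. Six
    classic dehydration/rehydration protocols (acute water load, 24-36 h
    water deprivation with water or saline recovery, hypertonic saline
    infusion with and without drinking) ship as event schedules, together
    with a steady-state baseline finder, mass-conservation audits, and a
    z-score/RMSE harness for validating simulated trajectories against
    experimental reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
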