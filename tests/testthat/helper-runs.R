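# shared simulation fixtures, computed once per test run and memoised.
# Long deprivation protocols run at dt = 0.25 min (time constants are >= 5
# min, so this is far inside the stability/accuracy region; the step
# refinement test quantifies the discretisation error); the acute protocol A
# runs at the default dt = 0.05 min.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

base_params <- function() cached("params", default_params())

baseline_run <- function() cached("baseline", find_baseline(params = base_params()))

protocol_run <- function(id, dt = 0.25) {
  cached(paste0("sim_", id, "_", dt), {
    simulate_protocol(build_protocol(id), params = base_params(), dt = dt,
                      init = baseline_run())
  })
}

deprivation_end <- function(id) {
  switch(id, B = 2160, B1 = 2160, C = 1440, D = 1440, stop("no window"))
}
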