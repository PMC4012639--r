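# Shared, lazily computed fixtures. Heavy objects (smoke sweeps) are
# computed once per test session and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 2-step-per-parameter corner grid sweep (512 models): the smoke surface
smoke_sweep <- function() {
  cached("smoke_sweep", run_sweep(q10_grid(2)))
}

reference_cold_fi <- function() {
  cached("cold_fi", compute_fi_curve(cs_neuron_params(), q10_set(), 18))
}
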