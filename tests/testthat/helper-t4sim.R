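# Shared fixtures: a reduced geometry that keeps the physics of the
# paper-scale runs (same 0.9 deg pixel pitch, same 4.5 deg receptor
# spacing, same dt) but a 45 x 45 deg patch and a few seconds of time.
small_dims <- function(nt = 300L) c(50L, 50L, nt)
small_n_rec <- 10L

small_grating <- function(tf = 1, direction = 0, nt = 300L, ...) {
  make_grating(tf, direction = direction, dims = small_dims(nt), ...)
}

# random circuit parameter draws for property tests
random_circuit_params <- function() {
  circuit_params(E_exc = stats::runif(1, 10, 100),
                 E_inh = -stats::runif(1, 1, 60))
}
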