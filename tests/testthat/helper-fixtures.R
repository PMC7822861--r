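# Shared fixtures built in code at test time.

# generating parameter set used throughout (the published reference values)
ref_rates <- function() atto488_rates()
ref_truth <- c(k_on_T = 10, k_on_S = 12, k_off_T = 2.8e-3, k_off_S = 1e-3)

# the reference noiseless association + chase bundle (four analogue
# concentrations at 2 uM actin plus one 100-uM ATP chase)
ref_bundle <- function(noise_sd = 0, seed = NULL) {
  c(synth_association_bundle(noise_sd = noise_sd, seed = seed),
    list(chase = synth_chase(noise_sd = noise_sd,
                             seed = if (is.null(seed)) NULL else seed + 100L)))
}

# random valid draws for property tests
random_rates <- function() {
  rate_constants(k_on_T = runif(1, 1, 20), k_on_S = runif(1, 1, 20),
                 k_off_T = 10^runif(1, -4, -2), k_off_S = 10^runif(1, -4, -2))
}

rel_err <- function(x, truth) abs(x / truth - 1)
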