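# Shared parameter sets and small utilities for the suite.

# multistep secondary nucleation, saturated (K2 << m0): the generator default
p_multistep <- function(m0 = 20) default_kinetics(m0)

p_single <- function(m0 = 20, n2 = 2) {
  # kappa = 2 h^-1 at m0 = 20 uM
  k2 <- 2^2 / (2 * 1 * m0^(n2 + 1))
  kinetic_params(m0 = m0, nc = 2, kn = 2e-6, kplus = 1,
                 mechanism = "secondary_single", k2 = k2, n2 = n2)
}

p_frag <- function(m0 = 20) {
  kinetic_params(m0 = m0, nc = 2, kn = 2e-6, kplus = 1,
                 mechanism = "fragmentation", kf = 2^2 / (2 * 1 * m0))
}

p_oosawa <- function(m0 = 20, nc = 2, lambda = 0.5) {
  kinetic_params(m0 = m0, nc = nc, kn = lambda^2 / (2 * 1 * m0^nc),
                 kplus = 1, mechanism = "oosawa")
}

# fractional deviation helper
rel_err <- function(x, truth) abs(x / truth - 1)
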