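# Shared fixture builders: everything is generated in code at test time.

std_params <- function(...) pulse_params(delta = 1e-3, t_d = 0.05, ...)

# Simulate a decay for a known component set on an attenuation-targeted grid.
make_decay <- function(fraction, D, n = 16, attenuation = 12, sigma = 0,
                       seed = NULL, A0 = 100, params = std_params()) {
  comp <- exp_components(fraction, D)
  g <- gradient_grid(params, comp, n, attenuation)
  A <- echo_amplitude(A0, comp, b_factor(params, g))
  if (sigma > 0) {
    A <- A + withr::with_seed(seed, rnorm(length(g))) * sigma * A0
  }
  decay_curve(g, A, params)
}

# The two decomposition parameter sets used as reference bi-exponential
# truths throughout the suite (majority component first).
biexp_set_high <- list(fraction = c(0.88, 0.12), D = c(2.9e-11, 7.6e-11))
biexp_set_low  <- list(fraction = c(0.55, 0.45), D = c(7.8e-11, 0.23e-11))

# Piecewise-linear surfactant diffusion-concentration curve with a known
# breakpoint (monomer plateau, then linear decline in log10 C).
make_cmc_curve <- function(break_gL = 0.4, n = 12, D0 = 8e-10,
                           slope = -3e-10, lo = -1.5, hi = 2) {
  C <- 10^seq(lo, hi, length.out = n)
  D <- ifelse(C <= break_gL, D0, D0 + slope * (log10(C) - log10(break_gL)))
  list(C = C, D = D)
}
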