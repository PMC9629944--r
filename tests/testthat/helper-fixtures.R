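# Shared fixtures, all generated in code.

# A small noiseless GAB dataset (one mode, three temperatures).
noiseless_sim <- function(aw = c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85)) {
  simulate_sorption(sigma = 0, seed = 1, aw = aw)
}

# GAB parameters scaled across temperature so that ln(a_w) at constant
# moisture is exactly linear in 1/T with slope -q/R (net isosteric heat q).
clausius_params <- function(q = 10e3, b0 = 0.8, t0 = 313.15,
                            temperatures = c(30, 40, 50)) {
  tk <- temperatures + 273.15
  b <- b0 * exp(q / 8.314 * (1 / tk - 1 / t0))
  stats::setNames(lapply(seq_along(tk), function(i) c(A = 10, B = b[i], C = 8)),
                  as.character(temperatures))
}

random_gab_params <- function() {
  c(A = runif(1, 2, 30), B = runif(1, 0.2, 0.95), C = runif(1, 0.5, 50))
}
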