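# Independent oracles used across the suite.

# 3D-Gaussian diffusion factor, written independently of the package internals
oracle_diffusion <- function(tau, tau_D, beta) {
  1 / ((1 + tau / tau_D) * sqrt(1 + tau / (beta^2 * tau_D)))
}

# Gillespie simulation of a two-state telegraph process with constant rates;
# returns effective rate estimates and their standard errors
oracle_telegraph <- function(r_on, r_off, n_events, seed) {
  withr::with_seed(seed, {
    d_on <- stats::rexp(n_events, r_on)   # deprotonated dwells
    d_off <- stats::rexp(n_events, r_off) # protonated dwells
    list(k_on = 1 / mean(d_on), k_off = 1 / mean(d_off),
         se_k_on = (1 / mean(d_on)) / sqrt(n_events),
         se_k_off = (1 / mean(d_off)) / sqrt(n_events))
  })
}

# random valid FCS parameter sets for property-style tests
random_fcs_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        P <- stats::runif(1, 0, 0.6)
        T <- stats::runif(1, 0, 0.35)
        R <- stats::runif(1, 0, 0.2)
        if (P + T + R < 0.95) break
      }
      fcs_params(N = stats::runif(1, 0.5, 10),
                 tau_D = 10^stats::runif(1, -5, -3),
                 beta = stats::runif(1, 3, 8),
                 P = P, tau_prot = 10^stats::runif(1, -6, -4.5),
                 T = T, tau_T = 10^stats::runif(1, -6.2, -5.5),
                 R = R, tau_R = 10^stats::runif(1, -5, -4))
    })
  })
}
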