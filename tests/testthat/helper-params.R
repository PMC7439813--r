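# Shared fixtures: small parameter sets that keep network tests fast while
# preserving the exact-indegree structure (c * N integral).

mf_linear <- function(...) {
  meanfield_params(transfer = transfer_spec("linear", beta = 0.05), ...)
}

mf_none <- function(...) {
  meanfield_params(transfer = transfer_spec("none"), ...)
}

# 64 E + 16 I with c = 0.25: indegrees 16 (E) and 4 (I)
small_rate_params <- function(...) {
  rate_net_params(N_E = 64, N_I = 16, c = 0.25, ...)
}

# single E-afferent network (c * N_E = 1) isolates the per-synapse BCM rule
unit_indegree_params <- function(...) {
  rate_net_params(N_E = 4, N_I = 4, c = 0.25, ...)
}

# external count kept at 2000 so the mean external drive (c N_ext r w tau
# = 20 mV) matches the full-size operating point
small_spiking_params <- function(...) {
  spiking_params(N_E = 200, N_I = 50, N_ext = 2000, ...)
}

# independent Poisson spike train on [0, duration]
poisson_train <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}
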