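# Independent oracles and small fixtures shared across tests.

# closed-form logistic growth, the single-population limit of the hierarchy
logistic_n <- function(t, n0, r, K = 1) {
  K / (1 + (K / n0 - 1) * exp(-r * t))
}

# product-limit estimator written directly from its definition, independent
# of the survival-package-backed implementation
hand_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- as.logical(event[ord])
  tt <- sort(unique(time[event]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    died <- sum(time == tt[i] & event)
    s <- s * (1 - died / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# a mid-range virtual patient used where one concrete patient is enough
example_patient <- function() {
  patient_params(list(
    delta_s = 0.001, delta_is = 10, delta_ns = 5, delta_m = 0.5,
    delta_b = 0.5, u_b = 0.5, c_rel = 0.55, n = 10, ms = 50, mis = 3,
    psi = 0.1, phi = 0.05, alpha_s = 0.005, eta = 0.3, mu = 0.6,
    psmax = 0.55, psmin = 0.2
  ))
}

# assay-conditions hierarchy for a given doubling time
assay_hp <- function(doubling_time_hours, mis = 2) {
  hierarchy_params(ms = log(2) / (doubling_time_hours / 24), mis = mis,
                   n = 10, psmax = 1, psmin = 0)
}

# sampled (non-fixed) virtual-patient parameter names
sampled_parameters <- function() {
  rng <- parameter_ranges()
  rng$parameter[rng$sampled]
}
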