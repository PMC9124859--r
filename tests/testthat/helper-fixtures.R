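# Shared fixtures, built lazily and memoized so expensive objects (forward
# model, small simulated dataset) are computed once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_forward <- function() {
  fixture("forward_small", function()
    mi_forward_model(n_sources = 500, n_terms = 150))
}

small_dataset <- function() {
  fixture("dataset_small", function()
    generate_dataset(sim_config(trials_per_class = 2, seed = 42,
                                baseline_s = 8),
                     small_forward()))
}

# independently coded single-sphere analytic dipole potential (series form
# derived from the boundary condition sigma * dV/dr = 0 at the surface);
# the oracle for the three-shell model's homogeneous limit
single_sphere_potential <- function(e_pos, s_pos, ori, R, sigma, n_terms = 300) {
  b <- sqrt(sum(s_pos^2))
  sh <- s_pos / b; eh <- e_pos / sqrt(sum(e_pos^2))
  u <- sum(sh * eh)
  mr <- sum(ori * sh); me <- sum(ori * eh)
  tot <- 0
  Pm <- 1; P <- u; dPm <- 0; dP <- 1
  for (n in seq_len(n_terms)) {
    if (n > 1) {
      P1 <- ((2 * n - 1) * u * P - (n - 1) * Pm) / n
      dP1 <- dPm + (2 * n - 1) * P
      Pm <- P; P <- P1; dPm <- dP; dP <- dP1
    }
    tot <- tot + (2 * n + 1) / n * b^(n - 1) / R^(n + 1) *
      (n * mr * P + (me - u * mr) * dP)
  }
  tot / (4 * pi * sigma)
}

# mu-band (10-12 Hz) power of a single series via the periodogram (Welch-style
# band average), the oracle for ERD depth checks
oracle_band_power <- function(v, fs = 160, lo = 10, hi = 12) {
  s <- stats::spec.pgram(stats::ts(v, frequency = fs), plot = FALSE,
                         taper = 0, detrend = FALSE)
  mean(s$spec[s$freq >= lo & s$freq <= hi])
}
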