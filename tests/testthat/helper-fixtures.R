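# Small lattices and analytic oracles shared across the suite.

tiny_lattice <- function(rho_tn = 1, ru_span = 9, seed = 1) {
  lat <- generate_fixtures("tiny_lattice")
  lat <- assign_troponin(lat, rho_tn = rho_tn, seed = seed)
  influence_map(lat, ru_span = ru_span)
}

standard_lattice <- function(rho_tn = 1, ru_span = 9, seed = 1) {
  lat <- build_lattice()
  lat <- assign_troponin(lat, rho_tn = rho_tn, seed = seed)
  influence_map(lat, ru_span = ru_span)
}

# dense direct solve of an assembled system (independent of Matrix's sparse path)
dense_solve_oracle <- function(system) {
  K <- as.matrix(system$K)
  solve(K, system$V)
}

# empirical transition frequency within 3 binomial SE of p
expect_binomial <- function(hits, n, p, label = "frequency") {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se + 1e-12, label = label)
}
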