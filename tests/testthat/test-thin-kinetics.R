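test_that("rate table encodes the psi/xi scalings and equilibria", {
  rt <- thin_rate_table()
  expect_equal(rt$r_t12, 5e4)
  expect_equal(rt$coop_r_t12, rt$psi * rt$r_t12)
  expect_equal(rt$coop_r_t23, rt$psi * rt$r_t23)
  expect_equal(rt$K1_prime, rt$r_t12 / rt$r_t21)
  expect_equal(rt$K3_prime, rt$r_t31 / rt$r_t13)
  expect_equal(rt$effective_K1, 1e5)  # K1' * psi
  # xi rescales the Ca on-rates
  rt10 <- thin_rate_table(xi = 10)
  expect_equal(rt10$r_t12, 5e5)
  # the loop product of one-way equilibria is reported, not silently fixed
  expect_equal(rt$loop_product, (5e4 / 50) * (10 / 10) * (5 / 5e4))
})

test_that("effective rates substitute cooperative values per source/target", {
  rt <- thin_rate_table()
  cc <- coop_config(sources = c("TF3", "XB2", "XB3"), targets = c("rt12", "rt23"))
  # context false -> basic rates; pCa 4 gives 5 /s pseudo-first-order
  r <- effective_rates(1e-4, c(TF3 = FALSE), rt, cc)
  expect_equal(unname(r["r12"]), 5)
  expect_equal(unname(r["r13"]), 5)
  expect_equal(unname(r["r23"]), 10)
  # context true -> targeted rates psi-scaled, reverse rates untouched
  rc <- effective_rates(1e-4, c(TF3 = TRUE), rt, cc)
  expect_equal(unname(rc["r12"]), 500)
  expect_equal(unname(rc["r23"]), 1000)   # p = 1 at dt = 1 ms
  expect_equal(rc[c("r21", "r32", "r31")], r[c("r21", "r32", "r31")])
  # cooperative r12 at 2e-4 M reaches the forced-transition threshold
  expect_equal(unname(effective_rates(2e-4, c(TF3 = TRUE), rt, cc)["r12"]), 1000)
  # identical scaling however many sources are simultaneously true
  rc2 <- effective_rates(1e-4, c(TF3 = TRUE, XB2 = TRUE, XB3 = TRUE), rt, cc)
  expect_equal(rc2, rc)
  # non-targeted rate stays basic
  cc12 <- coop_config(sources = "TF3", targets = "rt12")
  r12only <- effective_rates(1e-4, c(TF3 = TRUE), rt, cc12)
  expect_equal(unname(r12only["r23"]), 10)
  # disabled cooperativity is basic everywhere
  expect_equal(effective_rates(1e-4, logical(0), rt, coop_config(enabled = FALSE)),
               r)
})

test_that("neighbour context discriminates sources and helices", {
  lat <- standard_lattice(ru_span = 9)
  tr <- lat$troponins
  n_tr <- nrow(tr)
  ru_states <- rep(1L, n_tr)
  n_myo <- lat$params$n_myosins
  xb_states <- rep(1L, n_myo)
  xb_partner <- rep(NA_integer_, n_myo)
  cc <- coop_config()
  ru <- tr$troponin[!is.na(tr$prev) & !is.na(tr$nxt)][10]
  # all TF1, no XBs -> all false
  ctx <- neighbor_context(lat, ru, ru_states, xb_states, xb_partner, cc)
  expect_false(any(ctx))
  # left neighbour in TF3 -> TF3 source true
  ru_states[tr$prev[ru]] <- 3L
  ctx <- neighbor_context(lat, ru, ru_states, xb_states, xb_partner, cc)
  expect_true(ctx[["TF3"]])
  expect_false(ctx[["XB2"]])
  # XB2 bound within the right neighbour's influence: XB2 true, XB3 false
  node <- tr$influence[[tr$nxt[ru]]][1]
  xb_states[1] <- 2L; xb_partner[1] <- node
  ctx <- neighbor_context(lat, ru, ru_states, xb_states, xb_partner, cc)
  expect_true(ctx[["XB2"]])
  expect_false(ctx[["XB3"]])  # source discrimination
  # a source not configured is not reported
  ctx3 <- neighbor_context(lat, ru, ru_states, xb_states, xb_partner,
                           coop_config(sources = "XB3"))
  expect_false(ctx3[["XB3"]])
  expect_named(ctx3, "XB3")
})

test_that("step_thin is a faithful multi-exit Monte Carlo update", {
  # all rates zero -> unchanged
  states <- c(1L, 2L, 3L)
  rates0 <- matrix(0, 3, 6)
  expect_equal(as.integer(step_thin(states, rates0, 1e-3)), states)
  # single-exit binomial frequency within 3 SE (TF2 -> TF3 at 10 /s)
  n <- 1e5
  rates <- matrix(rep(c(0, 0, 10, 0, 0, 0), each = n), n, 6)
  set.seed(1)
  new <- step_thin(rep(2L, n), rates, 1e-3)
  expect_binomial(sum(new == 3L), n, 0.01)
  # forced transition: summed exit probability >= 1 renormalises to ratio
  rates_hot <- matrix(rep(c(0, 50, 1000, 0, 0, 0), each = 4), 4, 6)
  set.seed(2)
  forced <- step_thin(rep(2L, 4), rates_hot, 1e-3)
  expect_true(all(forced != 2L))              # transition is forced
  expect_equal(attr(forced, "forced"), 4L)
})

test_that("isolated RU occupancies match the stationary eigen-oracle", {
  fx <- generate_fixtures("frozen_markov")
  pi_oracle <- fx$stationary
  expect_equal(sum(pi_oracle), 1)
  # simulate many independent RUs at frozen rates (no cooperativity, no XBs)
  n_ru <- 600
  rates <- matrix(rep(fx$rates, each = n_ru), n_ru, 6)
  states <- rep(1L, n_ru)
  set.seed(42)
  burn <- 600; keep <- 1200
  occ <- numeric(3)
  for (s in seq_len(burn + keep)) {
    states <- as.integer(step_thin(states, rates, 1e-3))
    if (s > burn) occ <- occ + tabulate(states, 3)
  }
  occ <- occ / sum(occ)
  # within 3 SE of the eigen-oracle (effective sample ~ n_ru * keep / tau)
  se <- sqrt(pi_oracle * (1 - pi_oracle) / (n_ru * keep / 100))
  expect_true(all(abs(occ - pi_oracle) < 3 * se + 0.01))
})

test_that("node availability applies the most-activated-governor rule", {
  lat <- standard_lattice(ru_span = 9)
  tr <- lat$troponins
  n_tr <- nrow(tr)
  # all TF3 at rho 1 -> everything available
  av <- node_availability(lat, rep(3L, n_tr))
  expect_true(all(av$available))
  # all TF1 -> nothing available
  expect_false(any(node_availability(lat, rep(1L, n_tr))$available))
  # governors (TF1, TF2) -> unavailable; (TF2, TF3) -> available
  states <- rep(1L, n_tr)
  node <- tr$influence[[5]][1]
  gov <- node_governors(lat)
  governors <- gov$governors[[match(node, gov$node)]]
  states[governors[1]] <- 2L
  expect_false(node_availability(lat, states)$available[
    match(node, gov$node)])
  states[governors[2]] <- 3L
  expect_true(node_availability(lat, states)$available[
    match(node, gov$node)])
  # knocked-out governors never grant availability
  lat0 <- assign_troponin(build_lattice(), 0)
  lat0 <- influence_map(lat0, 9)
  expect_false(any(node_availability(lat0, rep(3L, n_tr))$available))
})
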