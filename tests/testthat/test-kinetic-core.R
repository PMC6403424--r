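test_that("rate parameter validation names the offending field", {
  expect_error(rate_params(k_nuc = -1), "k_nuc")
  expect_error(rate_params(uv_factor = 0.5), "uv_factor")
  expect_error(rate_params(activation_efficiency = 1.2),
               "activation_efficiency")
  expect_error(update_params(default_params(), bogus = 1), "bogus")
  p <- default_params()
  expect_equal(p$k_open / p$k_close, 5.5e-3)
  expect_gte(p$k_el / p$k_nuc, 10)
})

test_that("null rates give a network with zero propensity everywhere", {
  net <- build_reaction_network(only_rates())
  for (st in random_states(10)) {
    a <- vapply(net, function(ch) ch$propensity(st), numeric(1))
    expect_true(all(a == 0))
  }
})

test_that("propensities are zero whenever a required reactant is absent", {
  net <- build_reaction_network(default_params())
  empty <- system_state(volume = count_volume(100, 30))
  a <- vapply(net, function(ch) ch$propensity(empty), numeric(1))
  expect_true(all(a == 0))
  # one open toroid cannot nucleate with itself
  one_open <- system_state(n_active_open = 1, volume = count_volume(100, 30))
  expect_equal(net$nucleate$propensity(one_open), 0)
})

test_that("bimolecular propensities follow pair counting", {
  p <- default_params()
  net <- build_reaction_network(p)
  st <- system_state(n_active_open = 2, volume = count_volume(1000, 30))
  f <- uM_per_unit(st)
  c_nuc <- 2 * p$k_nuc * f
  # two open toroids: exactly one reactant pair
  expect_equal(net$nucleate$propensity(st), c_nuc * (2 * 1) / 2)
  # brute-force pair enumeration for larger counts
  for (n in c(3, 7, 20)) {
    stn <- system_state(n_active_open = n, volume = st$volume)
    pairs <- sum(outer(seq_len(n), seq_len(n), "<"))
    expect_equal(net$nucleate$propensity(stn), c_nuc * pairs)
  }
  # joining counts distinct chain pairs
  st2 <- system_state(chains = c(2, 3, 4, 5), volume = st$volume)
  expect_equal(net$join$propensity(st2), p$k_join * f * 4 * 3 / 2)
  # elongation: chains x open
  st3 <- system_state(n_active_open = 5, chains = c(10, 20),
                      volume = st$volume)
  expect_equal(net$elongate$propensity(st3), p$k_el * f * 2 * 5)
})

test_that("scission propensity is per in-chain subunit and sites are uniform", {
  p <- only_rates(k_relax_chain = 0.3)
  net <- build_reaction_network(p)
  st <- system_state(chains = 5L, volume = count_volume(100, 30))
  # enumerating per-subunit events: 5 subunits, rate r each
  expect_equal(net$relax_scission$propensity(st), 5 * 0.3)
  # each of the five sites occurs with equal frequency
  set.seed(7)
  outcomes <- replicate(4000, {
    out <- apply_channel(st, net$relax_scission)
    paste(sort(out$chains), collapse = "-")
  })
  tab <- table(outcomes)
  # sites 1 and 5 give {4}, site 2 and 4 give {3}(+open), site 3 gives {2,2}
  freq <- tab / length(outcomes)
  expect_equal(unname(freq[["4"]]), 2 / 5, tolerance = 0.1)
  expect_equal(unname(freq[["3"]]), 2 / 5, tolerance = 0.1)
  expect_equal(unname(freq[["2-2"]]), 1 / 5, tolerance = 0.15)
})

test_that("channel stoichiometry conserves units and books species correctly", {
  p <- default_params()
  net <- build_reaction_network(p)
  vol <- count_volume(1000, 30)

  # scission of a 2-chain: one inactive + one free open active, no chains
  st <- system_state(chains = 2L, volume = vol)
  set.seed(1)
  out <- apply_channel(st, net$relax_scission)
  expect_equal(length(out$chains), 0L)
  expect_equal(out$n_inactive, 1)
  expect_equal(out$n_active_open, 1)
  expect_equal(total_units(out), 2)

  # join {3,4} -> {7}, free counts untouched
  st <- system_state(n_inactive = 10, chains = c(3L, 4L), volume = vol)
  set.seed(2)
  out <- apply_channel(st, net$join)
  expect_equal(sort(out$chains), 7L)
  expect_equal(out$n_inactive, 10)
  expect_equal(total_units(out), total_units(st))

  # elongate chain 10 with 5 open: chain 11, 4 open, units conserved
  st <- system_state(n_active_open = 5, chains = 10L, volume = vol)
  set.seed(3)
  out <- apply_channel(st, net$elongate)
  expect_equal(out$chains, 11L)
  expect_equal(out$n_active_open, 4)
  expect_equal(total_units(out), total_units(st))

  # applying a channel without reactants is a logic error
  empty <- system_state(volume = vol)
  expect_error(apply_channel(empty, net$open), "lacking its reactants")
})

test_that("every channel conserves units on randomized states", {
  net <- build_reaction_network(default_params())
  set.seed(99)
  for (st in random_states(40, seed = 99)) {
    for (ch in net) {
      if (ch$propensity(st) > 0) {
        out <- apply_channel(st, ch)
        expect_equal(total_units(out), total_units(st))
        expect_true(all(out$chains >= 2))
        expect_true(out$n_inactive >= 0 && out$n_active_closed >= 0 &&
                      out$n_active_open >= 0)
      }
    }
  }
})

test_that("heat pulse activates a deterministic floor fraction of the inactive pool", {
  vol <- count_volume(2000, 30)
  st <- system_state(n_inactive = 1000, volume = vol)
  p1 <- update_params(default_params(), activation_efficiency = 1)
  out <- apply_heat_pulse(st, p1)
  expect_equal(out$n_inactive, 0)
  expect_equal(out$n_active_closed, 1000)

  p0 <- update_params(default_params(), activation_efficiency = 0)
  expect_identical(apply_heat_pulse(st, p0), st)

  p75 <- update_params(default_params(), activation_efficiency = 0.75)
  out <- apply_heat_pulse(st, p75)
  expect_equal(out$n_active_closed, 750)
  expect_equal(out$n_inactive, 250)

  # floor rule on a non-divisible count
  st7 <- system_state(n_inactive = 7, volume = vol)
  out <- apply_heat_pulse(st7, p75)  # floor(5.25) = 5
  expect_equal(out$n_active_closed, 5)
  expect_equal(out$n_inactive, 2)

  # chains untouched
  stc <- system_state(n_inactive = 10, chains = c(4L, 6L), volume = vol)
  expect_equal(apply_heat_pulse(stc, p1)$chains, c(4L, 6L))
})

test_that("compiled and R propensity evaluations agree exactly", {
  p <- default_params()
  for (st in random_states(25, seed = 31)) {
    for (uv in c(1, p$uv_factor)) {
      ar <- channel_propensities(st, p, uv, engine = "R")
      ac <- channel_propensities(st, p, uv, engine = "compiled")
      expect_equal(unname(ac), unname(ar), tolerance = 1e-12)
    }
  }
})
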