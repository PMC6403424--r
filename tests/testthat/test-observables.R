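test_that("mean assembly length matches brute-force averaging", {
  st <- system_state(n_active_open = 2, chains = c(2L, 4L),
                     volume = count_volume(100, 30))
  expect_equal(mean_chain_length(st, "chains_only"), 3)
  expect_equal(mean_chain_length(st, "all_assemblies"), (2 + 6) / 4)
  # no chains
  st0 <- system_state(n_inactive = 10, volume = count_volume(100, 30))
  expect_equal(mean_chain_length(st0, "all_assemblies"), 1)
  expect_equal(mean_chain_length(st0, "chains_only"), 1)
  # randomized audit against explicit enumeration
  for (st in random_states(15, seed = 5)) {
    free <- st$n_inactive + st$n_active_closed + st$n_active_open
    objs <- c(rep(1, free), as.numeric(st$chains))
    if (length(objs)) {
      expect_equal(mean_chain_length(st, "all_assemblies"), mean(objs))
    }
  }
})

test_that("the CD proxy is affine, monotone and intensive", {
  expect_equal(cd_proxy(1, baseline = 2, amplitude = 5), 7)
  expect_equal(cd_proxy(0, baseline = 2, amplitude = 5), 2)
  expect_error(cd_proxy(0.5, amplitude = -1), "amplitude")
  # intensive: scaling every count leaves the signal unchanged
  st <- mixed_state()
  big <- system_state(st$n_inactive * 10, st$n_active_closed * 10,
                      st$n_active_open * 10, rep(st$chains, 10),
                      volume = st$volume * 10)
  expect_equal(cd_proxy(active_fraction(st)), cd_proxy(active_fraction(big)))
})

test_that("length mapping uses the toroid diameter for monomers and pitch for chains", {
  g <- toroid_geometry()
  expect_equal(length_to_nm(1, g), 12)
  expect_equal(length_to_nm(2, g), 2 * g$pitch)
  expect_equal(length_to_nm(c(1, 10), g), c(12, 10 * g$pitch))
  expect_error(length_to_nm(0), "n_units")
  # round trip for chains longer than the toroid diameter
  for (n in c(5, 40, 333)) {
    expect_equal(nm_to_length(length_to_nm(n, g), g), n)
  }
  expect_equal(nm_to_length(12, g), 1)
})

test_that("DLS proxy follows the sphere and rigid-rod rules", {
  g <- toroid_geometry()
  # all monomers: the toroid diameter
  expect_equal(dls_proxy(system_state(n_inactive = 100,
                                      volume = count_volume(100, 30))), 12)
  # a single rod of 34 turns (L = 102 nm): direct formula evaluation,
  # close to the canonical 100 nm rod giving D_h of about 41 nm
  st <- system_state(chains = 34L, volume = count_volume(100, 30))
  L <- 34 * g$pitch
  expect_equal(dls_proxy(st, include_monomers = FALSE),
               L / (log(L / 12) + 0.32), tolerance = 1e-6)
  expect_equal(100 / (log(100 / 12) + 0.32), 41, tolerance = 0.01)
  # degenerate weighting with one species present
  expect_equal(dls_proxy(st), L / (log(L / 12) + 0.32), tolerance = 1e-6)
  # monotone non-decreasing in chain length, strictly above the diameter
  dh <- vapply(2:400, function(n)
    dls_proxy(system_state(chains = as.integer(n),
                           volume = count_volume(1000, 30)),
              include_monomers = FALSE), numeric(1))
  expect_true(all(diff(dh) >= -1e-12))
  strict <- (2:400) * g$pitch > g$external_diameter * exp(0.68)
  expect_true(all(diff(dh)[strict[-1]] > 0))
  expect_equal(dls_proxy(system_state(volume = count_volume(10, 30))),
               NA_real_)
})

test_that("cryo-TEM sampling is unbiased with multiplicative log-normal noise", {
  st <- system_state(n_inactive = 50, chains = rep(20L, 50),
                     volume = count_volume(2000, 30))
  # zero noise, single species: constant sample
  st1 <- system_state(chains = rep(10L, 5), volume = count_volume(100, 30))
  set.seed(1)
  s1 <- sample_cryotem(st1, 20, noise_sd_log = 0)
  expect_true(all(s1 == 10 * 3))
  # sample mean within 3 sigma of the population mean (CLT)
  pop <- c(rep(12, 50), rep(60, 50))
  set.seed(2)
  draws <- sample_cryotem(st, 400, noise_sd_log = 0)
  se <- stats::sd(pop) / sqrt(400)
  expect_lt(abs(mean(draws) - mean(pop)), 3 * se)
  # log-normal noise is multiplicative and positive
  set.seed(3)
  noisy <- sample_cryotem(st1, 500, noise_sd_log = 0.1)
  expect_true(all(noisy > 0))
  expect_equal(stats::sd(log(noisy)), 0.1, tolerance = 0.2)
  # default draw count in the generator is 100 per time point
  expect_equal(formals(generate_dataset)$n_per_time, 100)
  # chains-only sampling falls back to toroids when no chains exist
  set.seed(4)
  s0 <- sample_cryotem(system_state(n_inactive = 5,
                                    volume = count_volume(10, 30)),
                       10, noise_sd_log = 0, include_monomers = FALSE)
  expect_true(all(s0 == 12))
})

test_that("the observable frame carries consistent per-snapshot columns", {
  sim <- ssa_simulate(initial_state(600, 30), default_params(),
                      single_fuel(), 3, 0:3, seed = 2)
  df <- sim_observables(sim)
  expect_equal(nrow(df), 4)
  expect_true(all(df$active_fraction >= 0 & df$active_fraction <= 1))
  expect_true(all(df$mean_length_units >= 1))
  expect_equal(df$n_inactive + df$n_active_closed + df$n_active_open +
                 df$chain_units, rep(600, 4))
  expect_equal(df$cd_signal, df$active_fraction)
})
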