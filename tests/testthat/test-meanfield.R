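test_that("null rates give the constant solution", {
  mf0 <- meanfield_init(30, 50)
  mf <- ode_simulate(mf0, only_rates(), protocol(), t_end = 5,
                     record_times = 0:5)
  expect_true(all(abs(mf$summary$inactive - 30) < 1e-10))
  expect_true(all(mf$summary$chain_units == 0))
  expect_error(ode_simulate(mf0, only_rates(), protocol(), t_end = 5,
                            rel_tol = -1), "tolerances")
})

test_that("relaxation-only decay matches the analytic exponential", {
  k <- log(20) / 20
  p <- only_rates(k_relax_free = k)
  mf <- ode_simulate(meanfield_init(30, 20), p, single_fuel(), 20,
                     record_times = 0:20)
  expect_equal(mf$summary$active_fraction, exp(-k * (0:20)),
               tolerance = 1e-5)
  # time to 5% of the post-pulse value: the 20-day recovery
  expect_equal(log(20) / k, 20)
})

test_that("irreversible elongation with excess open monomer grows linearly", {
  p <- only_rates(k_el = 10)
  mf0 <- meanfield_init(0, 300)
  mf0$active_open <- 100   # uM, effectively constant over the window
  mf0$c[1] <- 0.01         # seed dimers
  mf <- ode_simulate(mf0, p, protocol(), 0.1,
                     record_times = seq(0, 0.1, 0.01), rel_tol = 1e-8,
                     abs_tol = 1e-12)
  slopes <- diff(mf$summary$mean_length_chains) / 0.01
  expect_equal(slopes, rep(10 * 100, length(slopes)), tolerance = 0.02)
})

test_that("two-state subsystem converges to the exact stationary ratio", {
  p <- rate_params(k_open = 0.8, k_close = 0.8 / 5.5e-3, k_nuc = 0,
                   k_el = 0, k_join = 0, k_relax_free = 0,
                   k_relax_chain = 0, uv_factor = 1,
                   activation_efficiency = 1)
  mf <- ode_simulate(meanfield_init(30, 10), p, single_fuel(), 1,
                     record_times = c(0, 1))
  s <- mf$summary
  expect_equal(s$active_open[2] / s$active_closed[2], 5.5e-3,
               tolerance = 1e-6)
})

test_that("units are conserved to solver tolerance over the full horizon", {
  mf <- ode_simulate(meanfield_init(30, 3000), default_params(),
                     single_fuel(), 12, record_times = 0:12)
  drift <- max(abs(mf$summary$total_units + mf$summary$leak_units - 30)) / 30
  expect_lt(drift, 1e-6)
  expect_lt(max(mf$summary$leak_units) / 30, 1e-3)
  expect_true(all(diff(mf$summary$time) > 0))
})

test_that("truncation leakage beyond the bound fails loudly", {
  expect_error(ode_simulate(meanfield_init(30, 60), default_params(),
                            single_fuel(), 8, record_times = 0:8),
               "raise n_max")
})

test_that("reflecting truncation conserves units exactly and tracks the open system", {
  full <- ode_simulate(meanfield_init(30, 2500), default_params(),
                       single_fuel(), 8, 0:8, rel_tol = 1e-6,
                       abs_tol = 1e-9, leak_bound = 0.05)
  refl <- ode_simulate(meanfield_init(30, 1000), default_params(),
                       single_fuel(), 8, 0:8, rel_tol = 1e-6,
                       abs_tol = 1e-9, boundary = "reflect")
  expect_lt(max(abs(refl$summary$total_units - 30)) / 30, 1e-9)
  expect_equal(refl$summary$mean_length_units,
               full$summary$mean_length_units, tolerance = 0.005)
  expect_equal(refl$summary$active_fraction,
               full$summary$active_fraction, tolerance = 0.005)
})

test_that("the quasi-stationary open-pool approximation tracks the full dynamics", {
  full <- ode_simulate(meanfield_init(30, 400), default_params(),
                       single_fuel(), 8, 0:8, rel_tol = 1e-6,
                       abs_tol = 1e-9, boundary = "reflect")
  qss <- ode_simulate(meanfield_init(30, 400), default_params(),
                      single_fuel(), 8, 0:8, rel_tol = 1e-6,
                      abs_tol = 1e-9, boundary = "reflect",
                      qss_open = TRUE)
  expect_equal(qss$summary$mean_length_units,
               full$summary$mean_length_units, tolerance = 0.01)
  expect_equal(qss$summary$active_fraction, full$summary$active_fraction,
               tolerance = 0.005)
})

test_that("SSA ensemble and mean-field twin agree; mismatched rates are caught", {
  init <- initial_state(1e4, 30)
  cc <- crosscheck_with_ssa(init, default_params(), single_fuel(),
                            t_end = 4, record_times = 0:4, n_reps = 10,
                            seed_base = 77, n_max = 3000)
  expect_true(cc$pass)
  # negative control: a deliberately different chain relaxation rate
  # (3x) collapses the mean-field chains early and must be flagged
  bad <- update_params(default_params(), k_relax_chain = 0.21)
  cc_bad <- crosscheck_with_ssa(init, default_params(), single_fuel(),
                                t_end = 4, record_times = 0:4, n_reps = 10,
                                seed_base = 77, n_max = 3000,
                                params_ode = bad)
  expect_false(cc_bad$pass)
  # frozen system: exact agreement
  cc0 <- crosscheck_with_ssa(mixed_state(), only_rates(), protocol(),
                             t_end = 2, record_times = 0:2, n_reps = 3,
                             seed_base = 1, n_max = 100)
  expect_true(all(abs(cc0$table$z) < 1e-9))
})
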