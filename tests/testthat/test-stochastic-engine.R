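test_that("a frozen system never moves and validates its inputs", {
  st <- mixed_state()
  sim <- ssa_simulate(st, only_rates(), protocol(), t_end = 5,
                      record_times = c(0, 2.5, 5), seed = 1)
  expect_equal(sim$event_count, 0)
  final <- sim$states[[3]]
  expect_equal(final$n_inactive, st$n_inactive)
  expect_equal(sort(final$chains), sort(st$chains))

  expect_error(ssa_simulate(st, only_rates(), protocol(), t_end = -1,
                            seed = 1), "t_end")
  expect_error(ssa_simulate(st, only_rates(), protocol(), t_end = 1,
                            record_times = c(0, 2), seed = 1),
               "record_times")
})

test_that("identical inputs and seed reproduce bit-identical trajectories", {
  init <- initial_state(800, 30)
  for (eng in c("compiled", "R")) {
    a <- ssa_simulate(init, default_params(), single_fuel(), 3, 0:3,
                      seed = 11, engine = eng)
    b <- ssa_simulate(init, default_params(), single_fuel(), 3, 0:3,
                      seed = 11, engine = eng)
    expect_identical(lapply(a$states, unclass), lapply(b$states, unclass))
    expect_identical(a$event_count, b$event_count)
  }
})

test_that("total units are exactly conserved over a long event sequence", {
  init <- initial_state(1e4, 30)
  sim <- ssa_simulate(init, default_params(), single_fuel(), 6,
                      record_times = seq(0, 6, 0.25), seed = 5)
  expect_gt(sim$event_count, 1e4)  # well over ten thousand reactions
  expect_units_conserved(sim, 1e4)
  expect_true(all(vapply(sim$states, function(s) all(s$chains >= 2),
                         logical(1))))
})

test_that("pure-death relaxation matches the closed form within 3 sigma", {
  # 1000 active closed toroids, only free relaxation at rate k
  k <- 0.5
  p <- only_rates(k_relax_free = k)
  init <- system_state(n_active_closed = 1000,
                       volume = count_volume(1000, 30))
  ens <- run_ensemble(50, 301, init, p, protocol(), t_end = 2,
                      record_times = c(0.5, 1, 2))
  for (i in seq_along(ens$summary$time)) {
    t <- ens$summary$time[i]
    surv <- exp(-k * t)
    expected <- 1000 * surv
    se <- sqrt(1000 * surv * (1 - surv)) / sqrt(50)
    expect_lt(abs(ens$summary$n_active_closed[i] - expected), 3 * se)
    # ensemble variance ~ binomial N p (1-p)
    expect_equal(ens$sd$n_active_closed[i]^2, 1000 * surv * (1 - surv),
                 tolerance = 0.5)
  }
})

test_that("open/close equilibrium reaches the two-state stationary law", {
  p <- rate_params(k_open = 0.8, k_close = 0.8 / 5.5e-3, k_nuc = 0,
                   k_el = 0, k_join = 0, k_relax_free = 0,
                   k_relax_chain = 0, uv_factor = 1,
                   activation_efficiency = 1)
  n <- 2e4
  init <- system_state(n_active_closed = n, volume = count_volume(n, 30))
  # ~40 mean switching times, averaged over a stationary window
  sim <- ssa_simulate(init, p, protocol(), t_end = 0.4,
                      record_times = seq(0.1, 0.4, by = 0.01), seed = 17)
  fr_open <- vapply(sim$states, function(s)
    s$n_active_open / (s$n_active_open + s$n_active_closed), numeric(1))
  K <- 5.5e-3
  target <- K / (1 + K)
  se <- sqrt(target * (1 - target) / n) / sqrt(length(fr_open) / 10)
  expect_lt(abs(mean(fr_open) - target), 3 * se)
})

test_that("racemic toroids (k_open = 0) never polymerize", {
  p <- update_params(default_params(), k_open = 0)
  sim <- ssa_simulate(initial_state(3000, 30), p, single_fuel(), 15,
                      record_times = 0:15, seed = 23)
  expect_true(all(vapply(sim$states, function(s) length(s$chains),
                         integer(1)) == 0L))
})

test_that("ensemble summaries reduce correctly in degenerate cases", {
  init <- initial_state(500, 30)
  # a single replicate equals its own trajectory
  ens1 <- run_ensemble(1, 41, init, default_params(), single_fuel(), 2, 0:2)
  sim1 <- ssa_simulate(init, default_params(), single_fuel(), 2, 0:2,
                       seed = 41)
  expect_equal(ens1$summary$mean_length_units,
               sim_observables(sim1)$mean_length_units)
  # frozen system: zero variance at all times
  ensf <- run_ensemble(10, 1, mixed_state(), only_rates(), protocol(), 2,
                       0:2)
  expect_true(all(ensf$sd$mean_length_units == 0))
  expect_error(run_ensemble(0, 1, init, default_params(), single_fuel(),
                            1, 0:1), "n_reps")
})

test_that("compiled and R engines agree statistically", {
  init <- initial_state(400, 30)
  p <- default_params()
  mc <- run_ensemble(12, 7, init, p, single_fuel(), 2, 0:2,
                     engine = "compiled")
  mr <- run_ensemble(12, 107, init, p, single_fuel(), 2, 0:2, engine = "R")
  for (col in c("mean_length_units", "active_fraction")) {
    se <- sqrt(mc$sd[[col]]^2 + mr$sd[[col]]^2) / sqrt(12)
    dz <- abs(mc$summary[[col]] - mr$summary[[col]]) / pmax(se, 1e-9)
    expect_true(all(dz[-1] < 4))
  }
})

test_that("doubling concentration accelerates growth but not CD decay", {
  p <- default_params()
  lens <- matrix(NA_real_, 3, 2)
  for (s in 1:3) {
    a <- ssa_simulate(initial_state(6000, 30), p, single_fuel(), 2,
                      c(0, 2), seed = 600 + s)
    b <- ssa_simulate(initial_state(12000, 60), p, single_fuel(), 2,
                      c(0, 2), seed = 600 + s)
    lens[s, ] <- c(sim_observables(a)$mean_length_units[2],
                   sim_observables(b)$mean_length_units[2])
  }
  expect_true(all(lens[, 2] > lens[, 1]))
  # CD decay rate: relaxation-only subsystem is concentration independent
  pr <- update_params(p, k_nuc = 0, k_el = 0, k_join = 0)
  af <- sapply(c(3000, 12000), function(n) {
    sim <- ssa_simulate(initial_state(n, 30 * n / 3000), pr, single_fuel(),
                        4, c(0, 4), seed = 9)
    active_fraction(sim$states[[2]])
  })
  rates <- -log(af) / 4
  expect_equal(rates[1], rates[2], tolerance = 0.1)
  expect_equal(mean(rates), log(20) / 20, tolerance = 0.1)
})
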