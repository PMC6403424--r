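# Shared builders for small, fast test systems.

# parameters with every channel off except those supplied
only_rates <- function(...) {
  p <- list(k_open = 0, k_close = 0, k_nuc = 0, k_el = 0, k_join = 0,
            k_relax_free = 0, k_relax_chain = 0, uv_factor = 1,
            activation_efficiency = 1)
  repl <- list(...)
  p[names(repl)] <- repl
  do.call(rate_params, p)
}

# a mixed state exercising every species slot
mixed_state <- function(n_units = 1000, conc_uM = 30) {
  system_state(n_inactive = n_units - 320, n_active_closed = 200,
               n_active_open = 50, chains = c(2L, 3L, 5L, 10L, 50L),
               volume = count_volume(n_units, conc_uM))
}

# random valid states under a fixed seed, for property-style loops
random_states <- function(n, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nch <- sample(0:6, 1)
    system_state(n_inactive = sample(0:500, 1),
                 n_active_closed = sample(0:500, 1),
                 n_active_open = sample(0:100, 1),
                 chains = if (nch) sample(2:80, nch, replace = TRUE)
                          else integer(),
                 volume = count_volume(1000, 30))
  })
}

expect_units_conserved <- function(sim, n0) {
  tots <- vapply(sim$states, total_units, numeric(1))
  expect_true(all(tots == n0))
}
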