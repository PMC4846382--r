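# Shared fixture builders and a memo cache so expensive simulations are run
# once per test session and reused across test blocks.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# a deterministic 5-neuron network with explicit edges, for stepper checks
tiny_network <- function(w = 2) {
  pop <- tibble::tibble(neuron_id = 1:5,
                        e_l = c(-63, -62.5, -62, -61.5, -61),
                        g_nap = c(4.6, 4.8, 5, 5.2, 5.4))
  edges <- tibble::tibble(from = c(1L, 2L, 3L, 4L, 5L, 1L),
                          to   = c(2L, 3L, 4L, 5L, 1L, 3L),
                          weight = w)
  network_model(pop, edges)
}

# hand-built classified burst table: one LA followed by n_sa SA bursts per
# cycle, repeated
synthetic_burst_cycle <- function(n_sa, n_cycles = 6, period = 1000) {
  per_cycle <- n_sa + 1
  onsets <- seq(0, by = period, length.out = per_cycle * n_cycles)
  tibble::tibble(
    onset = onsets,
    offset = onsets + 200,
    peak = rep(c(80, rep(30, n_sa)), n_cycles),
    class = rep(c("LA", rep("SA", n_sa)), n_cycles)
  )
}

# uncoupled population simulations (shared by several acceptance blocks)
uncoupled_sims <- function(seeds = 1:5) {
  lapply(seeds, function(s) cached(paste0("uncoupled_", s), {
    net <- build_network(n = 100, w = 0, p = 0,
                         seed_population = s, seed_topology = s + 100)
    simulate_network(net, duration = 50000, discard = 20000, seed_init = s + 200)
  }))
}

reduced_traj <- function(w, duration = 350000, discard = 50000) {
  cached(sprintf("reduced_w%.2f_%d", w, duration),
         simulate_reduced(w = w, duration = duration, discard = discard))
}
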