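# Time stepping of the full conductance-based network with the
# exponential-Euler scheme at a fixed step (0.1 ms by default), upward
# threshold-crossing spike detection, and recording of spikes and of
# (V, h_NaP) traces for selected neurons.

#' Detect spikes as upward threshold crossings
#'
#' A spike is registered when the membrane potential crosses the threshold
#' from below between two consecutive samples: `v_prev < threshold <= v_curr`.
#' A neuron sitting above threshold therefore spikes exactly once, at onset.
#'
#' @param v_prev,v_curr Aligned voltage vectors at consecutive steps (mV).
#' @param threshold Spike threshold (mV).
#' @return Logical vector, `TRUE` where a spike occurred.
#' @export
detect_spikes <- function(v_prev, v_curr, threshold = -35) {
  stopifnot(length(v_prev) == length(v_curr))
  v_prev < threshold & v_curr >= threshold
}

# Pure-R exponential-Euler step over a state tibble; mirrors the compiled
# integrator exactly and serves as its cross-check on small problems.
# `incoming_spikes`: logical vector of presynaptic spikes from the previous
# step, consumed as synaptic increments at the start of this one.
step_exponential_euler <- function(state, network, dt,
                                   incoming_spikes = rep(FALSE, nrow(state))) {
  p <- network$params
  g <- p$gates
  pop <- network$population
  s <- state

  inc <- numeric(nrow(s))
  e <- network$edges
  if (nrow(e) && any(incoming_spikes)) {
    act <- e[incoming_spikes[e$from], , drop = FALSE]
    if (nrow(act)) {
      add <- tapply(p$g_syn_bar * act$weight, act$to, sum)
      inc[as.integer(names(add))] <- as.numeric(add)
    }
  }
  g_syn <- s$g_syn + inc

  v <- s$v
  adv <- function(x, gate) {
    xi <- steady_state(gate, v)
    xi + (x - xi) * exp(-dt / time_constant(gate, v))
  }
  # gates advance first; the membrane step uses the updated gates
  m_na <- adv(s$m_na, g$m_na); h_na <- adv(s$h_na, g$h_na)
  m_nap <- adv(s$m_nap, g$m_nap); h_nap <- adv(s$h_nap, g$h_nap)
  m_k <- adv(s$m_k, g$m_k)

  g_na_eff  <- p$g_na * m_na^3 * h_na
  g_nap_eff <- pop$g_nap * m_nap * h_nap
  g_k_eff   <- p$g_k * m_k^4
  g_tot <- g_na_eff + g_nap_eff + g_k_eff + p$g_l + g_syn
  v_inf <- (g_na_eff * p$e_na + g_nap_eff * p$e_na + g_k_eff * p$e_k +
            p$g_l * pop$e_l + g_syn * p$e_syn) / g_tot
  v_new <- v_inf + (v - v_inf) * exp(-dt * g_tot / p$C)
  spiked_now <- detect_spikes(v, v_new, p$spike_threshold)

  tibble::tibble(
    neuron_id = s$neuron_id,
    v = v_new,
    m_na = m_na, h_na = h_na,
    m_nap = m_nap, h_nap = h_nap,
    m_k = m_k,
    g_syn = g_syn * exp(-dt / p$tau_syn),
    spiked = spiked_now
  )
}

#' Simulate the conductance-based network
#'
#' Integrates the full network with the exponential-Euler scheme: every
#' variable with first-order kinetics \eqn{dx/dt = (x_\infty - x)/\tau} is
#' advanced exactly for coefficients frozen at the start of each step, the
#' membrane equation being rewritten as \eqn{\tau_V = C/\sum g},
#' \eqn{V_\infty = \sum g E / \sum g}.  Synaptic increments produced by
#' spikes in one step are applied at the start of the next (no delay).
#' Spikes and traces inside the initial `discard` window are dropped.
#'
#' @param network An `mmo_network` from [build_network()].
#' @param duration Total simulated time (ms).
#' @param dt Integration step (ms); 0.1 ms default.
#' @param discard Initial transient to drop from all outputs (ms).
#' @param init Initial-state tibble ([initial_conditions()]); if `NULL`, drawn
#'   with `seed_init`.
#' @param seed_init Seed for the initial-condition stream when `init` is NULL.
#' @param record_ids Neuron ids whose `(V, h_nap)` traces are recorded.
#' @param record_every Trace sampling stride in steps (10 => 1 ms at default dt).
#' @return An object of class `mmo_sim`: list with `spikes` (tibble
#'   `neuron_id`, `time`), `traces` (tibble `time`, `neuron_id`, `v`,
#'   `h_nap`), `network`, and `config`.
#' @examples
#' \donttest{
#' net <- build_network(n = 100, w = 2.5, p = 0.15)
#' sim <- simulate_network(net, duration = 50000, discard = 20000)
#' }
#' @export
simulate_network <- function(network, duration = 50000, dt = 0.1,
                             discard = 20000, init = NULL, seed_init = 3,
                             record_ids = integer(), record_every = 10) {
  stopifnot(inherits(network, "mmo_network"), dt > 0)
  if (discard > duration) stop("discard must not exceed duration")
  init_was_null <- is.null(init)
  if (init_was_null) init <- initial_conditions(network, seed = seed_init)
  init_m <- as.matrix(init[, c("v", "m_na", "h_na", "m_nap", "h_nap", "m_k", "g_syn")])

  res <- cpp_simulate_network(
    network$population$e_l, network$population$g_nap,
    network$params[c("C", "g_na", "g_k", "g_l", "e_na", "e_k", "e_syn",
                     "g_syn_bar", "tau_syn", "spike_threshold")],
    as.integer(network$edges$from), as.integer(network$edges$to),
    as.numeric(network$edges$weight),
    init_m, dt, duration, discard,
    as.integer(record_ids), as.integer(record_every)
  )

  spikes <- tibble::tibble(
    neuron_id = rep(seq_len(network$n), lengths(res$spikes)),
    time = unlist(res$spikes, use.names = FALSE)
  )
  if (!nrow(spikes)) spikes <- tibble::tibble(neuron_id = integer(), time = numeric())

  traces <- tibble::tibble(time = numeric(), neuron_id = integer(),
                           v = numeric(), h_nap = numeric())
  if (length(record_ids) && nrow(res$traces)) {
    tm <- res$traces
    k <- length(record_ids)
    traces <- tibble::tibble(
      time = rep(tm[, 1], times = k),
      neuron_id = rep(as.integer(record_ids), each = nrow(tm)),
      v = as.numeric(tm[, 1 + seq_len(k)]),
      h_nap = as.numeric(tm[, 1 + k + seq_len(k)])
    )
  }

  structure(list(
    spikes = spikes, traces = traces, network = network,
    config = list(duration = duration, dt = dt, discard = discard,
                  seed_init = if (init_was_null) seed_init else NA_integer_,
                  record_ids = record_ids, record_every = record_every),
    final_state = res$final_state
  ), class = "mmo_sim")
}

#' @export
print.mmo_sim <- function(x, ...) {
  cat("<mmo_sim> ", x$network$n, " neurons, ",
      round((x$config$duration - x$config$discard) / 1000, 1),
      " s analysed (", nrow(x$spikes), " spikes)\n", sep = "")
  invisible(x)
}

#' Tidy a network simulation into its spike table
#'
#' @param x An `mmo_sim` object.
#' @param ... Unused.
#' @return The spike tibble (`neuron_id`, `time` in ms).
#' @export
tidy.mmo_sim <- function(x, ...) x$spikes

#' One-row summary of a network simulation
#'
#' @param x An `mmo_sim` object.
#' @param ... Unused.
#' @return A one-row tibble with counts and timing metadata.
#' @export
glance.mmo_sim <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$network$n,
    n_spikes = nrow(x$spikes),
    duration_ms = x$config$duration,
    discard_ms = x$config$discard,
    dt_ms = x$config$dt,
    n_active = dplyr::n_distinct(x$spikes$neuron_id)
  )
}
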