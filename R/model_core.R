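# Conductance-based single-neuron kinetics for the 100-neuron network model.
#
# Each neuron carries a fast sodium current I_Na, a persistent (slowly
# inactivating) sodium current I_NaP, a delayed-rectifier potassium current
# I_K, a leak current I_L and an excitatory synaptic current I_SynE, with
# C dV/dt = -(I_Na + I_NaP + I_K + I_L + I_SynE).  Gating variables follow
# first-order kinetics tau_x(V) dx/dt = x_inf(V) - x.

#' Gating-kinetics specifications for the conductance-based neuron
#'
#' Returns the voltage-dependent kinetics of the five gating variables of the
#' network neuron model: fast-sodium activation (`m_na`) and inactivation
#' (`h_na`), persistent-sodium activation (`m_nap`) and slow inactivation
#' (`h_nap`), and delayed-rectifier potassium activation (`m_k`).  All gates
#' except `m_k` use sigmoid steady states
#' \eqn{x_\infty(V) = 1/(1+\exp(-(V - V_{1/2})/k))} with cosh-shaped time
#' constants peaking at \eqn{V_{1/2}}; the potassium gate uses classical
#' rate functions \eqn{\alpha_K(V)}, \eqn{\beta_K(V)}.
#'
#' A negative slope `k` encodes an inactivation gate (steady state decreasing
#' in V).  Units: mV for voltages and slopes, ms for time constants.
#'
#' @return A named list of gating specs, each a list with `form`
#'   (`"sigmoid_cosh"` or `"alpha_beta"`) and the corresponding constants.
#' @examples
#' g <- hh_gates()
#' steady_state(g$m_nap, -47.1)   # half-activation: 0.5
#' time_constant(g$h_nap, -60)    # slowest point of the slow inactivation: 6000 ms
#' @export
hh_gates <- function() {
  sig <- function(v_half, k, tau_max, tau_v_half, tau_k) {
    list(form = "sigmoid_cosh", v_half = v_half, k = k,
         tau_max = tau_max, tau_v_half = tau_v_half, tau_k = tau_k)
  }
  list(
    m_na  = sig(-43.8,  6.0, 0.25, -43.8, 14.0),
    h_na  = sig(-67.5, -10.8, 8.46, -67.5, 12.8),
    m_nap = sig(-47.1,  3.1, 1.0,  -47.1,  6.2),
    h_nap = sig(-60.0, -9.0, 6000, -60.0,  9.0),
    m_k   = list(form = "alpha_beta")
  )
}

alpha_k <- function(v) {
  x <- v + 45
  ifelse(abs(x) < 1e-7, 0.05, 0.01 * x / (1 - exp(-x / 5)))
}

beta_k <- function(v) 0.17 * exp(-(v + 49) / 40)

#' Steady-state value of a gating variable
#'
#' @param gate One element of [hh_gates()].
#' @param v Membrane potential (mV); vectorised.
#' @return Steady-state activation/inactivation in (0, 1).
#' @export
steady_state <- function(gate, v) {
  stopifnot(all(is.finite(v)))
  if (gate$form == "alpha_beta") {
    a <- alpha_k(v)
    b <- beta_k(v)
    a / (a + b)
  } else {
    1 / (1 + exp(-(v - gate$v_half) / gate$k))
  }
}

#' Voltage-dependent time constant of a gating variable
#'
#' @inheritParams steady_state
#' @return Time constant in ms (strictly positive).
#' @export
time_constant <- function(gate, v) {
  stopifnot(all(is.finite(v)))
  if (gate$form == "alpha_beta") {
    1 / (alpha_k(v) + beta_k(v))
  } else {
    gate$tau_max / cosh((v - gate$tau_v_half) / gate$tau_k)
  }
}

#' Fixed parameters of the conductance-based network neuron
#'
#' Default single-neuron and synaptic constants of the 100-neuron model.
#' The two heterogeneous parameters (`e_l`, `g_nap`) give the population
#' means; per-neuron values are drawn by [build_population()].
#'
#' @param ... Named overrides of the defaults.
#' @return A list with membrane capacitance `C` (pF), maximal conductances
#'   `g_na`, `g_nap`, `g_k`, `g_l` (nS), reversal potentials `e_na`, `e_k`,
#'   `e_l`, `e_syn` (mV), synaptic increment scale `g_syn_bar` (nS), synaptic
#'   decay `tau_syn` (ms), `spike_threshold` (mV) and the [hh_gates()] table.
#' @export
hh_params <- function(...) {
  p <- list(
    C = 36.2,
    g_na = 170, g_nap = 5, g_k = 180, g_l = 2.5,
    e_na = 60, e_k = -94, e_l = -62, e_syn = -10,
    g_syn_bar = 0.05, tau_syn = 5, spike_threshold = -35,
    gates = hh_gates()
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown hh_params field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$C > 0, p$g_na >= 0, p$g_nap >= 0, p$g_k >= 0, p$g_l >= 0,
            p$e_k < p$e_l, p$e_l < p$e_na, p$g_syn_bar >= 0, p$tau_syn > 0)
  p
}

#' Instantaneous ionic currents of one neuron
#'
#' Evaluates the five membrane currents from a neuron state.  Units follow
#' the nS x mV = pA convention, so positive values hyperpolarise through
#' \eqn{C\,dV/dt = -\sum I}.
#'
#' @param state A data frame or named list with `v`, `m_na`, `h_na`, `m_nap`,
#'   `h_nap`, `m_k`, `g_syn` (one row per neuron).
#' @param params [hh_params()] list; per-neuron `e_l`/`g_nap` may be supplied
#'   as columns of `state` and override the scalar defaults.
#' @return A tibble with columns `i_na`, `i_nap`, `i_k`, `i_l`, `i_syn` (pA).
#' @export
ionic_currents <- function(state, params = hh_params()) {
  s <- tibble::as_tibble(as.list(state)[c("v", "m_na", "h_na", "m_nap",
                                          "h_nap", "m_k", "g_syn",
                                          intersect(names(state), c("e_l", "g_nap")))])
  e_l <- if ("e_l" %in% names(s)) s$e_l else params$e_l
  g_nap <- if ("g_nap" %in% names(s)) s$g_nap else params$g_nap
  tibble::tibble(
    i_na  = params$g_na * s$m_na^3 * s$h_na * (s$v - params$e_na),
    i_nap = g_nap * s$m_nap * s$h_nap * (s$v - params$e_na),
    i_k   = params$g_k * s$m_k^4 * (s$v - params$e_k),
    i_l   = params$g_l * (s$v - e_l),
    i_syn = s$g_syn * (s$v - params$e_syn)
  )
}

#' Advance the aggregate synaptic conductance by one step
#'
#' The synaptic conductance is a superposition of single-exponential kernels:
#' every presynaptic spike from neuron j adds `g_syn_bar * w_ji` instantly and
#' the total decays with time constant `tau_syn`.  Tracking the single decaying
#' state is mathematically identical to summing the kernel over the full spike
#' history, with no truncation.
#'
#' @param g_syn Current aggregate conductance (nS); vectorised.
#' @param dt Time step (ms), > 0.
#' @param incoming Data frame (or NULL) of spikes arriving at the start of the
#'   step, with columns `weight` and `count`.
#' @param g_syn_bar Conductance increment scale (nS).
#' @param tau_syn Synaptic decay time constant (ms).
#' @return Updated conductance after increments then `dt` of decay.
#' @export
synaptic_conductance_update <- function(g_syn, dt, incoming = NULL,
                                        g_syn_bar = 0.05, tau_syn = 5) {
  stopifnot(dt > 0, tau_syn > 0, g_syn_bar >= 0, all(g_syn >= 0))
  inc <- 0
  if (!is.null(incoming) && nrow(incoming)) {
    if (any(incoming$weight < 0)) stop("negative synaptic weight: the model has only excitation")
    inc <- sum(g_syn_bar * incoming$weight * incoming$count)
  }
  (g_syn + inc) * exp(-dt / tau_syn)
}
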