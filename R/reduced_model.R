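# The reduced activity-based network: three non-spiking neurons, each a
# fast voltage V (persistent sodium + leak + synaptic currents) coupled to
# the slow I_NaP inactivation h_NaP.  A piecewise-linear output f(V)
# represents each unit's normalised firing rate; units are coupled
# all-to-all through w * f(V_j).  Leak reversal potentials set the
# excitability ordering HE > ME > LE.

#' Parameters of the reduced activity-based neuron
#'
#' Default constants of the two-variable activity-based unit.  `e_l` holds
#' the three leak reversal potentials (HE, ME, LE); pass a single value for a
#' one-neuron model.
#'
#' @param ... Named overrides.
#' @return List with capacitance `C` (pF); conductances `g_nap`, `g_l`,
#'   `g_syn` (nS); reversals `e_na`, `e_syn`, `e_l` (mV); activation sigmoid
#'   `v_m`, `k_m`; inactivation sigmoid `v_h`, `k_h`; inactivation time
#'   constant `v_tau`, `k_tau`, `tau_max` (ms); output clamp `v_min`, `v_max`.
#' @export
reduced_params <- function(...) {
  p <- list(
    C = 20, g_nap = 5, g_l = 2.8, g_syn = 0.1,
    e_na = 50, e_syn = -10,
    e_l = c(HE = -54.5, ME = -59.0, LE = -63.5),
    v_m = -40, k_m = -6,
    v_h = -59, k_h = 10,
    v_tau = -59, k_tau = 20, tau_max = 5000,
    v_min = -50, v_max = 0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown reduced_params field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$v_min < p$v_max, p$tau_max > 0,
            p$g_nap >= 0, p$g_l >= 0, p$g_syn >= 0)
  p
}

#' Piecewise-linear output function of the activity-based neuron
#'
#' \eqn{f(V)} is 0 below `v_min`, rises linearly to 1 at `v_max`, and
#' saturates at 1 above; it stands for the unit's normalised firing rate.
#'
#' @param v Voltage (mV); vectorised.
#' @param params [reduced_params()].
#' @return Output in `[0, 1]`.
#' @export
output_function <- function(v, params = reduced_params()) {
  pmin(1, pmax(0, (v - params$v_min) / (params$v_max - params$v_min)))
}

#' Steady-state I_NaP activation of the reduced neuron
#' @inheritParams output_function
#' @return Activation in (0, 1), increasing in `v` (the slope constant is
#'   negative in the `1/(1+exp((V - V_m)/k_m))` form).
#' @export
reduced_m_inf <- function(v, params = reduced_params()) {
  1 / (1 + exp((v - params$v_m) / params$k_m))
}

#' Steady-state I_NaP inactivation of the reduced neuron
#' @inheritParams output_function
#' @return Inactivation in (0, 1), decreasing in `v`.
#' @export
reduced_h_inf <- function(v, params = reduced_params()) {
  1 / (1 + exp((v - params$v_h) / params$k_h))
}

#' Voltage-dependent time constant of the slow inactivation
#' @inheritParams output_function
#' @return Time constant (ms), maximal `tau_max` at `v_tau`.
#' @export
reduced_tau_h <- function(v, params = reduced_params()) {
  params$tau_max / cosh((v - params$v_tau) / params$k_tau)
}

#' Right-hand side of the reduced model
#'
#' Evaluates \eqn{dV_i/dt} and \eqn{dh_i/dt} for all units at one state.
#' The synaptic current into unit i is
#' \eqn{\sum_{j \ne i} w f(V_j)\, \bar g_{SynE} (V_i - E_{SynE})}.
#'
#' @param v,h Numeric vectors of voltages (mV) and inactivations.
#' @param w Uniform coupling weight.
#' @param params [reduced_params()]; `e_l` must match `length(v)`.
#' @return Tibble with `dv` (mV/ms) and `dh` (1/ms).
#' @export
reduced_derivatives <- function(v, h, w = 0, params = reduced_params()) {
  stopifnot(length(v) == length(h), length(params$e_l) == length(v))
  f <- output_function(v, params)
  drive <- w * (sum(f) - f)
  i_nap <- params$g_nap * reduced_m_inf(v, params) * h * (v - params$e_na)
  i_l <- params$g_l * (v - params$e_l)
  i_syn <- drive * params$g_syn * (v - params$e_syn)
  tibble::tibble(
    dv = -(i_nap + i_l + i_syn) / params$C,
    dh = (reduced_h_inf(v, params) - h) / reduced_tau_h(v, params)
  )
}

#' Simulate the reduced network
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration (0.5 ms step
#' by default; convergence is checked by halving the step).  A transient
#' multiplicative perturbation of all leak reversals and/or of the coupling
#' weight can be applied inside a time window to reproduce
#' excitability/weight modulation experiments.
#'
#' @param w Coupling weight (dimensionless).
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param discard Initial span dropped from the returned trajectory (ms).
#' @param params [reduced_params()].
#' @param v0,h0 Initial state (defaults: all units at -60 mV, h = 0.6).
#' @param record_every Output stride in steps.
#' @param perturb `NULL`, or `list(t_on, t_off, e_l_scale = 1, w_scale = 1)`
#'   applying `e_l * e_l_scale` and `w * w_scale` for `t_on <= t < t_off`.
#' @return A tibble of class `mmo_reduced`: `time`, `v1..`, `h1..`, `f1..`
#'   and `f_sum`, with `w`, `params` and `dt` attributes.
#' @examples
#' traj <- simulate_reduced(w = 2, duration = 60000, discard = 20000)
#' @export
simulate_reduced <- function(w = 0, duration = 100000, dt = 0.5, discard = 0,
                             params = reduced_params(),
                             v0 = NULL, h0 = NULL, record_every = 2L,
                             perturb = NULL) {
  n <- length(params$e_l)
  if (is.null(v0)) v0 <- rep(-60, n)
  if (is.null(h0)) h0 <- rep(0.6, n)
  stopifnot(length(v0) == n, length(h0) == n, dt > 0, discard <= duration)
  pb <- list(t_on = 0, t_off = 0, e_l_scale = 1, w_scale = 1)
  if (!is.null(perturb)) pb[names(perturb)] <- perturb

  m <- cpp_simulate_reduced(unname(params$e_l), params, w, v0, h0, dt,
                            duration, discard, as.integer(record_every),
                            pb$t_on, pb$t_off, pb$e_l_scale, pb$w_scale)
  out <- tibble::as_tibble(as.data.frame(m),
                           .name_repair = ~ c("time",
                                              paste0("v", seq_len(n)),
                                              paste0("h", seq_len(n))))
  fs <- lapply(seq_len(n), function(i) output_function(out[[paste0("v", i)]], params))
  names(fs) <- paste0("f", seq_len(n))
  out <- dplyr::bind_cols(out, tibble::as_tibble(fs))
  out$f_sum <- Reduce(`+`, fs)
  class(out) <- c("mmo_reduced", class(out))
  attr(out, "w") <- w
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  out
}

interval_events <- function(time, active) {
  # maximal runs of TRUE -> (onset, offset) using sample times
  if (!any(active)) return(tibble::tibble(onset = numeric(), offset = numeric()))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(onset = time[starts[r$values]], offset = time[ends[r$values]])
}

#' Detect activation events and classify network burst cycles
#'
#' A unit's activation event is a maximal interval with
#' `f(V) > active_threshold`.  Overlapping events across units are merged
#' (transitively) into network events; a network event is a large-amplitude
#' (LA) burst exactly when the LE unit's activation overlaps it, otherwise a
#' small-amplitude (SA) burst.
#'
#' @param traj An `mmo_reduced` trajectory.
#' @param active_threshold Activation threshold on `f(V)`.
#' @param le_unit Index of the low-excitability unit (3 by default).
#' @return An object of class `mmo_cycles`: list with `unit_events`
#'   (tibble `unit`, `onset`, `offset`), `network_events` (tibble `event`,
#'   `onset`, `offset`, `class`, `units` list-column) and the settings.
#' @export
detect_cycles <- function(traj, active_threshold = 0.05, le_unit = 3L) {
  stopifnot(active_threshold > 0, active_threshold < 1)
  n <- sum(grepl("^v[0-9]+$", names(traj)))
  ue <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    ev <- interval_events(traj$time, traj[[paste0("f", i)]] > active_threshold)
    if (nrow(ev)) ev$unit <- i
    ev
  }))
  if (!nrow(ue)) {
    ne <- tibble::tibble(event = integer(), onset = numeric(),
                         offset = numeric(), class = character(),
                         units = list())
    return(structure(list(unit_events = ue, network_events = ne,
                          active_threshold = active_threshold,
                          le_unit = le_unit),
                     class = "mmo_cycles"))
  }
  ue <- dplyr::arrange(ue, .data$onset)
  # merge temporally overlapping unit events into network events
  grp <- integer(nrow(ue))
  grp[1] <- 1L
  cur_end <- ue$offset[1]
  for (k in seq_len(nrow(ue))[-1]) {
    if (ue$onset[k] <= cur_end) {
      grp[k] <- grp[k - 1]
      cur_end <- max(cur_end, ue$offset[k])
    } else {
      grp[k] <- grp[k - 1] + 1L
      cur_end <- ue$offset[k]
    }
  }
  ne <- tibble::tibble(grp = grp, onset = ue$onset, offset = ue$offset,
                       unit = ue$unit) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(onset = min(.data$onset), offset = max(.data$offset),
                     units = list(sort(unique(.data$unit))), .groups = "drop")
  ne <- dplyr::arrange(ne, .data$onset)
  ne$event <- seq_len(nrow(ne))
  ne$class <- ifelse(vapply(ne$units, function(u) le_unit %in% u, logical(1)),
                     "LA", "SA")
  ne <- ne[, c("event", "onset", "offset", "class", "units")]
  structure(list(unit_events = ue[, c("unit", "onset", "offset")],
                 network_events = ne,
                 active_threshold = active_threshold, le_unit = le_unit),
            class = "mmo_cycles")
}

#' @export
print.mmo_cycles <- function(x, ...) {
  ne <- x$network_events
  cat("<mmo_cycles> ", nrow(ne), " network events (",
      sum(ne$class == "LA"), " LA / ", sum(ne$class == "SA"), " SA)\n", sep = "")
  invisible(x)
}

#' Tidy the network events of a cycle detection
#' @param x An `mmo_cycles` object.
#' @param ... Unused.
#' @return The network-event tibble.
#' @export
tidy.mmo_cycles <- function(x, ...) x$network_events

#' Quantal-regime summary of a reduced-model run
#'
#' Applies [regime_summary()] to the detected network events: `n_per_la` is
#' the modal number of burst events per LE-activation (LA-to-LA) period, and
#' the regime is `stable` when at least `min_consistent` consecutive periods
#' agree.
#'
#' @param x An `mmo_cycles` object or an `mmo_reduced` trajectory.
#' @param ... Passed to [detect_cycles()] when `x` is a trajectory.
#' @param min_consistent Stability requirement (consecutive periods).
#' @return One-row regime tibble (see [regime_summary()]).
#' @export
reduced_regime <- function(x, ..., min_consistent = 5) {
  if (inherits(x, "mmo_reduced")) x <- detect_cycles(x, ...)
  ne <- x$network_events
  b <- tibble::tibble(onset = ne$onset, offset = ne$offset, peak = NA_real_,
                      class = ne$class)
  regime_summary(b, min_consistent = min_consistent)
}

#' Glance at a cycle detection
#' @param x An `mmo_cycles` object.
#' @param ... Unused.
#' @return One-row regime summary tibble.
#' @export
glance.mmo_cycles <- function(x, ...) reduced_regime(x)

#' Scan coupling weights and collect per-unit cycle periods
#'
#' For each weight the reduced network is simulated and every unit's
#' activation-onset-to-onset periods in the analysis window are collected,
#' reproducing the staircase of burst periods versus coupling weight.
#'
#' @param w_values Weights to scan.
#' @param duration,discard Per-weight simulation span (ms).
#' @param params,active_threshold,dt As in [simulate_reduced()] /
#'   [detect_cycles()].
#' @return Tibble `w`, `unit`, `onset`, `period` (ms; one row per completed
#'   cycle, `NA` period rows flag units with a single activation).
#' @export
scan_weights <- function(w_values, duration = 350000, discard = 50000,
                         params = reduced_params(), active_threshold = 0.05,
                         dt = 0.5) {
  dplyr::bind_rows(lapply(w_values, function(w) {
    traj <- simulate_reduced(w = w, duration = duration, dt = dt,
                             discard = discard, params = params)
    cyc <- detect_cycles(traj, active_threshold = active_threshold)
    ue <- cyc$unit_events
    if (!nrow(ue)) return(tibble::tibble(w = numeric(), unit = integer(),
                                         onset = numeric(), period = numeric()))
    t0 <- min(traj$time)
    dplyr::bind_rows(lapply(sort(unique(ue$unit)), function(u) {
      on <- sort(ue$onset[ue$unit == u])
      on <- on[on > t0]           # drop events truncated by the window start
      tibble::tibble(w = w, unit = u, onset = on,
                     period = c(diff(on), NA_real_))
    }))
  }))
}

#' Classify an uncoupled reduced neuron from a simulated trajectory
#'
#' Simulates a single uncoupled unit at the given leak reversal and labels
#' its long-run behaviour: `bursting` when the post-transient voltage keeps
#' oscillating with large amplitude (range above `osc_range` mV), otherwise
#' `silent`/`tonic` according to whether the state settles on the
#' low-voltage (high `h`) or depolarised (low `h`) branch.
#'
#' Near the tonic end the oscillation shrinks continuously (supercritical
#' Hopf), so the amplitude is measured on the final half of the analysis
#' window, after slowly-decaying transients have died out.
#'
#' @param e_l Leak reversal potential (mV).
#' @param duration,discard Simulation span and transient (ms).
#' @param params Base [reduced_params()] (its `e_l` is replaced).
#' @param osc_range Sustained voltage peak-to-peak amplitude above which the
#'   unit counts as oscillating (mV).
#' @param dt Integration step (ms).
#' @return One of `"silent"`, `"bursting"`, `"tonic"`.
#' @export
classify_reduced_neuron <- function(e_l, duration = 250000, discard = 50000,
                                    params = reduced_params(),
                                    osc_range = 1, dt = 0.5) {
  p <- params
  p$e_l <- e_l
  traj <- simulate_reduced(w = 0, duration = duration, dt = dt,
                           discard = discard, params = p, v0 = -60, h0 = 0.6,
                           record_every = 4L)
  late <- traj$time >= (discard + duration) / 2
  v <- traj$v1[late]
  if (diff(range(v)) > osc_range) "bursting"
  else if (mean(v) < p$v_min) "silent"   # resting below the output threshold
  else "tonic"
}

#' Scan excitability of the uncoupled reduced neuron
#'
#' Classifies the unit's intrinsic mode over a grid of leak reversal
#' potentials (silence, endogenous bursting or tonic depolarisation), the
#' simulation-based route to the conditional-bursting window.
#'
#' @param e_l_values Grid of leak reversals (mV).
#' @param ... Passed to [classify_reduced_neuron()].
#' @return Tibble `e_l`, `mode`.
#' @export
scan_excitability <- function(e_l_values, ...) {
  tibble::tibble(
    e_l = e_l_values,
    mode = vapply(e_l_values, classify_reduced_neuron, character(1), ...)
  )
}
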