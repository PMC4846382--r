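# Fast-slow geometry of the reduced neuron in the (V, h_NaP) plane.
#
# Setting dV/dt = 0 in the voltage equation gives the cubic V-nullcline
#   h(V) = -[g_L (V - E_L) + d * g_SynE (V - E_SynE)] /
#           [g_NaP m_inf(V) (V - E_Na)],
# where d = sum_j w f(V_j) is the synaptic drive held as a frozen parameter
# (quasi-static approximation).  The h-nullcline is h_inf(V).  The local
# maximum (left knee) of the V-nullcline sets the activation threshold and
# the local minimum (right knee) sets burst termination; excitatory input
# lowers the nullcline and its knees (fast threshold modulation).

#' Closed-form V-nullcline height
#'
#' @param v Voltage grid (mV); must exclude `e_na` (removable singularity).
#' @param e_l Leak reversal potential (mV).
#' @param drive Synaptic drive \eqn{d = \sum_j w f(V_j)} (dimensionless),
#'   frozen as a parameter.
#' @param params [reduced_params()].
#' @return The inactivation `h` at which \eqn{dV/dt = 0}.
#' @export
v_nullcline_h <- function(v, e_l, drive = 0, params = reduced_params()) {
  if (any(v == params$e_na)) stop("V grid must exclude e_na (singular point)")
  -(params$g_l * (v - e_l) + drive * params$g_syn * (v - params$e_syn)) /
    (params$g_nap * reduced_m_inf(v, params) * (v - params$e_na))
}

#' Sampled V-nullcline with branch labels
#'
#' Samples the closed form over a grid and, when both knees exist, labels
#' each point `left`, `middle`, or `right` by its position relative to the
#' knee voltages.
#'
#' @param e_l Leak reversal (mV).
#' @param drive Frozen synaptic drive.
#' @param v_grid Sampling grid (mV); defaults to 2001 points on
#'   `[-75, -10]`.
#' @param params [reduced_params()].
#' @return Tibble `v`, `h`, `branch` with attributes `e_l`, `drive`.
#' @export
v_nullcline <- function(e_l, drive = 0, v_grid = seq(-75, -10, length.out = 2001),
                        params = reduced_params()) {
  h <- v_nullcline_h(v_grid, e_l, drive, params)
  kn <- find_knees(e_l, drive, params = params,
                   v_range = range(v_grid))
  branch <- rep(NA_character_, length(v_grid))
  if (nrow(kn) == 2) {
    vl <- kn$v[kn$kind == "left"]
    vr <- kn$v[kn$kind == "right"]
    branch <- dplyr::case_when(v_grid < vl ~ "left",
                               v_grid > vr ~ "right",
                               TRUE ~ "middle")
  }
  out <- tibble::tibble(v = v_grid, h = h, branch = branch)
  attr(out, "e_l") <- e_l
  attr(out, "drive") <- drive
  out
}

#' Sampled h-nullcline
#'
#' The slow nullcline is simply the steady-state inactivation curve
#' `h = h_inf(V)`, monotone decreasing in V.
#'
#' @param v_grid Sampling grid (mV).
#' @param params [reduced_params()].
#' @return Tibble `v`, `h`.
#' @export
h_nullcline <- function(v_grid = seq(-75, -10, length.out = 2001),
                        params = reduced_params()) {
  tibble::tibble(v = v_grid, h = reduced_h_inf(v_grid, params))
}

#' Locate the knees (folds) of the V-nullcline
#'
#' Finds the local maximum (left knee) and local minimum (right knee) of the
#' closed-form nullcline by grid bracketing plus golden-section refinement.
#' Monotone nullclines (possible at extreme excitability or drive) yield
#' zero rows.
#'
#' @param e_l Leak reversal (mV).
#' @param drive Frozen synaptic drive.
#' @param params [reduced_params()].
#' @param v_range Search interval (mV), kept below `e_na`.
#' @param tol Refinement tolerance on V (mV).
#' @return Tibble `kind` (`"left"`/`"right"`), `v`, `h`, `drive`.
#' @export
find_knees <- function(e_l, drive = 0, params = reduced_params(),
                       v_range = c(-75, -10), tol = 1e-9) {
  f <- function(v) v_nullcline_h(v, e_l, drive, params)
  vg <- seq(v_range[1], v_range[2], length.out = 4001)
  hg <- f(vg)
  dh <- diff(hg)
  sign_change <- which(dh[-length(dh)] * dh[-1] < 0)
  out <- list()
  for (i in sign_change) {
    lo <- vg[i]
    hi <- vg[i + 2]
    if (dh[i] > 0) {               # rising then falling: local max = left knee
      o <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
      out[[length(out) + 1]] <- tibble::tibble(kind = "left", v = o$maximum,
                                               h = o$objective, drive = drive)
    } else {                        # falling then rising: local min = right knee
      o <- optimize(f, c(lo, hi), maximum = FALSE, tol = tol)
      out[[length(out) + 1]] <- tibble::tibble(kind = "right", v = o$minimum,
                                               h = o$objective, drive = drive)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(kind = character(), v = numeric(), h = numeric(),
                          drive = numeric()))
  }
  res <- dplyr::bind_rows(out)
  # keep the principal pair: the left knee with the largest h, right with smallest
  left <- res[res$kind == "left", ][which.max(res$h[res$kind == "left"]), ]
  right <- res[res$kind == "right", ][which.min(res$h[res$kind == "right"]), ]
  dplyr::bind_rows(left, right)
}

#' Fixed points of the reduced neuron under frozen drive
#'
#' Intersections of the V- and h-nullclines, located by sign changes of
#' `h_inf(V) - h_nullcline(V)` on a fine grid refined with [stats::uniroot()].
#' Each fixed point is assigned a branch (relative to the knee voltages), the
#' implied mode (left = silence, middle = bursting via an unstable focus
#' surrounded by a relaxation orbit, right = tonic depolarisation), and a
#' linearised stability label as a cross-check.
#'
#' @inheritParams find_knees
#' @return Tibble `v`, `h`, `branch`, `mode`, `stable` (from the Jacobian of
#'   the two-variable system).
#' @export
fixed_points <- function(e_l, drive = 0, params = reduced_params(),
                         v_range = c(-75, -10)) {
  g <- function(v) reduced_h_inf(v, params) - v_nullcline_h(v, e_l, drive, params)
  vg <- seq(v_range[1], v_range[2], length.out = 8001)
  gv <- g(vg)
  idx <- which(gv[-length(gv)] * gv[-1] < 0)
  kn <- find_knees(e_l, drive, params, v_range)
  p1 <- params
  rows <- lapply(idx, function(i) {
    r <- uniroot(g, c(vg[i], vg[i + 1]), tol = 1e-12)
    v0 <- r$root
    h0 <- reduced_h_inf(v0, params)
    branch <- if (nrow(kn) == 2) {
      if (v0 < kn$v[kn$kind == "left"]) "left"
      else if (v0 > kn$v[kn$kind == "right"]) "right"
      else "middle"
    } else NA_character_
    # numerical Jacobian of (dv, dh) at the fixed point (single unit with
    # frozen external drive folded into an effective leak)
    p1$e_l <- e_l
    rhs <- function(v, h) {
      i_nap <- p1$g_nap * reduced_m_inf(v, p1) * h * (v - p1$e_na)
      i_l <- p1$g_l * (v - e_l)
      i_syn <- drive * p1$g_syn * (v - p1$e_syn)
      c(-(i_nap + i_l + i_syn) / p1$C,
        (reduced_h_inf(v, p1) - h) / reduced_tau_h(v, p1))
    }
    eps <- 1e-6
    j11 <- (rhs(v0 + eps, h0)[1] - rhs(v0 - eps, h0)[1]) / (2 * eps)
    j12 <- (rhs(v0, h0 + eps)[1] - rhs(v0, h0 - eps)[1]) / (2 * eps)
    j21 <- (rhs(v0 + eps, h0)[2] - rhs(v0 - eps, h0)[2]) / (2 * eps)
    j22 <- (rhs(v0, h0 + eps)[2] - rhs(v0, h0 - eps)[2]) / (2 * eps)
    tr <- j11 + j22
    det <- j11 * j22 - j12 * j21
    tibble::tibble(
      v = v0, h = h0, branch = branch,
      mode = dplyr::case_when(branch == "left" ~ "silence",
                              branch == "middle" ~ "bursting",
                              branch == "right" ~ "tonic",
                              TRUE ~ NA_character_),
      stable = det > 0 & tr < 0
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(v = numeric(), h = numeric(), branch = character(),
                          mode = character(), stable = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Classify intrinsic excitability from phase-plane geometry
#'
#' Locates the uncoupled neuron's fixed point(s) and reports the implied
#' long-run mode.  A fixed point on the middle branch (unstable focus) means
#' endogenous bursting via the surrounding relaxation orbit.  A stable fixed
#' point means rest: silence when it sits on the hyperpolarised left branch
#' (below the output threshold `v_min`), tonic constant depolarisation when
#' it sits at elevated voltage.  Near the upper end of the bursting window
#' the two knees approach a cusp and branch labels degenerate, so the
#' stable-point dichotomy uses the voltage level rather than the branch
#' label; with several fixed points, stable ones take precedence.
#'
#' @param e_l Leak reversal (mV).
#' @param drive Frozen synaptic drive (0 = uncoupled).
#' @param params [reduced_params()].
#' @return One of `"silence"`, `"bursting"`, `"tonic"`.
#' @export
classify_excitability <- function(e_l, drive = 0, params = reduced_params()) {
  fp <- fixed_points(e_l, drive, params)
  if (!nrow(fp)) return(NA_character_)
  stab <- fp[fp$stable, , drop = FALSE]
  if (nrow(stab)) {
    if (stab$v[1] >= params$v_min) "tonic" else "silence"
  } else "bursting"
}

#' Left-knee height as a function of synaptic drive
#'
#' The curve of knees: the h-coordinate of the activation threshold (left
#' knee) sampled over drive levels.  Overlaying a unit's simulated
#' `(drive, h)` trajectory on this curve shows event-by-event whether an
#' input can recruit it: activation occurs when the trajectory lies above
#' the curve.
#'
#' @param drive_values Drive grid (>= 2 points).
#' @param e_l Leak reversal of the unit (mV).
#' @param params [reduced_params()].
#' @param kind `"left"` (default) or `"right"` knee.
#' @return Tibble `drive`, `v`, `h`.
#' @export
curve_of_knees <- function(drive_values, e_l, params = reduced_params(),
                           kind = c("left", "right")) {
  kind <- match.arg(kind)
  stopifnot(length(drive_values) >= 2)
  dplyr::bind_rows(lapply(drive_values, function(d) {
    kn <- find_knees(e_l, d, params)
    kn <- kn[kn$kind == kind, ]
    if (!nrow(kn)) return(tibble::tibble(drive = d, v = NA_real_, h = NA_real_))
    tibble::tibble(drive = d, v = kn$v, h = kn$h)
  }))
}
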