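# Seeded generation of the heterogeneous population and its sparse random
# excitatory connectivity.  Three independent seed streams (population,
# topology, initial conditions) make every simulation fully reproducible
# and independently re-randomisable.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw a heterogeneous neuronal population
#'
#' Per-neuron excitability (`e_l`, the leak reversal potential) and
#' persistent-sodium maximal conductance (`g_nap`) are drawn from independent
#' Gaussian distributions; all other parameters are fixed at the
#' [hh_params()] defaults.  The `+/- sd` spread is interpreted as a standard
#' deviation.  Draws are untruncated except that a non-positive `g_nap`
#' (probability ~1e-23 at the defaults) is redrawn to keep conductances
#' physical.
#'
#' @param n Number of neurons.
#' @param e_l_mean,e_l_sd Mean and SD of the leak reversal potential (mV).
#' @param g_nap_mean,g_nap_sd Mean and SD of the I_NaP maximal conductance (nS).
#' @param seed Integer seed for the population stream.
#' @return A tibble with `neuron_id`, `e_l`, `g_nap`, one row per neuron.
#' @examples
#' pop <- build_population(100, seed = 1)
#' @export
build_population <- function(n = 100, e_l_mean = -62, e_l_sd = 0.93,
                             g_nap_mean = 5, g_nap_sd = 0.5, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(e_l_sd >= 0, g_nap_sd >= 0)
  with_seed(seed, {
    e_l <- rnorm(n, e_l_mean, e_l_sd)
    g_nap <- rnorm(n, g_nap_mean, g_nap_sd)
    while (any(bad <- g_nap <= 0)) g_nap[bad] <- rnorm(sum(bad), g_nap_mean, g_nap_sd)
    tibble::tibble(neuron_id = seq_len(n), e_l = e_l, g_nap = g_nap)
  })
}

#' Draw sparse random directed connectivity
#'
#' Every ordered pair (j, i), j != i, is connected independently with
#' probability `p`; present edges carry the uniform weight `w`.  With `n`
#' neurons, `p * n` is the mean number of postsynaptic targets per neuron.
#' Connections are directed: the pairs (j, i) and (i, j) are decided
#' independently.
#'
#' @param n Number of neurons.
#' @param p Connection probability in `[0, 1]`.
#' @param w Uniform synaptic weight (dimensionless, >= 0).
#' @param seed Integer seed for the topology stream.
#' @return An edge-list tibble with `from`, `to`, `weight`.
#' @export
build_connectivity <- function(n, p = 0.15, w = 2.5, seed = 1) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (w < 0) stop("w must be >= 0: the model has only excitation")
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  # fixed pair order (by 'from' then 'to') keeps draws reproducible
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  keep <- with_seed(seed, runif(nrow(pairs)) < p)
  tibble::tibble(from = pairs$from[keep], to = pairs$to[keep], weight = w)
}

#' Assemble a reproducible network model
#'
#' Bundles a population, an edge list and the fixed single-neuron parameters
#' into the complete specification of one simulation.
#'
#' @param population Tibble from [build_population()].
#' @param edges Edge-list tibble from [build_connectivity()] (may have 0 rows
#'   for an uncoupled network).
#' @param params Fixed parameters, [hh_params()].
#' @param seeds Optional named list of the seeds used (kept for provenance).
#' @return An object of class `mmo_network`.
#' @export
network_model <- function(population, edges = NULL, params = hh_params(),
                          seeds = list()) {
  n <- nrow(population)
  if (is.null(edges)) edges <- tibble::tibble(from = integer(), to = integer(),
                                              weight = numeric())
  stopifnot(all(c("neuron_id", "e_l", "g_nap") %in% names(population)),
            all(c("from", "to", "weight") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$from != edges$to),
              all(edges$from >= 1), all(edges$to <= n), all(edges$weight >= 0))
  }
  structure(list(population = population, edges = edges, params = params,
                 seeds = seeds, n = n),
            class = "mmo_network")
}

#' Build a network in one call
#'
#' Convenience wrapper: population + connectivity + parameter bundle.
#'
#' @inheritParams build_population
#' @inheritParams build_connectivity
#' @param params Fixed parameters, [hh_params()].
#' @param seed_population,seed_topology Independent integer seeds.
#' @return An `mmo_network`.
#' @examples
#' net <- build_network(n = 100, w = 2.5, p = 0.15,
#'                      seed_population = 1, seed_topology = 2)
#' @export
build_network <- function(n = 100, p = 0.15, w = 2.5,
                          e_l_mean = -62, e_l_sd = 0.93,
                          g_nap_mean = 5, g_nap_sd = 0.5,
                          params = hh_params(),
                          seed_population = 1, seed_topology = 2) {
  pop <- build_population(n, e_l_mean, e_l_sd, g_nap_mean, g_nap_sd,
                          seed = seed_population)
  edges <- if (w > 0 && p > 0) build_connectivity(n, p, w, seed = seed_topology)
           else tibble::tibble(from = integer(), to = integer(), weight = numeric())
  network_model(pop, edges, params,
                seeds = list(population = seed_population, topology = seed_topology))
}

#' @export
print.mmo_network <- function(x, ...) {
  cat("<mmo_network> ", x$n, " neurons, ", nrow(x$edges), " directed edges",
      if (nrow(x$edges)) sprintf(" (w = %g, density %.3f)", x$edges$weight[1],
                                 nrow(x$edges) / (x$n * (x$n - 1))) else "",
      "\n", sep = "")
  cat("  e_l: mean ", round(mean(x$population$e_l), 2), " mV; g_nap: mean ",
      round(mean(x$population$g_nap), 2), " nS\n", sep = "")
  invisible(x)
}

#' Draw random initial conditions for a network
#'
#' Membrane potentials start uniformly in `[-70, -50]` mV and the slow
#' inactivation `h_nap` uniformly in `[0.2, 0.8]`; the fast gates start at
#' their steady state for the drawn voltage and the synaptic conductance at
#' zero.  The post-transient discard window makes results insensitive to
#' these ranges.
#'
#' @param network An `mmo_network`.
#' @param seed Integer seed for the initial-condition stream.
#' @param v_range,h_nap_range Sampling ranges.
#' @return A tibble with one row per neuron: `neuron_id`, `v`, `m_na`,
#'   `h_na`, `m_nap`, `h_nap`, `m_k`, `g_syn`.
#' @export
initial_conditions <- function(network, seed = 3,
                               v_range = c(-70, -50), h_nap_range = c(0.2, 0.8)) {
  n <- network$n
  g <- network$params$gates
  with_seed(seed, {
    v <- runif(n, v_range[1], v_range[2])
    h_nap <- runif(n, h_nap_range[1], h_nap_range[2])
    tibble::tibble(
      neuron_id = seq_len(n), v = v,
      m_na = steady_state(g$m_na, v), h_na = steady_state(g$h_na, v),
      m_nap = steady_state(g$m_nap, v), h_nap = h_nap,
      m_k = steady_state(g$m_k, v), g_syn = 0
    )
  })
}

#' Order neurons by excitability
#'
#' Returns the population with a `rank_e_l` column assigning ID 1 to the most
#' negative leak reversal potential, the "Neuron ID" convention used when
#' displaying rasters sorted from least to most excitable.
#'
#' @param population Population tibble.
#' @return The tibble sorted ascending in `e_l` with a `rank_e_l` column.
#' @export
sort_by_excitability <- function(population) {
  out <- dplyr::arrange(population, .data$e_l)
  out$rank_e_l <- seq_len(nrow(out))
  out
}

#' Persist / restore a realized network
#'
#' Writes the parameters and seeds as JSON and the edge list as CSV so a
#' realized network round-trips bit-exactly.
#'
#' @param network An `mmo_network`.
#' @param dir Output directory (created if needed).
#' @return `write_network()` the directory, invisibly; `read_network()` the
#'   restored `mmo_network`.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    n = network$n,
    params = network$params[setdiff(names(network$params), "gates")],
    seeds = network$seeds
  )
  jsonlite::write_json(meta, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(network$population, file.path(dir, "population.csv"))
  readr::write_csv(network$edges, file.path(dir, "edges.csv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "network.json"), simplifyVector = TRUE)
  pop <- readr::read_csv(file.path(dir, "population.csv"), show_col_types = FALSE)
  edges <- readr::read_csv(file.path(dir, "edges.csv"), show_col_types = FALSE,
                           col_types = "iid")
  params <- do.call(hh_params, meta$params)
  network_model(pop, edges, params, seeds = as.list(meta$seeds))
}
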