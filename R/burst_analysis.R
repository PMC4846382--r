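# Quantitative readouts of population activity: spike-count histograms,
# burst segmentation, large-amplitude (LA) vs small-amplitude (SA)
# classification, quantal 1:N regime summaries, per-neuron firing statistics,
# burst-participation clustering, and (w, p, g_NaP) sweep grids.
#
# Two LA definitions coexist deliberately: the main analyses classify a burst
# as LA when its peak exceeds 50 spikes per 10 ms bin, while the sweep/heat-map
# pipeline uses > 20 spikes in any 100 ms window; each pipeline applies its
# own rule.

#' Population spike-count histogram
#'
#' Counts spikes of all neurons in fixed-width time bins (10 ms by default).
#'
#' @param spikes Spike tibble (`neuron_id`, `time`) or an `mmo_sim`.
#' @param bin_width Bin width (ms), > 0.
#' @param t_start,t_end Analysis window; defaults to the spike range rounded
#'   out to whole bins (empty input gives a single empty bin at 0).
#' @return A tibble of class `mmo_hist` with `bin_start`, `bin_mid`, `count`,
#'   carrying `bin_width` as an attribute.
#' @export
population_histogram <- function(spikes, bin_width = 10,
                                 t_start = NULL, t_end = NULL) {
  stopifnot(bin_width > 0)
  if (inherits(spikes, "mmo_sim")) {
    if (is.null(t_start)) t_start <- spikes$config$discard
    if (is.null(t_end)) t_end <- spikes$config$duration
    spikes <- spikes$spikes
  }
  if (is.null(t_start)) t_start <- if (nrow(spikes)) floor(min(spikes$time) / bin_width) * bin_width else 0
  if (is.null(t_end)) t_end <- if (nrow(spikes)) max(spikes$time) else bin_width
  breaks <- seq(t_start, t_start + bin_width * ceiling((t_end - t_start) / bin_width),
                by = bin_width)
  if (length(breaks) < 2) breaks <- c(t_start, t_start + bin_width)
  keep <- spikes$time > breaks[1] & spikes$time <= breaks[length(breaks)]
  counts <- if (any(keep))
    as.integer(table(cut(spikes$time[keep], breaks = breaks, right = TRUE)))
  else integer(length(breaks) - 1)
  out <- tibble::tibble(bin_start = breaks[-length(breaks)],
                        bin_mid = breaks[-length(breaks)] + bin_width / 2,
                        count = counts)
  class(out) <- c("mmo_hist", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Segment population bursts from a histogram
#'
#' A burst is a maximal run of bins at or above `on_threshold`; runs whose
#' separating sub-threshold gap is shorter than `min_gap` are merged.  The
#' thresholds are analysis conveniences (the amplitude classification rule is
#' separate, see [classify_bursts()]) and are exposed in every pipeline.
#'
#' @param hist An `mmo_hist`.
#' @param on_threshold Minimum spikes/bin for a bin to be inside a burst.
#' @param min_gap Gaps shorter than this (ms) merge adjacent runs.
#' @return Burst tibble: `onset`, `offset` (ms), `peak` (spikes/bin),
#'   `class` (`NA` until classified).
#' @export
segment_bursts <- function(hist, on_threshold = 5, min_gap = 50) {
  stopifnot(on_threshold > 0, min_gap >= 0)
  bw <- attr(hist, "bin_width")
  on <- hist$count >= on_threshold
  if (!any(on)) {
    return(tibble::tibble(onset = numeric(), offset = numeric(),
                          peak = numeric(), class = character()))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by a sub-threshold stretch shorter than min_gap
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap_ms <- (runs$start[k] - merged$end[nrow(merged)] - 1) * bw
      if (gap_ms < min_gap) merged$end[nrow(merged)] <- runs$end[k]
      else merged <- rbind(merged, runs[k, ])
    }
  }
  tibble::tibble(
    onset = hist$bin_start[merged$start],
    offset = hist$bin_start[merged$end] + bw,
    peak = vapply(seq_len(nrow(merged)),
                  function(k) max(hist$count[merged$start[k]:merged$end[k]]),
                  numeric(1)),
    class = NA_character_
  )
}

#' Classify bursts as large- or small-amplitude
#'
#' Main-pipeline rule: a burst is LA when its peak strictly exceeds
#' `la_threshold` spikes per bin (default 50 per 10 ms bin); a peak exactly at
#' the threshold is SA.
#'
#' @param bursts Burst tibble from [segment_bursts()].
#' @param la_threshold LA classification threshold (spikes/bin).
#' @return The burst tibble with `class` set to `"LA"` or `"SA"`.
#' @export
classify_bursts <- function(bursts, la_threshold = 50) {
  bursts$class <- ifelse(bursts$peak > la_threshold, "LA", "SA")
  bursts
}

#' Classify bursts with the sweep (sliding-window) rule
#'
#' Heat-map/sweep rule: a burst is LA when the spike count in some 100 ms
#' window inside it exceeds `window_threshold` (default 20); remaining
#' bursting events are SA.
#'
#' @param bursts Burst tibble.
#' @param hist The `mmo_hist` the bursts were segmented from.
#' @param window Window length (ms).
#' @param window_threshold Spikes-per-window threshold.
#' @return The burst tibble with `class` and a `peak_window` column (max
#'   windowed count inside each burst).
#' @export
classify_bursts_windowed <- function(bursts, hist, window = 100,
                                     window_threshold = 20) {
  bw <- attr(hist, "bin_width")
  k <- max(1L, as.integer(round(window / bw)))
  roll <- as.numeric(stats::filter(hist$count, rep(1, k), sides = 1))
  roll[is.na(roll)] <- cumsum(hist$count[seq_len(min(k - 1, nrow(hist)))])
  win_end <- hist$bin_start + bw          # window ending at each bin's end
  pw <- vapply(seq_len(nrow(bursts)), function(i) {
    idx <- which(win_end > bursts$onset[i] & win_end <= bursts$offset[i] + window)
    if (!length(idx)) return(0)
    max(roll[idx], na.rm = TRUE)
  }, numeric(1))
  bursts$peak_window <- pw
  bursts$class <- ifelse(pw > window_threshold, "LA", "SA")
  bursts
}

modal_value <- function(x) {
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Summarise a burst sequence as a quantal regime
#'
#' Labels the mixed-mode pattern by the number of burst events per
#' large-amplitude period: `N` is the modal count of burst events from one LA
#' onset up to (excluding) the next, so an LA followed by three SA bursts per
#' cycle gives the `1:4` regime.  Inter-burst intervals (onset-to-onset) are
#' partitioned by the class of the preceding burst.
#'
#' @param bursts Classified burst tibble.
#' @param window Length of the analysed window (ms), used for the burst-rate
#'   columns; if `NULL`, the burst onset span is used.
#' @param min_consistent A regime is `stable` when at least this many
#'   consecutive LA-to-LA periods share the same event count.
#' @return One-row tibble: `n_la`, `n_sa`, `n_per_la` (modal events per LA
#'   period), `ratio_label`, `stable`, `la_freq_hz`, `sa_freq_hz`,
#'   `ibi_after_la`, `ibi_after_sa` (means, ms).
#' @export
regime_summary <- function(bursts, window = NULL, min_consistent = 5) {
  n_la <- sum(bursts$class == "LA")
  n_sa <- sum(bursts$class == "SA")
  span <- if (!is.null(window)) window
          else if (nrow(bursts) > 1) diff(range(bursts$onset)) else NA_real_
  ibi <- if (nrow(bursts) > 1) diff(bursts$onset) else numeric()
  prev_class <- if (nrow(bursts) > 1) bursts$class[-nrow(bursts)] else character()

  la_idx <- which(bursts$class == "LA")
  counts <- if (length(la_idx) > 1) diff(la_idx) else integer()
  n_per_la <- modal_value(counts)
  stable <- FALSE
  if (length(counts) >= min_consistent) {
    runs <- rle(counts)
    stable <- any(runs$lengths[runs$values == n_per_la] >= min_consistent)
  }
  label <- if (nrow(bursts) == 0) "silent"
           else if (n_la == 0) "SA-only"
           else if (nrow(bursts) == 1 || length(counts) == 0) "undefined"
           else if (!stable) sprintf("1:%d (irregular)", n_per_la)
           else sprintf("1:%d", n_per_la)

  tibble::tibble(
    n_la = n_la, n_sa = n_sa, n_per_la = n_per_la,
    ratio_label = label, stable = stable,
    la_freq_hz = if (!is.na(span) && span > 0) 1000 * n_la / span else NA_real_,
    sa_freq_hz = if (!is.na(span) && span > 0) 1000 * n_sa / span else NA_real_,
    ibi_after_la = if (any(prev_class == "LA")) mean(ibi[prev_class == "LA"]) else NA_real_,
    ibi_after_sa = if (any(prev_class == "SA")) mean(ibi[prev_class == "SA"]) else NA_real_
  )
}

#' Per-neuron firing-mode statistics
#'
#' Groups each neuron's spike train into bursts wherever an inter-spike
#' interval exceeds `isi_gap` (300 ms default, well between intra-burst
#' intervals of tens of ms and burst periods of seconds).  A neuron is
#' `silent` with no spikes, `tonic` when its whole train forms a single
#' gap-free group, and `bursting` otherwise.  Burst frequency is the rate of
#' burst onsets; intra-burst spike frequency is the inverse mean within-burst
#' inter-spike interval.
#'
#' @param spikes Spike tibble or `mmo_sim`.
#' @param population Population tibble (supplies `neuron_id` and `e_l`);
#'   taken from the `mmo_sim` if omitted.
#' @param isi_gap Gap (ms) starting a new burst.
#' @param window Analysed window length (ms) for rate normalisation.
#' @return Tibble per neuron: `neuron_id`, `e_l`, `mode`,
#'   `burst_freq_hz`, `intraburst_freq_hz`, `n_spikes`.
#' @export
neuron_burst_stats <- function(spikes, population = NULL, isi_gap = 300,
                               window = NULL) {
  if (inherits(spikes, "mmo_sim")) {
    if (is.null(population)) population <- spikes$network$population
    if (is.null(window)) window <- spikes$config$duration - spikes$config$discard
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(population))
  if (is.null(window) && nrow(spikes)) window <- diff(range(spikes$time))

  per <- lapply(population$neuron_id, function(id) {
    st <- sort(spikes$time[spikes$neuron_id == id])
    if (!length(st)) {
      return(tibble::tibble(mode = "silent", burst_freq_hz = 0,
                            intraburst_freq_hz = NA_real_, n_spikes = 0L))
    }
    isi <- diff(st)
    grp <- cumsum(c(1, as.integer(isi > isi_gap)))
    n_bursts <- max(grp)
    mode <- if (n_bursts == 1) "tonic" else "bursting"
    intra <- isi[isi <= isi_gap]
    tibble::tibble(
      mode = mode,
      burst_freq_hz = if (mode == "bursting") 1000 * n_bursts / window else NA_real_,
      intraburst_freq_hz = if (length(intra)) 1000 / mean(intra) else NA_real_,
      n_spikes = length(st)
    )
  })
  dplyr::bind_cols(population[, c("neuron_id", "e_l")], dplyr::bind_rows(per))
}

#' Neurons participating in each burst
#'
#' @param bursts Burst tibble.
#' @param spikes Spike tibble.
#' @return The burst tibble with a `participants` list-column of neuron ids
#'   spiking within `[onset, offset]`.
#' @export
burst_participants <- function(bursts, spikes) {
  bursts$participants <- lapply(seq_len(nrow(bursts)), function(k) {
    sort(unique(spikes$neuron_id[spikes$time >= bursts$onset[k] &
                                 spikes$time <= bursts$offset[k]]))
  })
  bursts
}

#' Cluster neurons by burst participation
#'
#' Neurons that spiked in exactly the same set of bursts share a cluster
#' (participation bit-vector identity).  Neurons active in every burst and
#' neurons active only in LA bursts form the two canonical clusters of a
#' mixed-mode rhythm.
#'
#' @param bursts Classified burst tibble.
#' @param spikes Spike tibble.
#' @param neuron_ids Ids to cluster (defaults to all ids present in `spikes`;
#'   pass the full population to include silent neurons).
#' @return Tibble `neuron_id`, `signature` (participation string), `cluster`
#'   (integer, 1 = most common signature).
#' @export
cluster_by_participation <- function(bursts, spikes,
                                     neuron_ids = sort(unique(spikes$neuron_id))) {
  sig <- vapply(neuron_ids, function(id) {
    st <- spikes$time[spikes$neuron_id == id]
    if (!nrow(bursts)) return("")
    paste(as.integer(vapply(seq_len(nrow(bursts)), function(k)
      any(st >= bursts$onset[k] & st <= bursts$offset[k]), logical(1))),
      collapse = "")
  }, character(1))
  tab <- sort(table(sig), decreasing = TRUE)
  tibble::tibble(neuron_id = neuron_ids, signature = sig,
                 cluster = as.integer(match(sig, names(tab))))
}

#' Sweep a parameter grid and summarise each cell's regime
#'
#' For each grid row a network is built, simulated for `duration` ms, and the
#' post-`discard` window is analysed with the sliding-window LA rule of the
#' heat-map pipeline ([classify_bursts_windowed()]).  The same seeds are used
#' in every cell so that only the swept parameters differ.
#'
#' @param grid Tibble/data frame with any of the columns `w`, `p`,
#'   `g_nap_mean` (missing columns take the defaults below).
#' @param n Population size.
#' @param w,p,g_nap_mean Defaults for parameters not present in `grid`.
#' @param g_nap_rel_sd The g_NaP SD is kept proportional to its mean
#'   (default 0.5/5 = 0.1) as the mean is swept.
#' @param duration,discard Per-cell simulation span (ms).
#' @param seeds Named list of the three stream seeds.
#' @param on_threshold,min_gap Segmentation settings.
#' @param window,window_threshold Sweep LA rule settings.
#' @return `grid` with the [regime_summary()] columns bound per row, plus
#'   `n_bursts` and `failed` (TRUE when a cell's simulation aborted).
#' @export
heatmap_sweep <- function(grid, n = 100, w = 2.5, p = 0.15, g_nap_mean = 5,
                          g_nap_rel_sd = 0.1,
                          duration = 50000, discard = 10000,
                          seeds = list(population = 1, topology = 2, init = 3),
                          on_threshold = 5, min_gap = 50,
                          window = 100, window_threshold = 20) {
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) return(dplyr::bind_cols(grid, regime_summary(
    tibble::tibble(onset = numeric(), offset = numeric(), peak = numeric(),
                   class = character()))[0, ]))
  cells <- lapply(seq_len(nrow(grid)), function(k) {
    wk <- if ("w" %in% names(grid)) grid$w[k] else w
    pk <- if ("p" %in% names(grid)) grid$p[k] else p
    gk <- if ("g_nap_mean" %in% names(grid)) grid$g_nap_mean[k] else g_nap_mean
    res <- tryCatch({
      net <- build_network(n = n, p = pk, w = wk,
                           g_nap_mean = gk, g_nap_sd = g_nap_rel_sd * gk,
                           seed_population = seeds$population,
                           seed_topology = seeds$topology)
      sim <- simulate_network(net, duration = duration, discard = discard,
                              seed_init = seeds$init)
      h <- population_histogram(sim)
      b <- segment_bursts(h, on_threshold = on_threshold, min_gap = min_gap)
      b <- classify_bursts_windowed(b, h, window = window,
                                    window_threshold = window_threshold)
      s <- regime_summary(b, window = duration - discard)
      s$n_bursts <- nrow(b)
      s$failed <- FALSE
      s
    }, error = function(e) {
      s <- regime_summary(tibble::tibble(onset = numeric(), offset = numeric(),
                                         peak = numeric(), class = character()))
      s$n_bursts <- NA_integer_
      s$failed <- TRUE
      s
    })
    res
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(cells))
}
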