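# Histograms, burst segmentation/classification, regime summaries,
# per-neuron statistics and participation clustering.

mk_hist <- function(counts, bw = 10) {
  h <- tibble::tibble(bin_start = seq(0, by = bw, length.out = length(counts)),
                      bin_mid = seq(bw / 2, by = bw, length.out = length(counts)),
                      count = as.integer(counts))
  class(h) <- c("mmo_hist", class(h))
  attr(h, "bin_width") <- bw
  h
}

test_that("population histogram bins and conserves spikes", {
  sp <- tibble::tibble(neuron_id = c(1L, 1L), time = c(5, 12))
  h <- population_histogram(sp, bin_width = 10, t_start = 0, t_end = 20)
  expect_equal(h$count, c(1L, 1L))
  empty <- population_histogram(tibble::tibble(neuron_id = integer(),
                                               time = numeric()),
                                t_start = 0, t_end = 50)
  expect_true(all(empty$count == 0))
  set.seed(1)
  sp <- tibble::tibble(neuron_id = sample(1:10, 500, TRUE),
                       time = runif(500, 0.01, 1000))
  h <- population_histogram(sp, bin_width = 10, t_start = 0, t_end = 1000)
  expect_equal(sum(h$count), 500)
})

test_that("burst segmentation finds runs and merges short gaps", {
  b <- segment_bursts(mk_hist(c(0, 0, 60, 70, 0, 0)), on_threshold = 5)
  expect_equal(nrow(b), 1)
  expect_equal(b$peak, 70)
  expect_equal(b$onset, 20)
  expect_equal(b$offset, 40)
  # two runs split by one sub-threshold bin merge when min_gap exceeds it
  h2 <- mk_hist(c(0, 60, 0, 60, 0))
  expect_equal(nrow(segment_bursts(h2, min_gap = 30)), 1)
  expect_equal(nrow(segment_bursts(h2, min_gap = 5)), 2)
  expect_equal(nrow(segment_bursts(mk_hist(rep(0, 12)))), 0)
})

test_that("segmentation matches a brute-force run enumeration oracle", {
  set.seed(99)
  for (rep in 1:30) {
    counts <- sample(0:12, 20, replace = TRUE)
    thr <- sample(3:8, 1)
    got <- segment_bursts(mk_hist(counts), on_threshold = thr, min_gap = 0)
    # oracle: enumerate maximal above-threshold runs directly
    on <- counts >= thr
    runs <- list()
    k <- 1
    while (k <= 20) {
      if (on[k]) {
        j <- k
        while (j < 20 && on[j + 1]) j <- j + 1
        runs[[length(runs) + 1]] <- c(k, j)
        k <- j + 1
      } else k <- k + 1
    }
    expect_equal(nrow(got), length(runs))
    for (i in seq_along(runs)) {
      expect_equal(got$onset[i], (runs[[i]][1] - 1) * 10)
      expect_equal(got$peak[i], max(counts[runs[[i]][1]:runs[[i]][2]]))
    }
  }
})

test_that("amplitude classification uses a strict threshold", {
  b <- tibble::tibble(onset = c(0, 1000, 2000), offset = c(200, 1200, 2200),
                      peak = c(70, 30, 50), class = NA_character_)
  out <- classify_bursts(b)
  expect_equal(out$class, c("LA", "SA", "SA"))  # exactly 50 is SA
})

test_that("sliding-window classification flags sustained but flat bursts", {
  # 30 spikes spread over 300 ms: peak/bin low but windowed count high
  h <- mk_hist(c(0, rep(3, 10), 0))
  b <- segment_bursts(h, on_threshold = 3)
  out <- classify_bursts_windowed(b, h, window = 100, window_threshold = 20)
  expect_equal(out$class, "LA")
  out2 <- classify_bursts_windowed(b, h, window = 100, window_threshold = 40)
  expect_equal(out2$class, "SA")
})

test_that("regime summary counts events per LA period and labels 1:N", {
  r <- regime_summary(synthetic_burst_cycle(n_sa = 3))
  expect_equal(r$n_per_la, 4)           # LA + 3 SA per cycle
  expect_equal(r$ratio_label, "1:4")
  expect_true(r$stable)
  all_la <- synthetic_burst_cycle(n_sa = 0, n_cycles = 8)
  expect_equal(regime_summary(all_la)$ratio_label, "1:1")
  one <- synthetic_burst_cycle(n_sa = 0, n_cycles = 1)
  expect_equal(regime_summary(one)$ratio_label, "undefined")
  none <- one[0, ]
  expect_equal(regime_summary(none)$ratio_label, "silent")
  sa_only <- synthetic_burst_cycle(n_sa = 2)
  sa_only$class <- "SA"
  expect_equal(regime_summary(sa_only)$ratio_label, "SA-only")
})

test_that("inter-burst intervals are partitioned by the preceding class", {
  b <- tibble::tibble(onset = c(0, 3000, 4000, 5000, 8000),
                      offset = c(200, 3200, 4200, 5200, 8200),
                      peak = c(80, 30, 30, 80, 30),
                      class = c("LA", "SA", "SA", "LA", "SA"))
  r <- regime_summary(b)
  expect_equal(r$ibi_after_la, mean(c(3000, 3000)))
  expect_equal(r$ibi_after_sa, mean(c(1000, 1000)))
})

test_that("per-neuron statistics separate silent, tonic and bursting trains", {
  pop <- tibble::tibble(neuron_id = 1:3, e_l = c(-63, -62, -60), g_nap = 5)
  sp <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 2L,
                   time = as.numeric(outer(seq(0, 90, by = 30),
                                           seq(0, 9000, by = 3000), "+"))),
    tibble::tibble(neuron_id = 3L, time = seq(0, 9900, by = 100))
  )
  st <- neuron_burst_stats(sp, pop, window = 10000)
  expect_equal(st$mode, c("silent", "bursting", "tonic"))
  expect_equal(st$burst_freq_hz[2], 1000 * 4 / 10000)   # 4 burst onsets in 10 s
  expect_equal(st$intraburst_freq_hz[2], 1000 / 30)
  expect_equal(st$n_spikes, c(0L, 16L, 100L))
})

test_that("participation clustering groups identical burst signatures", {
  bursts <- tibble::tibble(onset = c(0, 1000, 2000), offset = c(100, 1100, 2100),
                           peak = c(80, 30, 80), class = c("LA", "SA", "LA"))
  sp <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1L, time = c(50, 1050, 2050)),  # all bursts
    tibble::tibble(neuron_id = 2L, time = c(40, 1040, 2040)),  # all bursts
    tibble::tibble(neuron_id = 3L, time = c(60, 2060))         # LA bursts only
  )
  cl <- cluster_by_participation(bursts, sp)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[3] == cl$cluster[1])
  expect_equal(cl$signature[3], "101")
  # with no bursts every neuron shares the trivial cluster
  cl0 <- cluster_by_participation(bursts[0, ], sp)
  expect_true(all(cl0$cluster == 1L))
})

test_that("burst participants never double-count spikes", {
  sims <- uncoupled_sims(seeds = 1)
  sim <- sims[[1]]
  h <- population_histogram(sim)
  b <- burst_participants(classify_bursts(segment_bursts(h)), sim$spikes)
  in_burst <- sum(vapply(seq_len(nrow(b)), function(k)
    sum(sim$spikes$time >= b$onset[k] & sim$spikes$time <= b$offset[k]),
    numeric(1)))
  expect_lte(in_burst, nrow(sim$spikes))
})

test_that("a one-cell sweep returns a well-formed regime row", {
  res <- heatmap_sweep(tibble::tibble(w = 2, p = 0.2), n = 30,
                       duration = 8000, discard = 2000)
  expect_equal(nrow(res), 1)
  expect_false(res$failed)
  expect_true(all(c("n_la", "n_sa", "n_per_la", "ratio_label") %in% names(res)))
  empty <- heatmap_sweep(tibble::tibble(w = numeric(), p = numeric()))
  expect_equal(nrow(empty), 0)
})
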