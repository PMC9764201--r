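test_that("gating model validates rates and reports stationary Po", {
  m <- gating_model(25, 100, -1, 2)
  expect_equal(m$p_open, 0.2)
  expect_error(gating_model(0, 1, -1), "open_rate")
  expect_error(gating_model(1, 1, -1, 0), "n_channels")
})

test_that("silent and zero-amplitude models give flat sweeps", {
  m <- gating_model(1e-9, 1e4, -1, 1) # effectively never opens
  sw <- simulate_sweeps(m, 3, 0.5, noise_sd = 0.1, seed = 1)
  expect_lt(max(abs(sw$sweeps)), 1) # noise only, no unitary steps
  m0 <- gating_model(50, 50, 0, 1)
  sw0 <- simulate_sweeps(m0, 2, 0.5, noise_sd = 0.1, seed = 1)
  expect_lt(max(abs(sw0$sweeps)), 1)
})

test_that("long simulations are ergodic at the stationary Po", {
  m <- gating_model(125, 125, -1, 1) # Po = 0.5
  sw <- simulate_sweeps(m, 1, 60, noise_sd = 0, seed = 2)
  lv <- attr(sw, "true_levels")
  expect_equal(mean(lv), 0.5, tolerance = 0.03)
})

test_that("idealization reconstructs clean square pulses exactly", {
  fs <- 10000
  lv <- rep(0L, 2000)
  lv[501:900] <- 1L   # 40 ms opening
  lv[1201:1400] <- 2L # 20 ms double opening
  sw <- sweep_set(matrix(lv * -1.2, ncol = 1), fs, 2000)
  ev <- idealize_half_height(sw, -1.2, k_max = 3)[[1]]
  expect_equal(ev$level, c(0, 1, 0, 2, 0))
  expect_equal(ev$start_s, c(0, 500, 900, 1200, 1400) / fs)
  expect_equal(sum(ev$duration_s), 0.2) # events tile the sweep
  # all-closed trace: one level-0 event spanning the sweep
  ev0 <- idealize_half_height(sweep_set(matrix(0, 2000, 1), fs, 2000),
                              -1.2)[[1]]
  expect_equal(nrow(ev0), 1)
  expect_equal(ev0$level, 0)
  expect_equal(ev0$duration_s, 0.2)
})

test_that("idealization is invariant to polarity flip", {
  m <- gating_model(50, 150, -1, 2)
  sw <- simulate_sweeps(m, 4, 1, noise_sd = 0.15, seed = 3)
  ev_neg <- idealize_half_height(sw, -1)
  flipped <- sweep_set(-sw$sweeps, sw$sampling_rate, sw$filter_cutoff)
  ev_pos <- idealize_half_height(flipped, 1)
  expect_equal(lapply(ev_pos, as.list), lapply(ev_neg, as.list))
})

test_that("sub-risetime events are merged into their neighbours", {
  fs <- 10000
  lv <- rep(0L, 1000)
  lv[301] <- 1L # single-sample blip: below the 2 kHz risetime
  sw <- sweep_set(matrix(lv * -1, ncol = 1), fs, 2000)
  ev <- idealize_half_height(sw, -1)[[1]]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$level, 0)
})

test_that("channel count comes from resolved simultaneous openings", {
  ev1 <- structure(list(data.frame(level = c(0, 1, 0),
                                   start_s = c(0, 0.1, 0.3),
                                   duration_s = c(0.1, 0.2, 0.7))),
                   class = "event_list")
  expect_equal(estimate_channel_count(ev1), 1)
  ev3 <- structure(list(data.frame(level = c(0, 3, 0),
                                   start_s = c(0, 0.5, 0.52),
                                   duration_s = c(0.5, 0.02, 1.48))),
                   class = "event_list")
  expect_equal(estimate_channel_count(ev3), 3)
  # a threshold-grazing blip shorter than twice the risetime is not a
  # resolved opening and must not raise the count
  ev_blip <- structure(list(data.frame(level = c(1, 2, 1),
                                       start_s = c(0, 1, 1.0002),
                                       duration_s = c(1, 2e-4, 0.9998))),
                       class = "event_list", filter_cutoff = 2000)
  expect_equal(estimate_channel_count(ev_blip), 1)
  # simulated two-channel patch: count recovered with high probability
  m <- gating_model(125 * 0.3 / 0.7, 125, -1, 2)
  sw <- simulate_sweeps(m, 40, 2, noise_sd = 0.2, seed = 8)
  expect_equal(estimate_channel_count(idealize_half_height(sw, -1)), 2)
})

test_that("NPo integrates open levels over time and divides by k", {
  closed <- structure(list(data.frame(level = 0, start_s = 0,
                                      duration_s = 2)),
                      class = "event_list")
  expect_equal(open_probability(closed, 1)$po, 0)
  half <- structure(list(data.frame(level = c(1, 0), start_s = c(0, 1),
                                    duration_s = c(1, 1)),
                         data.frame(level = c(0, 1), start_s = c(0, 1),
                                    duration_s = c(1, 1))),
                    class = "event_list")
  expect_equal(open_probability(half, 1)$po, 0.5)
  expect_equal(open_probability(half, 2)$po, 0.25)
  expect_error(open_probability(half, 0), "k")
})

test_that("simulate-idealize-estimate recovers Po within 10%", {
  # spot checks of the full pipeline at moderate size (the full
  # 9-condition sweep runs in the acceptance suite)
  for (case in list(c(po = 0.2, k = 2, seed = 21),
                    c(po = 0.5, k = 1, seed = 22))) {
    m <- gating_model(125 * case["po"] / (1 - case["po"]), 125, -1,
                      case["k"])
    sw <- simulate_sweeps(m, 20, 2, noise_sd = 0.2, seed = case["seed"])
    ev <- idealize_half_height(sw, -1)
    k <- estimate_channel_count(ev)
    expect_lte(k, case[["k"]]) # never exceeds the generative count
    po <- open_probability(ev, k)$po
    expect_lt(abs(po - case[["po"]]) / case[["po"]], 0.1)
  }
})

test_that("mean ensemble average converges to k * Po * i", {
  m <- gating_model(125 * 0.4 / 0.6, 125, -1, 1)
  sw <- simulate_sweeps(m, 60, 1, noise_sd = 0.2, seed = 31)
  mea <- mean_ensemble_average(sw)
  expect_equal(mean(mea), -0.4, tolerance = 0.05)
  # identical sweeps average to themselves; antisymmetric sweeps cancel
  s2 <- sweep_set(cbind(c(1, -2, 3), c(1, -2, 3)), 10, 2)
  expect_equal(mean_ensemble_average(s2), c(1, -2, 3))
  s3 <- sweep_set(cbind(c(1, -2, 3), -c(1, -2, 3)), 10, 2)
  expect_equal(mean_ensemble_average(s3), c(0, 0, 0))
})

test_that("event lists export as tidy CSV", {
  m <- gating_model(50, 150, -1, 1)
  sw <- simulate_sweeps(m, 2, 0.5, noise_sd = 0.1, seed = 5)
  ev <- idealize_half_height(sw, -1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_list(ev, path)
  df <- utils::read.csv(path)
  expect_named(df, c("sweep", "level", "start_s", "dur_s"))
  expect_equal(sort(unique(df$sweep)), 1:2)
  expect_equal(sum(df$dur_s), 1, tolerance = 1e-9)
})
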