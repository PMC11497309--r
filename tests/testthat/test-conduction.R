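test_that("STTH binning follows the half-open 0.05 ms convention", {
  # empty target train: 320 zero bins
  h0 <- build_stth(c(0, 1, 2), numeric(0))
  expect_length(h0$counts, 320L)
  expect_true(all(h0$counts == 0L))
  expect_identical(h0$n_ref_spikes, 3L)

  # latency of exactly 1.00 ms falls in the bin with edges [1.00, 1.05) ms
  h1 <- build_stth(0, 0.001)
  expect_identical(sum(h1$counts), 1L)
  hit <- which(h1$counts == 1L)
  expect_equal(h1$bin_lower_ms[hit], 1.00)

  # latency 0 excluded, latency beyond the window excluded
  expect_true(all(build_stth(0.5, 0.5)$counts == 0L))
  expect_true(all(build_stth(0, 0.017)$counts == 0L))

  # latency exactly at the 16 ms window edge falls in the last bin
  h2 <- build_stth(0, 0.016)
  expect_identical(which(h2$counts == 1L), 320L)

  expect_error(build_stth(0, 0.001, window_s = 0.016, bin_s = 3e-5),
               "integer multiple")
})

test_that("STTH matches exhaustive pairwise enumeration", {
  # random train pairs
  for (s in 1:40) {
    set.seed(s)
    ref <- sort(runif(rpois(1, 40) + 1, 0, 2))
    tgt <- sort(c(runif(rpois(1, 40) + 1, 0, 2),
                  ref[1] + sample(0:320, 3) * 5e-5)) # edge-aligned latencies
    h <- build_stth(ref, tgt)
    expect_identical(h$counts, oracle_stth_counts(ref, tgt))
  }
  # crafted zero-latency and window-edge cases
  ref <- c(0.1, 0.2)
  tgt <- c(0.1, 0.1 + 0.016, 0.2 + 5e-5, 0.2 + 0.016)
  expect_identical(build_stth(ref, tgt)$counts,
                   oracle_stth_counts(ref, tgt))
})

test_that("latency peaks are located and tested against baseline", {
  mk <- function(counts, n_ref) {
    structure(list(counts = as.integer(counts),
                   bin_lower_ms = (0:(length(counts) - 1)) * 0.05,
                   n_ref_spikes = n_ref, window_s = length(counts) * 5e-5,
                   bin_s = 5e-5), class = "stth")
  }
  # flat non-zero histogram: peak equals baseline, not significant
  pk_flat <- find_latency_peak(mk(rep(4L, 320), 1000))
  expect_false(pk_flat$significant)

  # one towering bin over Poisson(1) background
  set.seed(12)
  cts <- rpois(320, 1); cts[101] <- 40L
  pk <- find_latency_peak(mk(cts, 100))
  expect_true(pk$significant)
  expect_equal(pk$t_peak_ms, 100 * 0.05)
  expect_gt(pk$peak_count, mean(cts) + 3 * sd(cts))  # brute-force criterion

  # all-zero histogram: no peak
  pk0 <- find_latency_peak(mk(rep(0L, 320), 100))
  expect_false(pk0$significant)
  expect_true(is.na(pk0$t_peak_ms))

  # too few reference spikes blocks significance
  expect_false(find_latency_peak(mk(cts, 10))$significant)

  # argmax ties resolve to the earliest bin
  tie <- rpois(320, 1); tie[50] <- 40L; tie[200] <- 40L
  expect_equal(find_latency_peak(mk(tie, 100))$t_peak_ms, 49 * 0.05)

  # a peak in the first bin (lower edge 0) cannot yield a speed
  z0 <- rpois(320, 1); z0[1] <- 40L
  expect_false(find_latency_peak(mk(z0, 100))$significant)
})

test_that("conduction speed is distance over lower bin edge", {
  g <- channel_geometry("c", c("a", "b"), c(0, 500))
  # 500 spikes with a 1.02 ms latency (mid-bin, away from the float-fragile
  # bin edge): d = 0.5 mm, t_peak = lower edge 1.0 ms
  ref <- seq(0, 49.9, by = 0.1)
  sp <- estimate_conduction_speed(g, list(a = ref, b = ref + 0.00102))
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$d_elec_mm, 0.5)
  expect_equal(sp$t_peak_ms, 1.0)
  expect_equal(sp$speed_m_s, 0.5)
  expect_true(sp$significant)
  # the lowest resolvable speed for the pair is d / 16 ms
  expect_equal(sp$speed_floor_m_s, 0.5 / 16)

  # a 2.4 mm pair peaking in the last bin gives the ~0.15 m/s floor
  g24 <- channel_geometry("c", c("a", "b"), c(0, 2400))
  sp24 <- estimate_conduction_speed(g24, list(a = ref, b = ref + 0.015975))
  expect_equal(sp24$t_peak_ms, 15.95)
  expect_equal(sp24$speed_m_s, 2.4 / 15.95)
  expect_equal(round(sp24$speed_m_s, 2), 0.15)
})

test_that("noise-free simulation recovers the speed within bin quantization", {
  run <- recovery_run(0.5, seed = 31, duration_s = 20, noise_free = TRUE)
  sp <- run$speeds
  expect_true(all(sp$significant))
  # 500 um at 0.5 m/s is a 1.0 ms delay on a bin edge: t_peak is 0.95 or
  # 1.00 ms for adjacent pairs
  adj <- sp[sp$d_elec_mm == 0.5, ]
  expect_true(all(adj$t_peak_ms %in% c(0.95, 1.00)))
  # every pair satisfies the analytic quantization envelope
  # d/(t_true + bin) <= v_hat <= d/(t_true - bin), to float precision
  t_true <- sp$d_elec_mm / 0.5
  expect_true(all(sp$speed_m_s >= sp$d_elec_mm / (t_true + 0.05) * (1 - 1e-12)))
  expect_true(all(sp$speed_m_s <= sp$d_elec_mm / (t_true - 0.05) * (1 + 1e-12)))
  # longer pairs recover more tightly (monotone envelope)
  rel_err <- abs(sp$speed_m_s - 0.5) / 0.5
  env <- 0.05 / (t_true - 0.05)
  expect_true(all(rel_err <= env + 1e-12))
})

test_that("reversed pairs on forward-propagating data show no peak", {
  run <- recovery_run(0.5, seed = 32, duration_s = 20)
  g_rev <- channel_geometry("rev", rev(run$geometry$electrode_ids),
                            run$geometry$positions_um)
  sp_rev <- estimate_conduction_speed(g_rev, run$trains)
  expect_false(any(sp_rev$significant))
  expect_identical(nrow(suppressMessages(channel_speed_summary(sp_rev))), 0L)
})

test_that("channel summary is the median over significant pairs", {
  df <- data.frame(channel_id = "c", ref_electrode = letters[1:4],
                   target_electrode = letters[2:5], d_elec_mm = 0.5,
                   t_peak_ms = 1, speed_m_s = c(0.4, 0.5, 0.6, 9),
                   peak_count = 10L, n_ref_spikes = 100L,
                   significant = c(TRUE, TRUE, TRUE, FALSE),
                   speed_floor_m_s = 0.03)
  s <- channel_speed_summary(df)
  expect_equal(s$speed_m_s, 0.5)
  expect_identical(s$n_significant, 3L)
})
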