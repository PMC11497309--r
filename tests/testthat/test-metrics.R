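test_that("mean firing rate aggregates per channel", {
  g <- channel_geometry("c1", c("a", "b"), c(0, 500))

  # no spikes anywhere: 0 Hz everywhere
  m0 <- mean_firing_rate(list(a = numeric(0), b = numeric(0)), g, 600)
  expect_identical(m0$channels$channel_rate_hz, 0)

  # 600 spikes in 600 s on one electrode: 1 Hz
  m1 <- mean_firing_rate(list(a = seq(0.5, 600, by = 1), b = numeric(0)),
                         g, 600)
  expect_equal(m1$electrodes$rate_hz, c(1, 0))
  expect_equal(m1$channels$channel_rate_hz, 0.5)   # mean over electrodes
  expect_equal(mean_firing_rate(list(a = seq(0.5, 600, 1), b = numeric(0)),
                                g, 600, aggregate = "sum")$channels$channel_rate_hz, 1)

  # unassigned electrodes are excluded with a warning
  expect_warning(mean_firing_rate(list(a = 1, zz = 1), g, 10),
                 "without channel assignment")

  # translation invariance and linear scaling in count
  tt <- sort(runif(120, 0, 600))
  r1 <- mean_firing_rate(list(a = tt, b = numeric(0)), g, 600)
  r2 <- mean_firing_rate(list(a = tt + 3, b = numeric(0)), g, 600)
  expect_identical(r1$channels$channel_rate_hz, r2$channels$channel_rate_hz)
})

test_that("simulated 5 Hz channel yields ~5 Hz detected rate", {
  run <- recovery_run(0.5, seed = 41, duration_s = 120)
  m <- mean_firing_rate(run$trains, run$geometry, 120)
  expect_gt(m$channels$channel_rate_hz, 4.5)
  expect_lt(m$channels$channel_rate_hz, 5.5)
  # detected counts track the ground-truth source count closely
  n_src <- length(generate_poisson_train(5, 120,
                                         seed = derive_seed(run$config$seed, 1)))
  expect_lt(abs(m$channels$channel_rate_hz - n_src / 120), 0.1)
})

test_that("Kruskal-Wallis H matches the hand-ranked oracle", {
  # identical multisets across groups: degenerate ties, H = 0, p = 1
  kw0 <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_identical(kw0$H, 0)
  expect_identical(kw0$p_value, 1)

  # ranks 1..6 split as {1,2,3} vs {4,5,6}:
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7 = 3.857
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-10)
  expect_equal(round(kw$H, 3), 3.857)

  # exchangeable groups give H near 0 / p near 1
  kw_same <- kruskal_wallis(list(c(1, 4, 2, 5), c(5, 1, 2, 4)))
  expect_gt(kw_same$p_value, 0.5)

  # invariance under strictly monotone transforms
  a <- c(0.3, 1.2, 4.5, 2.2); b <- c(0.9, 5.1, 3.3)
  h_raw <- kruskal_wallis(list(a, b))$H
  h_log <- kruskal_wallis(list(log(a), log(b)))$H
  h_cub <- kruskal_wallis(list(a^3, b^3))$H
  expect_equal(h_raw, h_log)
  expect_equal(h_raw, h_cub)

  expect_error(kruskal_wallis(list(1:3)), "groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("length summaries use linear-interpolation quartiles", {
  # single value per condition: median = q1 = q3 = the value
  t1 <- data.frame(condition = "w5", length_um = 123)
  s1 <- summarize_lengths(t1)
  expect_equal(unlist(s1[, c("median_um", "q1_um", "q3_um")]),
               c(median_um = 123, q1_um = 123, q3_um = 123))

  # odd n: {1..5} mm -> median 3, q1 2, q3 4
  t2 <- data.frame(condition = "w10", length_um = c(1, 2, 3, 4, 5) * 1000)
  s2 <- summarize_lengths(t2)
  expect_equal(s2$median_um, 3000)
  expect_equal(s2$q1_um, 2000)
  expect_equal(s2$q3_um, 4000)

  # permutation invariance within condition
  set.seed(2)
  x <- rlnorm(40, 6, 0.5)
  sa <- summarize_lengths(data.frame(condition = "c", length_um = x))
  sb <- summarize_lengths(data.frame(condition = "c", length_um = sample(x)))
  expect_identical(sa, sb)

  expect_error(summarize_lengths(data.frame()), "empty")
})

test_that("lognormal lengths are recovered within the bootstrap interval", {
  set.seed(8)
  meanlog <- log(800); sdlog <- 0.4
  x <- rlnorm(60, meanlog, sdlog)
  s <- summarize_lengths(data.frame(condition = "w", length_um = x))
  boot_med <- replicate(500, median(sample(x, replace = TRUE)))
  ci <- quantile(boot_med, c(0.025, 0.975))
  expect_gte(exp(meanlog), ci[1] * 0.999)  # generator truth inside the interval
  expect_lte(exp(meanlog), ci[2] * 1.001)
  expect_gte(s$median_um, ci[1])
  expect_lte(s$median_um, ci[2])
})

test_that("penetration fractions carry Wilson intervals", {
  tab <- data.frame(tunnel_width_nm = c(350, 600, 1000),
                    n_tunnels = c(10L, 100L, 100L),
                    n_passed = c(0L, 18L, 40L))
  pf <- penetration_fraction(tab)
  expect_equal(pf$fraction, c(0, 0.18, 0.40))
  # closed-form Wilson interval for 18/100, frozen independently:
  # centre (p + z^2/2n)/(1 + z^2/n) = 0.191838, half-width 0.074836
  expect_equal(pf$ci_low[2], 0.117002, tolerance = 1e-5)
  expect_equal(pf$ci_high[2], 0.266674, tolerance = 1e-5)
  # boundary: 0/10 has a lower bound of 0
  expect_equal(pf$ci_low[1], 0)
  # intervals lie in [0,1] and contain the point estimate
  expect_true(all(pf$ci_low >= 0 & pf$ci_high <= 1))
  expect_true(all(pf$ci_low <= pf$fraction & pf$fraction <= pf$ci_high))

  bad <- data.frame(tunnel_width_nm = 1, n_tunnels = 5L, n_passed = 7L)
  expect_error(penetration_fraction(bad), "n_passed")
})

test_that("bundled synthetic morphometry tables are analysable", {
  lengths <- read.csv(system.file("extdata", "synthetic_axon_lengths.csv",
                                  package = "axonmea"))
  s <- summarize_lengths(lengths)
  expect_true(all(c("condition", "n", "median_um", "q1_um", "q3_um")
                  %in% names(s)))
  expect_true(all(s$q1_um <= s$median_um & s$median_um <= s$q3_um))

  pen <- read.csv(system.file("extdata", "synthetic_tunnel_penetration.csv",
                              package = "axonmea"))
  pf <- penetration_fraction(pen)
  expect_true(all(pf$fraction >= 0 & pf$fraction <= 1))
})
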