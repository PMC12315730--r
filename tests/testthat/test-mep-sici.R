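test_that("MEP preprocessing matches its analytic frequency response", {
  bp <- design_bandpass(10, 450, 10000, 4)
  nt <- design_notch(50, 10000, 30)
  g50 <- filter_gain(bp, 50, 10000) * filter_gain(nt, 50, 10000)
  g100 <- filter_gain(bp, 100, 10000) * filter_gain(nt, 100, 10000)
  expect_lt(20 * log10(g50), -20)
  expect_gt(20 * log10(g100), -1)

  rec50 <- sine_rec(50, dur = 1, srate = 10000)
  seg <- preprocess_mep(rec50, stim_time = 0.5)
  expect_lt(steady_amp(seg$data[1, ]), 10^(-20 / 20))

  zero <- preprocess_mep(recording(rep(0, 10000), 10000), stim_time = 0.5)
  expect_true(all(zero$data == 0))
  expect_equal(n_samples(zero), 2500)   # -100..+150 ms at 10 kHz
  expect_error(preprocess_mep(recording(rnorm(500), 10000), stim_time = 0.01),
               "exceeds")
})

test_that("peak-to-peak follows its definition on constructed traces", {
  flat <- recording(rep(0, 2500), 10000, start_time = -0.1)
  expect_equal(peak_to_peak(flat), 0)
  spikes <- rep(0, 2500)
  spikes[1300] <- 700; spikes[1400] <- -700   # 30 and 40 ms post-stimulus
  rec <- recording(spikes, 10000, start_time = -0.1)
  expect_equal(peak_to_peak(rec), 1.4)        # 2a in mV
  expect_error(peak_to_peak(rec, search_window = c(0.2, 0.3)), "empty")
})

test_that("noise-free sweeps round-trip amplitude and SICI ratios exactly", {
  sweep <- generate_mep(mep_gen_config(ptp_true = 1.0))
  # oracle: max - min on the unfiltered generator output
  expect_equal(diff(range(sweep$data)) / 1000, 1.0, tolerance = 1e-12)
  seg <- preprocess_mep(sweep, stim_time = 0.1)
  # causal filtering distorts the waveform slightly; bound from the analytic
  # gain at the MEP frequency (80 Hz) of the 10-450 Hz chain
  g <- filter_gain(design_bandpass(10, 450, 10000, 4), 80, 10000) *
    filter_gain(design_notch(50, 10000, 30), 80, 10000)
  expect_lt(abs(peak_to_peak(seg) - 1.0), 2 * abs(1 - g) + 0.02)

  tab <- rbind(
    data.frame(protocol = "single", condition = "rest", ptp = 1.0),
    data.frame(protocol = "paired", condition = "rest", ptp = 0.5))
  sweeps <- generate_mep_set(tab, n_per_cell = 3, noise_sd = 0)
  res <- sici_from_sweeps(sweeps)
  # identical waveform shape scaled linearly: the ratio is exact
  expect_equal(res$sici$sici_percent, 50, tolerance = 1e-9)

  same <- sici(data.frame(protocol = c("single", "paired"),
                          condition = "rt50", mean_ptp = c(0.8, 0.8)))
  expect_equal(same$sici_percent, 100)
})

test_that("condition means and SICI report missing cells by name", {
  sweeps <- data.frame(protocol = c("single", "single"),
                       condition = c("rest", "rt50"), ptp = c(1, 1.2))
  m <- condition_means(sweeps)
  expect_equal(m$mean_ptp[m$condition == "rt50"], 1.2)
  req <- data.frame(protocol = "paired", condition = "rest")
  expect_error(condition_means(sweeps, required = req), "paired rest")
  expect_error(sici(m), "paired")
})

test_that("SICI is scale-equivariant: amplitudes scale, percentages do not", {
  tab <- rbind(
    data.frame(protocol = "single", condition = c("rest", "rt80"),
               ptp = c(1.0, 1.3)),
    data.frame(protocol = "paired", condition = c("rest", "rt80"),
               ptp = c(0.5, 0.9)))
  sw1 <- generate_mep_set(tab, n_per_cell = 2, noise_sd = 0, seed = 1)
  sw2 <- sw1
  sw2$rec <- lapply(sw1$rec, function(r) { r$data <- r$data * 3; r })
  r1 <- sici_from_sweeps(sw1)
  r2 <- sici_from_sweeps(sw2)
  # IEEE multiplication does not distribute exactly over the IIR recursion
  expect_equal(r2$means$mean_ptp, 3 * r1$means$mean_ptp, tolerance = 1e-6)
  expect_equal(r2$sici$sici_percent, r1$sici$sici_percent, tolerance = 1e-6)
})

test_that("pre/post SICI change scores are exact bookkeeping at zero noise", {
  make_tab <- function(sici_rest, sici_rt80) rbind(
    data.frame(protocol = "single", condition = c("rest", "rt80"),
               ptp = c(1.0, 1.3)),
    data.frame(protocol = "paired", condition = c("rest", "rt80"),
               ptp = c(1.0 * sici_rest / 100, 1.3 * sici_rt80 / 100)))
  get_sici <- function(tab) {
    res <- sici_from_sweeps(generate_mep_set(tab, n_per_cell = 2,
                                             noise_sd = 0))$sici
    setNames(res$sici_percent, res$condition)
  }
  pre <- get_sici(make_tab(50, 60))
  post <- get_sici(make_tab(50, 90))
  expect_equal(unname(post["rest"] - pre["rest"]), 0, tolerance = 1e-6)
  expect_equal(unname(post["rt80"] - pre["rt80"]), 30, tolerance = 1e-6)
})

test_that("SICI recovery stays within 5 points at 5% noise and 7 sweeps per cell", {
  tab <- rbind(
    data.frame(protocol = "single", condition = "rt80", ptp = 1.0),
    data.frame(protocol = "paired", condition = "rt80", ptp = 0.6))
  errs <- sapply(1:20, function(s) {
    sweeps <- generate_mep_set(tab, n_per_cell = 7, noise_sd = 0.05, seed = s)
    sici_from_sweeps(sweeps)$sici$sici_percent - 60
  })
  expect_lt(abs(mean(errs)), 5)
})
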