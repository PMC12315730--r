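test_that("recording and schedule containers enforce their invariants", {
  expect_error(recording(matrix(c(1, NA), 1), 100), "non-finite")
  expect_error(recording(matrix(1:4, 2), 100, labels = c("a", "a")), "unique")
  expect_error(recording(matrix(1:4, 2), -1, labels = c("a", "b")), "positive")

  sched <- trial_schedule(3, iti = 2)
  expect_equal(nrow(sched), 3)
  expect_equal(sched$ready_onset - sched$rest_onset, rep(6, 3))
  expect_equal(sched$imagery_onset - sched$ready_onset, rep(1, 3))
  expect_equal(sched$imagery_end - sched$imagery_onset, rep(5, 3))
  # trials must not overlap
  bad <- as.data.frame(sched)
  bad$rest_onset[2] <- bad$imagery_end[1] - 1
  expect_error(validate_schedule(bad), "overlap")
  # epoch-duration conservation: trial spans tile the block minus intervals
  expect_equal(schedule_duration(sched),
               3 * 12 + 2 * attr(sched, "iti"))
})

test_that("recording CSV round trip preserves data, rate and labels", {
  rec <- recording(matrix(rnorm(400), 4), 100,
                   labels = c("C3", "FC3", "C1", "CP3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$srate, rec$srate)
  expect_equal(back$data, rec$data, tolerance = 1e-8)
})

test_that("identical seeds give bit-identical generator output", {
  sched <- trial_schedule(2, iti = 0)
  a <- generate_eeg(eeg_gen_config(seed = 11), sched)
  b <- generate_eeg(eeg_gen_config(seed = 11), sched)
  expect_identical(a$data, b$data)
  e1 <- generate_emg_trial(emg_gen_config(rt_true = 0.2, seed = 5))
  e2 <- generate_emg_trial(emg_gen_config(rt_true = 0.2, seed = 5))
  expect_identical(e1$data, e2$data)
})

test_that("EEG generator attenuates imagery mu power by erd_depth", {
  # Welch-style PSD ratio on the raw target channel, depth 0.5 at 11 Hz
  sched <- trial_schedule(8, iti = 0)
  ratios <- sapply(1:6, function(s) {
    rec <- generate_eeg(eeg_gen_config(erd_depth = 0.5, mu_freq = 11,
                                       seed = s), sched)
    est <- sliding_psd(pick_channels(rec, "C3"), align = "center")
    rest <- windows_within(est, sched$rest_onset, sched$ready_onset)
    imag <- windows_within(est, sched$imagery_onset, sched$imagery_end)
    band <- est$freqs >= 10 & est$freqs <= 12
    mean(est$power[band, imag]) / mean(est$power[band, rest])
  })
  expect_true(all(abs(ratios - 0.5) < 0.1))
})

test_that("EEG generator with erd_depth 0 leaves rest and imagery mu power equal", {
  sched <- trial_schedule(6, iti = 0)
  pvals <- sapply(1:8, function(s) {
    rec <- generate_eeg(eeg_gen_config(erd_depth = 0, seed = s), sched)
    # non-overlapping windows so the two-sample test sees independent draws
    est <- sliding_psd(pick_channels(rec, "C3"), step = 1, align = "center")
    rest <- windows_within(est, sched$rest_onset, sched$ready_onset)
    imag <- windows_within(est, sched$imagery_onset, sched$imagery_end)
    band <- est$freqs >= 9 & est$freqs <= 12
    stats::t.test(log(colMeans(est$power[band, rest])),
                  log(colMeans(est$power[band, imag])))$p.value
  })
  # no-effect case: differences are sampling noise only
  expect_gt(sum(pvals > 0.01), 6)
})

test_that("degenerate EEG config yields flat white-noise spectra", {
  sched <- trial_schedule(2, iti = 0)
  cfg <- eeg_gen_config(mu_amp_rest = 0, line_noise_amp = 0,
                        common_mode_level = 0, noise_exponent = 0,
                        beta_coupling = 0, seed = 3)
  rec <- generate_eeg(cfg, sched)
  est <- sliding_psd(pick_channels(rec, "C3"), window_len = 1, step = 1)
  P <- rowMeans(est$power)
  lo <- mean(P[est$freqs >= 5 & est$freqs <= 20])
  hi <- mean(P[est$freqs >= 100 & est$freqs <= 115])
  expect_lt(abs(lo / hi - 1), 0.25)
})

test_that("EEG config validation rejects invalid depth and montage", {
  expect_error(eeg_gen_config(erd_depth = 1.2), "\\[0, 1\\]")
  expect_error(eeg_gen_config(neighbor_channels = c("a", "b")), "six")
  expect_error(eeg_gen_config(target_channel = "FC3"), "exclude")
})

test_that("EMG generator stores exact ground truth and respects flags", {
  cfg <- emg_gen_config(rt_true = 0.150, go_time = 1, seed = 2)
  trial <- generate_emg_trial(cfg)
  expect_identical(trial$meta$ground_truth$onset_true, 1 + 0.150)
  expect_false(trial$meta$ground_truth$pre_cue_burst)
  pre <- generate_emg_trial(emg_gen_config(rt_true = 0.15,
                                           pre_cue_burst = TRUE, seed = 2))
  expect_true(pre$meta$ground_truth$pre_cue_burst)
  expect_error(emg_gen_config(rt_true = -0.1), "non-negative")
  expect_error(generate_emg_trial(cfg, duration = 1.0), "duration")
})

test_that("EMG trace without a burst stays within baseline noise bounds", {
  cfg <- emg_gen_config(rt_true = 0.15, burst_amp = 0, baseline_sd = 10,
                        seed = 4)
  trial <- generate_emg_trial(cfg, duration = 2)
  expect_lt(max(abs(trial$data)), 6 * 10)
})

test_that("go-cue generator paces cues every 6 +/- 1 seconds", {
  gaps <- diff(draw_go_times(50, seed = 9))
  expect_true(all(gaps >= 5 & gaps <= 7))
})

test_that("noise-free MEP round-trips its configured peak-to-peak exactly", {
  sweep <- generate_mep(mep_gen_config(ptp_true = 1.0))
  expect_equal(diff(range(sweep$data)) / 1000, 1.0, tolerance = 1e-12)
  sweep2 <- generate_mep(mep_gen_config(ptp_true = 2.5))
  expect_equal(diff(range(sweep2$data)) / 1000, 2.5, tolerance = 1e-12)
  expect_error(mep_gen_config(ptp_true = 0), "positive")
})

test_that("noisy MEP peak-to-peak bias matches the extreme-value oracle", {
  # oracle: empirical bias of max - min under pure Gaussian noise in the
  # search window, computed brute force on noise-only traces
  set.seed(77)
  n_win <- length(seq(0.015, 0.060, by = 1e-4))
  noise_ptp <- replicate(200, {
    z <- rnorm(n_win, sd = 0.05)
    max(z) - min(z)
  })
  bias_bound <- mean(noise_ptp)          # upper bound on additive inflation
  set.seed(88)
  rec_ptp <- replicate(100, {
    sweep <- generate_mep(mep_gen_config(ptp_true = 1.0, noise_sd = 0.05))
    tt <- sample_times(sweep) - 0.1
    sel <- tt >= 0.015 & tt <= 0.060
    (max(sweep$data[sel]) - min(sweep$data[sel])) / 1000
  })
  expect_gte(mean(rec_ptp), 1.0)                 # extremes only inflate
  expect_lte(mean(rec_ptp), 1.0 + bias_bound)
})

test_that("cohort generator realizes the mixed model exactly at zero variance", {
  spec <- cohort_spec(n_per_group = 3,
                      baseline = c(rt = 0.2, sici = 50),
                      shift_real = c(rt = -0.01, sici = 30),
                      between_sd = 0, within_sd = 0, seed = 1)
  tab <- generate_cohort(spec)
  expect_equal(tab$rt[tab$group == "real" & tab$time == "pre"], rep(0.2, 3))
  expect_equal(tab$rt[tab$group == "real" & tab$time == "post"],
               rep(0.19, 3))
  expect_equal(tab$sici[tab$group == "sham" & tab$time == "post"],
               rep(50, 3))
  expect_error(cohort_spec(n_per_group = 1, baseline = c(rt = 1)),
               "at least 2")
})

test_that("latent cohort factors couple only the outcomes they load on", {
  spec <- cohort_spec(n_per_group = 200,
                      baseline = c(a = 0, b = 0, c = 0),
                      shift_real = c(a = 1, b = 1, c = 1),
                      between_sd = 0, within_sd = 1e-3,
                      latent = list(list(sd = 0.5, loads = c(a = 1, b = 1))),
                      seed = 42)
  tab <- generate_cohort(spec)
  pre <- tab[tab$time == "pre" & tab$group == "real", ]
  post <- tab[tab$time == "post" & tab$group == "real", ]
  d <- post[c("a", "b", "c")] - pre[c("a", "b", "c")]
  expect_gt(cor(d$a, d$b), 0.9)
  expect_lt(abs(cor(d$a, d$c)), 0.2)
})
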