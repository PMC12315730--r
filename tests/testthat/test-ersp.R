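test_that("epoch segmentation spans rest through imagery end + 1 s", {
  sched <- trial_schedule(3, iti = 2)
  rec <- recording(matrix(rnorm(2 * 45 * 100), 2), 100, c("C3", "x"))
  eps <- segment_epochs(rec, sched)
  expect_length(eps, 3)
  expect_equal(n_samples(eps[[1]]), 13 * 100)  # 6 + 1 + 5 + 1 s
  expect_equal(eps[[2]]$meta$epoch$imagery_onset, 7)
  # trial at the recording edge errors
  short <- recording(matrix(rnorm(2 * 1200), 2), 100, c("C3", "x"))
  expect_error(segment_epochs(short, sched), "exceeds")
})

test_that("bad-trial rejection drops exactly the epochs above threshold", {
  sched <- trial_schedule(3, iti = 0)
  set.seed(8)
  rec <- recording(matrix(rnorm(2 * 40 * 100, sd = 20), 2), 100, c("C3", "x"))
  eps <- segment_epochs(rec, sched)
  out <- reject_bad_trials(eps, 200)
  expect_equal(sum(out$log$rejected), 0)

  eps[[2]]$data[1, 50] <- 500   # injected blink-sized artifact
  out <- reject_bad_trials(eps, 200)
  expect_equal(out$log$trial[out$log$rejected], 2)
  expect_length(out$epochs, 2)

  expect_identical(reject_bad_trials(eps, Inf)$epochs, eps)
  eps_all_bad <- lapply(eps, function(e) { e$data[] <- 300; e })
  expect_error(reject_bad_trials(eps_all_bad, 200), "all 3 trials")
})

test_that("artifact hook is a pass-through when disabled and removes template components", {
  sched <- trial_schedule(2, iti = 0)
  set.seed(10)
  rec <- recording(matrix(rnorm(4 * 25 * 100), 4), 100,
                   c("C3", "a", "b", "c"))
  eps <- segment_epochs(rec, sched)
  expect_identical(artifact_removal_hook(eps)$epochs, eps)
  expect_error(artifact_removal_hook(eps, enabled = TRUE), "template")

  # mix a strong blink-like template into all channels
  n <- n_samples(eps[[1]])
  template <- exp(-((seq_len(n) - n / 2) / 40)^2)
  mixed <- lapply(eps, function(e) {
    e$data <- e$data + outer(c(8, 5, 4, 6), template)
    e
  })
  before <- max(abs(cor(t(mixed[[1]]$data), template)))
  cleaned <- artifact_removal_hook(mixed, enabled = TRUE,
                                   template = template)
  expect_true(all(cleaned$removed >= 1))
  after <- max(abs(cor(t(cleaned$epochs[[1]]$data), template)))
  expect_lt(after, 0.2 * before)

  # nothing correlates above threshold: SVD round trip is the identity
  intact <- artifact_removal_hook(eps, enabled = TRUE,
                                  template = template, r_thresh = 0.999)
  expect_equal(intact$epochs[[1]]$data, eps[[1]]$data, tolerance = 1e-6)
})

test_that("common average reference has the defining zero-mean property", {
  rec <- recording(matrix(rnorm(300), 3), 100, c("a", "b", "c"))
  ref <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(ref$data))), 1e-12)
  # identical channels cancel entirely
  same <- recording(matrix(rep(rnorm(100), 3), 3, byrow = TRUE), 100,
                    c("a", "b", "c"))
  expect_lt(max(abs(common_average_reference(same)$data)), 1e-12)
  # channel-constant offsets are invisible
  shifted <- rec; shifted$data <- shifted$data + 7
  expect_equal(common_average_reference(shifted)$data, ref$data)
  expect_error(common_average_reference(recording(rnorm(10), 10)),
               "at least 2")
})

test_that("ERSP is zero when imagery and rest spectra coincide", {
  # stationary oscillation, no attenuation, no noise -> ERSP identically 0
  fx <- quick_eeg(0, n_trials = 3, seed = 1, noise_level = 0,
                  common_mode_level = 0, line_noise_amp = 0)
  eps <- common_average_reference(segment_epochs(preprocess_offline(fx$rec),
                                                 fx$sched))
  er <- compute_ersp(eps, "C3", list(iaf = c(9, 12)))
  expect_lt(max(abs(er$trial_band$iaf)), 1e-3)
})

test_that("ERSP attenuation is specific to the modulated band", {
  fx <- quick_eeg(0.3, n_trials = 6, seed = 2, beta_coupling = 0)
  eps <- common_average_reference(segment_epochs(preprocess_offline(fx$rec),
                                                 fx$sched))
  er <- compute_ersp(eps, "C3", list(iaf = c(9, 12), high = c(30, 40)))
  expect_lt(abs(median(er$trial_band$iaf) + 30), 6)
  expect_lt(abs(median(er$trial_band$high)), 8)
})

test_that("ERSP maps carry the negative-is-desynchronization sign convention", {
  fx <- quick_eeg(0.6, n_trials = 4, seed = 3)
  eps <- common_average_reference(segment_epochs(preprocess_offline(fx$rec),
                                                 fx$sched))
  er <- compute_ersp(eps, "C3", list(iaf = c(9, 12)))
  m <- er$maps[[1]]
  sel <- m$freqs >= 9 & m$freqs <= 12
  imag <- m$times >= 8 & m$times <= 11    # epoch-relative imagery interior
  rest <- m$times >= 1 & m$times <= 5
  expect_lt(mean(m$values[sel, imag]), mean(m$values[sel, rest]))
  expect_error(compute_ersp(eps, "C3", list(bad = c(1, 10))), "3-40")
})

test_that("offline ERSP and online raw ERD agree in magnitude with opposite sign", {
  # noise-light narrowband fixture; filters differ between the chains, so the
  # agreement tolerance is a few percentage points
  fx <- quick_eeg(0.4, n_trials = 5, seed = 4, noise_level = 0.05,
                  common_mode_level = 0, line_noise_amp = 0)
  calib <- calibrate(fx$rec, fx$sched)
  online <- run_online_session(fx$rec, calib, fx$sched)
  offline <- offline_ersp_block(fx$rec, fx$sched, calib)
  expect_lt(abs(offline$summary$ersp_iaf + mean(online$trials$mean_raw_erd)),
            5)
})

test_that("median block summaries shrug off a single extreme trial", {
  fx <- quick_eeg(0.4, n_trials = 7, seed = 5)
  pre <- preprocess_offline(fx$rec)
  eps <- common_average_reference(segment_epochs(pre, fx$sched))
  er <- compute_ersp(eps, "C3", list(iaf = c(9, 12)))
  base <- median(er$trial_band$iaf)
  spiked <- er$trial_band$iaf
  spiked[3] <- 500
  expect_lt(abs(median(spiked) - base), 2)
})
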