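# Small fixtures shared across test files. Everything is generated in code.

# single-channel sinusoid recording
sine_rec <- function(freq, dur = 2, srate = 1000, amp = 1, phase = 0,
                     label = "sig") {
  tt <- (seq_len(round(dur * srate)) - 1) / srate
  recording(amp * sin(2 * pi * freq * tt + phase), srate, label)
}

# steady-state amplitude of a filtered sinusoid (skip the transient)
steady_amp <- function(x, skip_frac = 0.5) {
  n <- length(x)
  max(abs(x[seq(round(n * skip_frac), n)]))
}

# compact EEG block for chain tests: few trials, no inter-trial interval
quick_eeg <- function(depth, n_trials = 5, seed = 1, ...) {
  sched <- trial_schedule(n_trials, iti = 0)
  rec <- generate_eeg(eeg_gen_config(erd_depth = depth, seed = seed, ...),
                      sched)
  list(rec = rec, sched = sched)
}

# offline block ERSP at a fixed alpha band, bypassing calibration
quick_block_ersp <- function(rec, sched, band = c(9, 12)) {
  pre <- preprocess_offline(rec)
  kept <- reject_bad_trials(segment_epochs(pre, sched))
  ep <- common_average_reference(kept$epochs)
  median(compute_ersp(ep, "C3", list(iaf = band))$trial_band$iaf)
}
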