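---
title: "Methods: simulating and analysing SMR-ERD neurofeedback experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing SMR-ERD neurofeedback experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrloop)
```

## The problem this package addresses

Closed-loop sensorimotor-rhythm (SMR) neurofeedback trains participants to
attenuate the mu-band oscillation over sensorimotor cortex during motor
imagery. A typical study couples four measurement chains: (i) a real-time
EEG scoring loop that converts mu-band power into a 0–100% feedback score
every 100 ms; (ii) an offline time–frequency evaluation of event-related
spectral perturbation (ERSP); (iii) an EMG reaction-time (RT) task probing
behavioral consequences; and (iv) single- and paired-pulse TMS probing
corticospinal excitability (MEP) and short-interval intracortical inhibition
(SICI). Group claims then rest on mixed repeated-measures ANOVAs and on
correlations between change scores.

Human recordings from such studies are rarely public. `smrloop` therefore
pairs every analysis stage with a synthetic-data generator whose ground truth
is known exactly, so each stage — and the full chain — can be verified
quantitatively.

## The online scoring model

The feedback score is the event-related desynchronization

$$\mathrm{ERD}(t) = \frac{R - A(t)}{R} \times 100\,[\%],$$

where $A(t)$ is the mu-band power of the spatially filtered EEG in the last
second and $R$ the band power of the resting baseline. The chain is strictly
causal: a large Laplacian (centre electrode minus the mean of its six
neighbours), a 1–70 Hz fourth-order Butterworth band-pass plus a 50 Hz notch
applied single-pass with persistent state, a trailing 1-s Hanning-tapered FFT
recomputed every 100 ms (adjacent windows overlap 90%), and band-averaging
over the calibrated individual alpha frequency (IAF) band. Truncating the
input after time $t$ changes no output at or before $t$ minus one update
step; the test suite asserts this.

Design points the surrounding literature leaves open, decided here:

* **Clipping.** The displayed score is the raw ERD clipped to $[0, 100]$
  (a hand-image aperture cannot be negative); the raw value is kept for
  analysis.
* **"90% overlap" with a 100-ms update.** Read as one 1-s window per 100-ms
  step — adjacent windows overlap 90% — with no sub-window averaging.
* **Band scalars.** $A$ is the mean PSD across the band's 1-Hz bins; $R$
  likewise from the stored baseline spectrum (band-mean-then-ratio). The
  alternative (ratio per bin, then band mean) dilutes recovered ERD whenever
  the rhythm does not fill the whole band.
* **Notch design.** A second-order IIR notch with quality factor 30; the
  source protocol names no design.
* **Warm-up.** The first second of each session is excluded from scoring
  while the causal filter settles.
* **Trial score.** The mean of the scores of all windows lying wholly inside
  the imagery epoch.
* **Filter naming.** "Fourth-order Butterworth band-pass" follows the
  MATLAB/EEGLAB convention: the band transformation of an order-4 prototype
  (8 poles). Note that no fourth-order 3–40 Hz design attenuates a 45-Hz tone
  by 20 dB even after a zero-phase double pass — the analytic squared
  magnitude there is about −12 dB — so tests assert agreement with the
  analytic response rather than folklore attenuation figures.

## Calibration

From a no-feedback evaluation block, the baseline $R(f)$ is the
per-frequency **median** PSD over all complete resting-epoch windows.
The IAF band is the contiguous 3-Hz window inside 8–13 Hz with the most
pronounced mean ERD; on the 1-Hz grid the admissible candidates are the
integer-edged windows 8–11, 9–12 and 10–13, and ties resolve to the lowest
window. The "median of IAF" is read as the band centre, the only scalar
consistent with the "twice the median ± 2 Hz" construction of the individual
beta frequency (IBF). Calibration is deterministic: recomputing on the same
block reproduces identical output.

## Offline ERSP

Offline evaluation mirrors the published chain: 3–40 Hz fourth-order
zero-phase Butterworth plus 50 Hz notch, segmentation from rest onset to
imagery end + 1 s, amplitude-threshold bad-trial rejection (default 200 µV —
the original criteria are unreported, so the rule is explicit and
configurable), a pluggable artifact-removal hook, common average reference
(CAR), and a centre-aligned short-time Fourier transform with the same window
settings. ERSP$(t,f) = (A(t,f) - R(f))/R(f) \times 100$, negative =
desynchronization; the block outcome is the median over trials of the
imagery-epoch band value.

Three numerical choices deserve emphasis:

* **Imagery summary window 0.5–4.5 s after imagery onset.** A centre-aligned
  1-s window whose centre lies beyond imagery-end − 0.5 s straddles the
  post-imagery boundary; restricting centres to 0.5–4.5 s keeps every
  contributing window wholly inside the 5-s epoch.
* **Baseline statistic for band summaries.** The per-bin median $R(f)$ is
  kept for maps and the online formula, but the scalar band outcome divides
  by the median over rest windows of the *band-mean* power. The periodogram
  of a noise bin is exponentially distributed, and its per-bin median sits
  $\ln 2$ below its mean; dividing a mean-based $A$ by a per-bin-median $R$
  would fabricate ≈ +44% ERSP at bins that carry no rhythm. With the matched
  statistic the estimator is unbiased where nothing happens and unchanged
  where the rhythm dominates.
* **Artifact hook.** ICA internals are out of scope here; the hook's default
  decomposition is the SVD (principal components), removing components whose
  time courses correlate with a supplied artifact template at $|r| > 0.8$ and
  back-projecting. Any factorization with the same `(mixing, sources)`
  contract can be plugged in. Disabled (the default for synthetic data) it is
  a bit-identical pass-through.

## EMG reaction time

Onset detection implements the 4-SD rule: the threshold is four standard
deviations of the rectified, 10–500 Hz band-passed baseline (500 ms before
the Go cue); the onset is the first post-cue sample whose rectified envelope
(5-ms causal moving average) exceeds the threshold and stays above it for at
least 10 ms. The sustained-exceedance debounce and the envelope smoothing are
additions that make the rule well-posed for stochastic bursts — with raw
rectified samples, a burst modelled as high-variance noise crosses and
re-crosses any threshold — and both are configurable to zero to recover the
literal first-crossing rule. Detection can only lag a true crossing; across
seeds the lag is 1–4 ms, within the ±5 ms recovery budget. Anticipatory
(pre-cue) muscle activity is flagged with the same threshold computed on an
earlier reference segment, and flagged trials are excluded from the session
mean. Movement-preparation TMS probes are scheduled at 50% and 80% of the
baseline mean RT after the cue.

## MEP and SICI

Sweeps are band-passed 10–450 Hz (fourth-order, single-pass) with a 50 Hz
notch and segmented −100…+150 ms around the stimulus. Peak-to-peak amplitude
is max − min within a 15–60 ms post-stimulus search window (the canonical
forearm MEP latency range; the source protocol names none). SICI is the
paired-pulse mean expressed as a percentage of the single-pulse mean; lower
is stronger inhibition, and pre-to-post increases are inhibition release.
Participant-level exclusions (absent resting SICI) surface as QC flags, never
silent drops. Optional ±2 ms stimulus blanking is off by default since
synthetic sweeps carry no pulse artifact.

## The statistical layer

Mixed repeated-measures ANOVAs run through the multivariate linear model
(type-III, sum-to-zero contrasts) via `car::Anova`; Mauchly's test on every
within effect with ≥ 3 levels triggers the Greenhouse–Geisser correction at
p < 0.05 (the trigger threshold is unreported in the emulated protocol).
A baseline covariate (e.g. baseline MEP amplitude) enters as a
between-participant regressor. Post-hocs are Bonferroni-corrected pairwise
t-tests with Cohen's d. Partial correlations residualize both members of a
pair on the control set and use the t-transform with $n - 2 - k$ degrees of
freedom. FDR correction is Benjamini–Hochberg. The a-priori sample size is
the smallest $n$ whose two-tailed noncentral-t power reaches the target; the
paired design is the default because it is the family that reproduces the
published requirement of 24 participants at $d = 0.6$, $\alpha = 0.05$,
power 0.8. The type-I error of the Time × Group interaction is calibrated:
0.052 over 4000 null replicates at n = 11/group.

## What the synthetic data emulate — and what they do not

The EEG generator superimposes, per channel: an amplitude-modulated mu
oscillator with an independent random phase per trial (200-ms raised-cosine
crossfades between trials — hard phase jumps would inject broadband clicks no
physiological rhythm has), an optional beta harmonic at twice the mu
frequency sharing the imagery attenuation, spectrally shaped $1/f$ Gaussian
background noise (PSD 1 µV²/Hz at 10 Hz, a typical scalp background),
one shared common-mode component (exercising CAR and Laplacian cancellation),
and 50 Hz mains. During imagery the mu envelope is $\sqrt{1-d}$ of its rest
level, so imagery/rest band power equals $1-d$ in expectation; the envelope
ramps down linearly across the 1-s ready epoch and recovers over 0.5 s after
imagery. The default montage has 12 channels: the target, its six
neighbours (which receive the mu signal at 0.3 amplitude so the Laplacian is
focal but non-degenerate), and five mu-silent background channels. The
background channels matter: with only the seven mu-carrying electrodes, CAR
would subtract 40% of the target's mu amplitude — an artifact of a minimal
montage, absent from the dense whole-head nets such studies record with.
Per-trial amplitude jitter is exposed (`amp_jitter_sd`) but defaults to 0;
inter-trial rhythm variability is not quantified in the emulated literature,
and the parameter exists to probe estimator robustness rather than to assert
a value.

Not modelled: volume conduction and realistic topographies, artifact families
beyond a template blink and mains, TMS pulse artifacts in EEG, EMG amplitude
normalization, fatigue. Passing recovery tests on these data therefore
demonstrates correctness of the algorithms under the stated signal model,
not robustness to everything real recordings contain.

The EMG generator is Gaussian baseline noise whose standard deviation steps
(2-ms rise) to the burst level exactly at the true onset; burst-to-baseline
SD ratio is the SNR knob. The MEP generator is a damped 80 Hz oscillation
(away from the 50 Hz notch) starting 20 ms post-stimulus, rescaled so its
noise-free peak-to-peak equals the configured value exactly — making the
downstream quantification a round trip.

## The synthetic cohort

`run_synthetic_study()` is the package-level integration: it draws a
two-group cohort (11 per group, the emulated design), realizes raw EEG, EMG
and MEP data per participant and evaluation block, and runs every stage —
calibration on the pre block, online scoring with yoked-sham replay for the
sham group, offline ERSP, RT extraction, SICI quantification, and the group
statistics. Injected real-group effects: −20 ERSP points at IAF, −18 ms RT,
+30 SICI points at 80% pre-RT (all d > 1; sham gets none). Two latent
factors shape individual differences: a global responsiveness factor
(sd 0.4) scaling all effects, and a disinhibition-to-behavior factor
(sd 0.4) loading only on SICI and RT. The second factor is essential: with a
single shared factor every change score proxies the same latent variable,
and the partial correlation between SICI release and RT change *controlling
for the EEG outcome* provably tends to zero as coupling grows. The
two-pathway structure reproduces the negative SICI–RT partial correlation
such studies report while keeping ANOVA power high.

Problem sizes are chosen for routine re-verification on a single CPU: 6 EEG
trials per evaluation block, 10 RT trials, 7 MEP sweeps per
movement-preparation cell and 10 per resting protocol, 5% MEP noise. Across
20 cohort seeds, the Time × Group interaction is significant for ERSP in
20/20 and RT in 19/20 seeds, and the SICI–RT change partial correlation is
negative in 20/20 (values typically −0.2 to −0.7); these same checks run in
the test suite.

## Worked example

```{r example, eval = FALSE}
library(smrloop)

# one participant, one evaluation block
sched <- trial_schedule(10, iti = 0)
rec   <- generate_eeg(eeg_gen_config(erd_depth = 0.4, seed = 7), sched)
calib <- calibrate(rec, sched)
calib
#> <calibration_result> IAF 9-12 Hz (median 10.5), IBF 19-23 Hz, centre C3

ses <- run_online_session(rec, calib, sched)
mean(ses$trials$mean_raw_erd)     # ~ 40% injected depth

blk <- offline_ersp_block(rec, sched, calib)
blk$summary$ersp_iaf              # ~ -40, negative = desynchronization

# the full synthetic study
st <- run_synthetic_study(seed = 1)
st
```

## Known limitations

* The generator's montage is label-based, not geometric; topographic claims
  cannot be tested.
* The ERSP noise-floor offset is real: with the default signal-to-background
  ratio the measured block ERSP sits 1.5–2.5 points above $-100 d$ because
  the scoring band contains background power that does not desynchronize.
  The same dilution affects any real recording.
* The ANCOVA realization of a baseline covariate (between-participant
  regressor on the change model) is one of two natural parameterizations;
  conclusions sensitive to this choice should be checked both ways.
* `required_sample_size()` covers the t family (paired / one-sample /
  two-sample); F-family designs are out of scope.
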