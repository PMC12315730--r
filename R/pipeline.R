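#' Run a full synthetic neurofeedback study through every analysis stage
#'
#' Generates a two-group (real vs yoked-sham) pre/post cohort with known
#' participant-level ground truth, realizes raw signals for every participant
#' and evaluation block, and pushes them through the complete chain:
#' EEG generation, spectral calibration (pre block), online ERD scoring with
#' sham replay for the sham group, offline ERSP evaluation, EMG reaction-time
#' extraction, MEP/SICI quantification, and the group statistics (mixed
#' rmANOVA for ERSP and RT, partial correlation of change scores).
#'
#' Injected effects (real group, pre to post): stronger ERD at the individual
#' alpha band (-20 ERSP points), an 18 ms reaction-time shortening, and a
#' release of pre-movement short-interval intracortical inhibition at 80% of
#' pre-reaction time (+30 points); all standardized effects exceed d = 1. The
#' sham group receives no shift. A global responsiveness factor couples each
#' participant's effect magnitudes, and a second latent pathway links
#' inhibition release to behavioral change beyond what the EEG outcome
#' carries, so the change-score partial correlation between SICI release and
#' reaction time remains negative after controlling for the other outcomes.
#'
#' @param n_per_group participants per group (default 11).
#' @param trials_per_block EEG trials per evaluation block (default 6; the
#'   median block summary is stable at this count for the injected effect
#'   sizes, keeping cohort-scale simulation tractable).
#' @param emg_trials reaction-time trials per behavioral test (default 10).
#' @param mep_per_cell MEP sweeps per movement-preparation cell (default 7;
#'   the resting condition uses `rest_per_protocol`).
#' @param rest_per_protocol resting sweeps per protocol (default 10).
#' @param effect_scale multiplies every injected real-group shift (default 1;
#'   0 gives a null study).
#' @param seed integer seed or `NULL`.
#' @return A `synthetic_study`: list with `outcomes` (long table), `deltas`
#'   (per-participant change scores), `anova_ersp`, `anova_rt`, `partial`
#'   (change-score partial correlations), `online` (per-participant mean
#'   online scores, real group, plus sham replays), and `truth`.
#' @export
run_synthetic_study <- function(n_per_group = 11, trials_per_block = 6,
                                emg_trials = 10, mep_per_cell = 7,
                                rest_per_protocol = 10, effect_scale = 1,
                                seed = NULL) {
  use_seed(seed)
  spec <- cohort_spec(
    n_per_group = n_per_group,
    baseline = c(ersp_iaf = -30, rt = 0.200, mep_single = 1.0,
                 sici_rest = 50, sici_rt50 = 60, sici_rt80 = 55),
    shift_real = c(ersp_iaf = -20, rt = -0.018, sici_rt80 = 30,
                   sici_rt50 = 10) * effect_scale,
    between_sd = c(ersp_iaf = 6, rt = 0.015, mep_single = 0.2,
                   sici_rest = 8, sici_rt50 = 8, sici_rt80 = 8),
    within_sd = c(ersp_iaf = 4, rt = 0.003, mep_single = 0.05,
                  sici_rest = 5, sici_rt50 = 5, sici_rt80 = 5),
    responsiveness_sd = 0.4,
    latent = list(disinhibition = list(
      sd = 0.4, loads = c(sici_rt80 = 1, sici_rt50 = 0.5, rt = 1))),
    seed = NULL)
  truth <- generate_cohort(spec)

  sched <- trial_schedule(trials_per_block, iti = 0)
  cond_gain <- c(rest = 1, rt50 = 1.15, rt80 = 1.3)  # pre-movement facilitation
  participants <- unique(truth$participant)
  rows <- list(); calibs <- list(); online_real <- list()
  pre_recs <- list()

  for (p in participants) {
    for (tm in c("pre", "post")) {
      tru <- truth[truth$participant == p & truth$time == tm, ]
      depth <- min(max(-tru$ersp_iaf / 100, 0.05), 0.95)
      rec <- generate_eeg(eeg_gen_config(erd_depth = depth, seed = NULL),
                          sched)
      if (tm == "pre") {
        calibs[[p]] <- calibrate(rec, sched)
        pre_recs[[p]] <- rec
      }
      blk <- offline_ersp_block(rec, sched, calibs[[p]])

      rts <- do.call(rbind, lapply(seq_len(emg_trials), function(i) {
        rt_i <- max(tru$rt + stats::rnorm(1, 0, 0.015), 0.05)
        trial <- generate_emg_trial(emg_gen_config(rt_true = rt_i))
        rt_trial(trial, go_time = 1, trial = i)
      }))
      rt_meas <- session_rt(rts)$mean_rt

      single <- tru$mep_single * cond_gain
      sici_true <- c(rest = tru$sici_rest, rt50 = tru$sici_rt50,
                     rt80 = tru$sici_rt80)
      ptp_tab <- rbind(
        data.frame(protocol = "single", condition = names(cond_gain),
                   ptp = unname(single)),
        data.frame(protocol = "paired", condition = names(cond_gain),
                   ptp = unname(single * pmax(sici_true, 5) / 100)))
      prep <- ptp_tab[ptp_tab$condition != "rest", ]
      rest <- ptp_tab[ptp_tab$condition == "rest", ]
      sweeps <- rbind(
        generate_mep_set(rest, n_per_cell = rest_per_protocol,
                         noise_sd = 0.05),
        generate_mep_set(prep, n_per_cell = mep_per_cell, noise_sd = 0.05))
      sres <- sici_from_sweeps(sweeps)
      stab <- sres$sici

      rows[[paste(p, tm)]] <- data.frame(
        participant = p, group = as.character(tru$group), time = tm,
        ersp_iaf = blk$summary$ersp_iaf, ersp_ibf = blk$summary$ersp_ibf,
        rt = rt_meas,
        mep_single = sres$means$mean_ptp[sres$means$protocol == "single" &
                                           sres$means$condition == "rest"],
        sici_rest = stab$sici_percent[stab$condition == "rest"],
        sici_rt50 = stab$sici_percent[stab$condition == "rt50"],
        sici_rt80 = stab$sici_percent[stab$condition == "rt80"])
    }
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  outcomes$time <- factor(outcomes$time, levels = c("pre", "post"))
  outcomes$group <- factor(outcomes$group, levels = c("real", "sham"))

  # online scoring on pre blocks (real group); sham receives yoked replays
  real_ids <- participants[seq_len(n_per_group)]
  sham_ids <- participants[n_per_group + seq_len(n_per_group)]
  for (i in seq_len(n_per_group)) {
    ses <- run_online_session(pre_recs[[real_ids[i]]], calibs[[real_ids[i]]],
                              sched)
    online_real[[real_ids[i]]] <- ses
  }
  sham_feedback <- lapply(seq_len(n_per_group), function(i) {
    sham_replay(online_real[[real_ids[i]]], nrow(sched))
  })
  names(sham_feedback) <- sham_ids

  pre <- outcomes[outcomes$time == "pre", ]
  post <- outcomes[outcomes$time == "post", ]
  post <- post[match(pre$participant, post$participant), ]
  deltas <- data.frame(
    participant = pre$participant, group = pre$group,
    d_ersp_iaf = post$ersp_iaf - pre$ersp_iaf,
    d_rt = post$rt - pre$rt,
    d_mep_single = post$mep_single - pre$mep_single,
    d_sici_rt80 = post$sici_rt80 - pre$sici_rt80)

  anova_ersp <- mixed_rmanova(outcomes, "ersp_iaf", within = "time",
                              between = "group")
  anova_rt <- mixed_rmanova(outcomes, "rt", within = "time",
                            between = "group")
  partial <- partial_correlation(deltas,
                                 vars = c("d_sici_rt80", "d_rt",
                                          "d_ersp_iaf", "d_mep_single"))

  structure(list(outcomes = outcomes, deltas = deltas,
                 anova_ersp = anova_ersp, anova_rt = anova_rt,
                 partial = partial,
                 online = list(real = online_real, sham = sham_feedback),
                 calibrations = calibs, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  it <- function(a) a$table[a$table$effect == "group:time", ]
  e <- it(x$anova_ersp); r <- it(x$anova_rt)
  cat("<synthetic_study>\n")
  cat(sprintf("  ERSP Time x Group: F(%g, %g) = %.2f, p = %.4g\n",
              e$df1, e$df2, e$F, e$p))
  cat(sprintf("  RT   Time x Group: F(%g, %g) = %.2f, p = %.4g\n",
              r$df1, r$df2, r$F, r$p))
  cat(sprintf("  partial r(dSICI, dRT) = %.3f (p = %.4g)\n",
              x$partial$r["d_sici_rt80", "d_rt"],
              x$partial$p["d_sici_rt80", "d_rt"]))
  invisible(x)
}
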