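#' Specification of a synthetic two-group cohort
#'
#' Describes the participant-level generative model of a pre/post,
#' real-vs-sham neurofeedback study. Every outcome follows the mixed model
#'
#' \deqn{y_{it} = \mu + b_i + \Delta_{g(i)} g_i 1[t = post] + \varepsilon_{it}}
#'
#' with participant random intercept `b_i` (sd `between_sd`), residual
#' `eps` (sd `within_sd`), and a group-specific pre-to-post shift `Delta`.
#' `responsiveness_sd` adds a per-participant multiplicative factor `g_i`
#' (mean 1) shared across all outcomes, coupling individual training-response
#' magnitudes the way correlated physiological changes would be — without it,
#' between-outcome change-score correlations carry no participant-level
#' signal.
#'
#' @param n_per_group participants per group (default 11).
#' @param baseline named numeric vector of grand means, one per outcome.
#' @param shift_real named numeric vector of pre-to-post shifts for the real
#'   group (same names as `baseline`; missing names default to 0).
#' @param shift_sham like `shift_real`, for the sham group (default all 0).
#' @param between_sd named numeric (or single number recycled) of
#'   participant-intercept standard deviations.
#' @param within_sd named numeric (or single number) of residual standard
#'   deviations.
#' @param responsiveness_sd sd of the shared responsiveness factor
#'   (default 0: independent outcomes).
#' @param latent optional list of additional latent factors, each a list
#'   `list(sd = , loads = named numeric)`: factor value `f_i ~ N(0, sd)` per
#'   participant scales the shifts of the outcomes named in `loads` (weights),
#'   on top of the global responsiveness factor. Outcomes not named load 0.
#'   This expresses pathways shared by a subset of outcomes only — e.g. a
#'   disinhibition-to-behavior pathway linking inhibition release and
#'   reaction-time change beyond what the EEG outcome carries. Without such a
#'   pathway every change score proxies the same single factor and partial
#'   correlations between them, controlling for the others, vanish.
#' @param seed integer seed or `NULL`.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 11, baseline, shift_real = NULL,
                        shift_sham = NULL, between_sd = 1, within_sd = 1,
                        responsiveness_sd = 0, latent = NULL, seed = NULL) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (is.null(names(baseline)) || any(names(baseline) == ""))
    stop("`baseline` must be a fully named numeric vector")
  outs <- names(baseline)
  fill <- function(x) {
    v <- stats::setNames(rep(0, length(outs)), outs)
    if (!is.null(x)) v[names(x)] <- x
    v
  }
  expand_sd <- function(x, what) {
    v <- if (length(x) == 1L && is.null(names(x)))
      stats::setNames(rep(x, length(outs)), outs)
    else fill(x)
    if (any(v < 0)) stop("`", what, "` must be non-negative")
    v
  }
  if (!is.null(latent)) {
    for (fc in latent) {
      if (is.null(fc$sd) || fc$sd < 0 || is.null(names(fc$loads)))
        stop("each latent factor needs `sd` >= 0 and a named `loads` vector")
      if (!all(names(fc$loads) %in% outs))
        stop("latent loads name unknown outcome(s)")
    }
  }
  spec <- list(n_per_group = n_per_group, outcomes = outs,
               baseline = baseline, shift_real = fill(shift_real),
               shift_sham = fill(shift_sham),
               between_sd = expand_sd(between_sd, "between_sd"),
               within_sd = expand_sd(within_sd, "within_sd"),
               responsiveness_sd = responsiveness_sd, latent = latent,
               seed = seed)
  structure(spec, class = "cohort_spec")
}

#' Draw a synthetic cohort outcome table
#'
#' Realizes the mixed model of a [cohort_spec()]: one row per participant and
#' time point, one column per outcome, with the injected ground truth attached.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame (`participant`, `group`, `time`, outcomes...) with
#'   attribute `ground_truth` (the spec plus each participant's realized
#'   responsiveness factor and true shifts).
#' @export
#' @examples
#' spec <- cohort_spec(baseline = c(rt = 0.2), shift_real = c(rt = -0.01),
#'                     between_sd = 0.02, within_sd = 0.005, seed = 1)
#' head(generate_cohort(spec))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  use_seed(spec$seed)
  n <- spec$n_per_group
  ids <- sprintf("P%02d", seq_len(2 * n))
  group <- rep(c("real", "sham"), each = n)
  outs <- spec$outcomes
  # per-participant shift multiplier: 1 + global responsiveness + extra factors
  mult <- matrix(1 + stats::rnorm(2 * n, 0, spec$responsiveness_sd),
                 nrow = 2 * n, ncol = length(outs),
                 dimnames = list(NULL, outs))
  fac_draws <- list()
  if (!is.null(spec$latent)) {
    for (k in seq_along(spec$latent)) {
      fc <- spec$latent[[k]]
      f <- stats::rnorm(2 * n, 0, fc$sd)
      fac_draws[[k]] <- f
      for (o in names(fc$loads))
        mult[, o] <- mult[, o] + fc$loads[o] * f
    }
  }

  b <- sapply(outs, function(o) stats::rnorm(2 * n, 0, spec$between_sd[o]))
  b <- matrix(b, nrow = 2 * n, dimnames = list(NULL, outs))
  shift <- rbind(real = spec$shift_real, sham = spec$shift_sham)
  true_shift <- shift[group, , drop = FALSE] * mult

  make_rows <- function(time) {
    vals <- sapply(outs, function(o) {
      spec$baseline[o] + b[, o] +
        (if (time == "post") true_shift[, o] else 0) +
        stats::rnorm(2 * n, 0, spec$within_sd[o])
    })
    data.frame(participant = ids, group = group, time = time,
               matrix(vals, nrow = 2 * n, dimnames = list(NULL, outs)))
  }
  out <- rbind(make_rows("pre"), make_rows("post"))
  out$time <- factor(out$time, levels = c("pre", "post"))
  out$group <- factor(out$group, levels = c("real", "sham"))
  out <- out[order(out$participant, out$time), ]
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(spec = spec, shift_multiplier = mult,
                                    latent_draws = fac_draws,
                                    true_shift = true_shift)
  out
}
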