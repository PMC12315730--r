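#' Mixed-design repeated-measures ANOVA
#'
#' F-tests for all main effects and interactions of a design with one or more
#' within-participant factors and optionally one between-participant factor,
#' fitted through the multivariate linear model route (type-III sums of
#' squares, sum-to-zero contrasts). Sphericity of every within effect with
#' more than two levels is assessed by Mauchly's test; when Mauchly's p falls
#' below `sphericity_alpha` the Greenhouse–Geisser-corrected p-value is
#' reported for that effect. A baseline covariate can be entered as an
#' additional between-participant regressor.
#'
#' @param table long-format data.frame: one row per participant x within-cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-factor column names.
#' @param between name of the between-factor column, or `NULL`.
#' @param covariate name of a numeric per-participant covariate column, or
#'   `NULL`.
#' @param subject name of the participant-identifier column
#'   (default `"participant"`).
#' @param sphericity_alpha Mauchly threshold triggering the correction
#'   (default 0.05).
#' @return An `anova_result`: list with `table` (data.frame `effect`, `df1`,
#'   `df2`, `F`, `p_uncorrected`, `mauchly_p`, `gg_eps`, `gg_applied`, `p` —
#'   the reported p-value after any correction) and `model` (the underlying
#'   `Anova.mlm` summary).
#' @export
#' @examples
#' tab <- generate_cohort(cohort_spec(baseline = c(rt = 0.2), seed = 1))
#' res <- mixed_rmanova(tab, "rt", within = "time", between = "group")
#' res$table
mixed_rmanova <- function(table, dv, within, between = NULL,
                          covariate = NULL, subject = "participant",
                          sphericity_alpha = 0.05) {
  for (col in c(dv, within, between, covariate, subject))
    if (!col %in% names(table)) stop("column `", col, "` not found")
  lv <- lapply(within, function(w) levels(factor(table[[w]])))
  names(lv) <- within
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  subjects <- unique(as.character(table[[subject]]))
  Y <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(grid))
  key_tab <- do.call(paste, c(lapply(within, function(w)
    as.character(table[[w]])), sep = "\r"))
  key_grid <- do.call(paste, c(grid, sep = "\r"))
  sub_idx <- match(as.character(table[[subject]]), subjects)
  col_idx <- match(key_tab, key_grid)
  if (anyNA(col_idx)) stop("rows with within-factor levels outside the design")
  for (r in seq_len(nrow(table)))
    Y[sub_idx[r], col_idx[r]] <- table[[dv]][r]
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop("missing design cell: participant `", subjects[miss[1]],
         "`, cell `", gsub("\r", "/", key_grid[miss[2]]), "`")
  }

  bet <- data.frame(row.names = seq_along(subjects))
  rhs <- "1"
  contr <- list()
  first_of <- match(subjects, as.character(table[[subject]]))
  if (!is.null(between)) {
    bet[[between]] <- factor(table[[between]][first_of])
    rhs <- between
    contr[[between]] <- "contr.sum"
    if (nlevels(bet[[between]]) < 2)
      stop("between factor `", between, "` needs at least 2 levels")
  }
  if (!is.null(covariate)) {
    bet[[covariate]] <- as.numeric(table[[covariate]][first_of])
    rhs <- paste(rhs, "+", covariate)
  }
  idata <- grid
  for (w in within) idata[[w]] <- factor(idata[[w]], levels = lv[[w]])
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  mod <- stats::lm(stats::as.formula(paste("Y ~", rhs)),
                   data = cbind(bet, list(Y = Y)),
                   contrasts = if (length(contr)) contr else NULL)
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- summary(av, multivariate = FALSE)

  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  tab <- data.frame(effect = effects,
                    df1 = ut[effects, "num Df"],
                    df2 = ut[effects, "den Df"],
                    F = ut[effects, "F value"],
                    p_uncorrected = ut[effects, "Pr(>F)"],
                    mauchly_p = NA_real_, gg_eps = NA_real_,
                    gg_applied = FALSE, row.names = NULL)
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  if (!is.null(sph) && nrow(sph)) {
    hit <- match(rownames(sph), tab$effect)
    tab$mauchly_p[hit] <- sph[, "p-value"]
    tab$gg_eps[hit] <- adj[, "GG eps"]
    corr <- !is.na(tab$mauchly_p) & tab$mauchly_p < sphericity_alpha
    tab$gg_applied <- corr
    tab$p <- tab$p_uncorrected
    tab$p[corr] <- adj[match(tab$effect[corr], rownames(adj)), "Pr(>F[GG])"]
  } else {
    tab$p <- tab$p_uncorrected
  }
  structure(list(table = tab, model = s), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(format(x$table[c("effect", "df1", "df2", "F", "p", "gg_applied")],
               digits = 4), row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise post-hoc tests
#'
#' All pairwise t-tests between the levels of one factor (paired when the
#' factor varies within participants), with Bonferroni-adjusted p-values and
#' Cohen's d.
#'
#' @param table long-format data.frame.
#' @param dv dependent-variable column name.
#' @param factor_name column whose levels are compared.
#' @param paired paired comparisons (within-participant factor) or two-sample.
#' @param subject participant column, used to align paired observations.
#' @return data.frame `comparison`, `t`, `df`, `p`, `p_adj`, `d`.
#' @export
posthoc_pairwise <- function(table, dv, factor_name, paired = TRUE,
                             subject = "participant") {
  levs <- levels(factor(table[[factor_name]]))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- table[table[[factor_name]] == pr[1], ]
    b <- table[table[[factor_name]] == pr[2], ]
    if (paired) {
      ids <- intersect(a[[subject]], b[[subject]])
      x <- a[[dv]][match(ids, a[[subject]])]
      y <- b[[dv]][match(ids, b[[subject]])]
      tt <- stats::t.test(x, y, paired = TRUE)
      d <- cohens_d(x, y, paired = TRUE)
    } else {
      x <- a[[dv]]; y <- b[[dv]]
      tt <- stats::t.test(x, y, var.equal = TRUE)
      d <- cohens_d(x, y)
    }
    data.frame(comparison = paste(pr, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, d = d)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out[c("comparison", "t", "df", "p", "p_adj", "d")]
}

#' Cohen's d effect size
#'
#' Paired: mean difference divided by the SD of the differences. Independent:
#' mean difference divided by the pooled SD. One-sample (no `y`): mean over
#' SD.
#'
#' @param x,y numeric samples (`y` omitted for one-sample d).
#' @param paired treat `x`, `y` as paired (default `FALSE`).
#' @return The effect size d.
#' @export
#' @examples
#' cohens_d(rnorm(20, 1), rnorm(20, 0))
cohens_d <- function(x, y = NULL, paired = FALSE) {
  if (is.null(y)) {
    if (length(x) < 2) stop("need at least 2 observations")
    s <- stats::sd(x)
    if (s == 0) stop("zero variance: effect size undefined")
    return(mean(x) / s)
  }
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    return(cohens_d(x - y))
  }
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero variance: effect size undefined")
  (mean(x) - mean(y)) / sp
}

#' Partial correlations between variable pairs
#'
#' Partial Pearson correlation between each pair of `vars`, controlling for
#' `controls` (by default, the remaining variables in `vars`): both members of
#' a pair are residualized on the control set by least squares, the residuals
#' are correlated, and the p-value follows from the t-transform with
#' `n - 2 - k` degrees of freedom (`k` controls). With an empty control set
#' this reduces to the plain Pearson correlation.
#'
#' @param data data.frame of numeric variables (complete cases are used).
#' @param vars character vector of variable names to correlate pairwise.
#' @param controls character vector of control variables, or `NULL` to
#'   control each pair for the remaining `vars`.
#' @return List with matrices `r` and `p` (vars x vars), and `n` (complete
#'   cases).
#' @export
#' @examples
#' z <- rnorm(100); d <- data.frame(x = z + rnorm(100), y = z + rnorm(100), z)
#' partial_correlation(d, c("x", "y"), controls = "z")$r
partial_correlation <- function(data, vars, controls = NULL) {
  all_vars <- union(vars, controls)
  d <- data[stats::complete.cases(data[all_vars]), all_vars, drop = FALSE]
  n <- nrow(d)
  r <- p <- matrix(NA_real_, length(vars), length(vars),
                   dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    ctrl <- if (is.null(controls)) setdiff(vars, vars[c(i, j)]) else
      setdiff(controls, vars[c(i, j)])
    k <- length(ctrl)
    if (n < k + 3) stop("need at least controls + 3 complete cases")
    if (k == 0) {
      rr <- stats::cor(d[[vars[i]]], d[[vars[j]]])
    } else {
      X <- as.matrix(cbind(1, d[ctrl]))
      if (qr(X)$rank < ncol(X))
        stop("control set is collinear: ", paste(ctrl, collapse = ", "))
      rx <- stats::lm.fit(X, d[[vars[i]]])$residuals
      ry <- stats::lm.fit(X, d[[vars[j]]])$residuals
      rr <- stats::cor(rx, ry)
    }
    df <- n - 2 - k
    tt <- rr * sqrt(df / (1 - rr^2))
    r[i, j] <- r[j, i] <- rr
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = p, n = n)
}

#' Benjamini–Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; monotone by construction.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
fdr_correct <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Power of a two-tailed t-test under the noncentral t distribution
#'
#' @param n sample size (pairs, or per group for `"two.sample"`).
#' @param d standardized effect size.
#' @param alpha two-tailed type-I level (default 0.05).
#' @param design `"paired"` (= one-sample on differences), `"one.sample"`, or
#'   `"two.sample"`.
#' @return Power in `[0, 1]`.
#' @export
power_t <- function(n, d, alpha = 0.05,
                    design = c("paired", "one.sample", "two.sample")) {
  design <- match.arg(design)
  if (design == "two.sample") {
    df <- 2 * n - 2; ncp <- d * sqrt(n / 2)
  } else {
    df <- n - 1; ncp <- d * sqrt(n)
  }
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' A-priori sample size for a two-tailed t-test
#'
#' Smallest n whose power under the noncentral t distribution reaches
#' `power`. The default paired two-tailed design with d = 0.6, alpha = 0.05,
#' power = 0.8 requires 24 participants.
#'
#' @inheritParams power_t
#' @param power target power (default 0.8).
#' @param n_max search guard (default 1e5).
#' @return The required n (pairs, or per group for `"two.sample"`).
#' @export
#' @examples
#' required_sample_size(0.6)   # 24
required_sample_size <- function(d, alpha = 0.05, power = 0.8,
                                 design = c("paired", "one.sample",
                                            "two.sample"),
                                 n_max = 1e5) {
  design <- match.arg(design)
  if (d <= 0) stop("`d` must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie strictly in (0, 1)")
  for (n in 2:n_max) {
    if (power_t(n, d, alpha, design) >= power) return(n)
  }
  stop("target power unreachable within n_max = ", n_max)
}

#' Between-group standardized mean difference with confidence interval
#'
#' Cohen's d between two groups' change scores, with the large-sample
#' standard error and normal-approximation confidence interval used in
#' meta-analytic summaries.
#'
#' @param x,y change scores of the two groups.
#' @param conf confidence level (default 0.95).
#' @return List with `smd`, `se`, `ci` (length 2), `n` (c(n1, n2)).
#' @export
standardized_mean_difference <- function(x, y, conf = 0.95) {
  d <- cohens_d(x, y)
  n1 <- length(x); n2 <- length(y)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(smd = d, se = se, ci = c(d - z * se, d + z * se), n = c(n1, n2))
}
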