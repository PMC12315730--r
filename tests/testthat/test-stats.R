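test_that("a symmetric construction yields an exactly null interaction", {
  tab <- expand.grid(participant = sprintf("P%02d", 1:8),
                     time = c("pre", "post"))
  tab$group <- rep(rep(c("real", "sham"), each = 4), 2)
  base <- c(1, 2, 3, 4, 2, 3, 4, 5)
  # identical pre-to-post changes in both groups (nonzero within error):
  delta <- rep(c(0.5, -0.5, 1, -1), 2)
  tab$y <- base[match(tab$participant, unique(tab$participant))] +
    ifelse(tab$time == "post", delta[match(tab$participant,
                                           unique(tab$participant))], 0)
  res <- mixed_rmanova(tab, "y", within = "time", between = "group")
  it <- res$table[res$table$effect == "group:time", ]
  expect_equal(it$F, 0, tolerance = 1e-10)
})

test_that("a two-level within-only design reproduces the paired t-test", {
  set.seed(14)
  n <- 12
  tab <- data.frame(participant = rep(sprintf("P%02d", 1:n), each = 2),
                    time = rep(c("pre", "post"), n),
                    y = rnorm(2 * n))
  res <- mixed_rmanova(tab, "y", within = "time")
  pre <- tab$y[tab$time == "pre"]; post <- tab$y[tab$time == "post"]
  tt <- t.test(pre, post, paired = TRUE)
  Frow <- res$table[res$table$effect == "time", ]
  expect_equal(Frow$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(Frow$p, tt$p.value, tolerance = 1e-8)
})

test_that("three-factor mixed designs report sphericity information", {
  set.seed(15)
  tab <- expand.grid(participant = sprintf("P%02d", 1:10),
                     condition = c("rest", "rt50", "rt80"),
                     time = c("pre", "post"))
  tab$group <- ifelse(as.integer(sub("P", "", tab$participant)) <= 5,
                      "real", "sham")
  tab$y <- rnorm(nrow(tab))
  res <- mixed_rmanova(tab, "y", within = c("condition", "time"),
                       between = "group")
  expect_true("condition" %in% res$table$effect)
  expect_true("group:condition:time" %in% res$table$effect)
  cond <- res$table[res$table$effect == "condition", ]
  expect_false(is.na(cond$mauchly_p))   # 3 levels: Mauchly defined
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
})

test_that("a baseline covariate can enter the between-participant model", {
  set.seed(16)
  n <- 10
  tab <- expand.grid(participant = sprintf("P%02d", 1:(2 * n)),
                     time = c("pre", "post"))
  tab$group <- ifelse(as.integer(sub("P", "", tab$participant)) <= n,
                      "real", "sham")
  cov <- rnorm(2 * n)
  tab$baseline_mep <- cov[match(tab$participant, unique(tab$participant))]
  tab$y <- rnorm(nrow(tab)) + 0.8 * tab$baseline_mep
  res <- mixed_rmanova(tab, "y", within = "time", between = "group",
                       covariate = "baseline_mep")
  expect_true("baseline_mep" %in% res$table$effect)
})

test_that("mixed_rmanova names the missing design cell", {
  tab <- data.frame(participant = c("a", "a", "b"),
                    time = c("pre", "post", "pre"), y = 1:3)
  expect_error(mixed_rmanova(tab, "y", within = "time"), "missing design cell")
})

test_that("Cohen's d follows the paired and pooled definitions", {
  # means 0 vs 1, both sds 1: pooled d = -1
  expect_equal(cohens_d(c(-1, 0, 1), c(0, 1, 2)), -1)
  # paired: mean difference over sd of differences
  expect_equal(cohens_d(c(1, 2, 6), c(0, 2, 4), paired = TRUE),
               1 / sd(c(1, 0, 2)))
  set.seed(17)
  a <- rnorm(30, 1); b <- rnorm(30, 0)
  sp <- sqrt((29 * var(a) + 29 * var(b)) / 58)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(a, a), 0)
  # constant paired differences have undefined effect size
  expect_error(cohens_d(c(1, 2, 3), c(0, 1, 2), paired = TRUE),
               "zero variance")
})

test_that("partial correlation removes shared variance and reduces to Pearson", {
  set.seed(18)
  n <- 500
  z <- rnorm(n)
  d <- data.frame(x = z + rnorm(n), y = z + rnorm(n), z = z)
  pc <- partial_correlation(d, c("x", "y"), controls = "z")
  expect_lt(abs(pc$r["x", "y"]), 0.1)
  # marginally the two are clearly correlated
  plain <- partial_correlation(d, c("x", "y"), controls = character(0))
  expect_equal(plain$r["x", "y"], cor(d$x, d$y))
  expect_gt(plain$r["x", "y"], 0.3)
  # collinear controls are refused
  d$z2 <- d$z
  expect_error(partial_correlation(d, c("x", "y"), controls = c("z", "z2")),
               "collinear")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  bh_brute <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.3), 0.3)
  expect_equal(fdr_correct(c(1, 1)), c(1, 1))
  set.seed(20)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_correct(p), bh_brute(p))
  }
  expect_error(fdr_correct(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("sample-size search hits its guard limits sensibly", {
  expect_equal(required_sample_size(100), 2)      # huge effect: minimum n
  expect_error(required_sample_size(-1), "positive")
  expect_error(required_sample_size(0.6, alpha = 2), "strictly")
  # two-sample design needs more participants per group than paired pairs
  expect_gt(required_sample_size(0.6, design = "two.sample"),
            required_sample_size(0.6, design = "paired"))
})

test_that("standardized mean difference and its CI behave as the formula says", {
  expect_equal(standardized_mean_difference(c(1, 2, 3), c(1, 2, 3))$smd, 0)
  x <- c(5, 15, 10, 10); y <- c(-5, 5, 0, 0)
  d <- standardized_mean_difference(x, y)
  expect_equal(d$smd, cohens_d(x, y))
  # CI width shrinks roughly as 1/sqrt(n)
  se10 <- standardized_mean_difference(rep(c(0, 1), 5), rep(c(1, 2), 5))$se
  se40 <- standardized_mean_difference(rep(c(0, 1), 20), rep(c(1, 2), 20))$se
  expect_equal(se10 / se40, 2, tolerance = 0.15)
})

test_that("Bonferroni post-hocs find a constructed group difference", {
  set.seed(21)
  tab <- data.frame(participant = rep(sprintf("P%02d", 1:20), each = 3),
                    condition = rep(c("rest", "rt50", "rt80"), 20))
  tab$y <- rnorm(60) + ifelse(tab$condition == "rt80", 2, 0)
  ph <- posthoc_pairwise(tab, "y", "condition", paired = TRUE)
  expect_equal(nrow(ph), 3)
  hit <- ph[ph$comparison == "rest vs rt80", ]
  expect_lt(hit$p_adj, 0.01)
  expect_true(all(ph$p_adj >= ph$p))
})
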