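# Statistics layer: normality gate, gated comparisons, fold changes,
# ANOVA/Tukey, correlation grid with Holm flags, stratification.

test_that("omnibus normality statistic matches its frozen reference values", {
  # reference K^2 and p computed independently from the same draws with the
  # standard skewness/kurtosis transformation implementation
  set.seed(42); x <- round(rnorm(30, 10, 2), 6)
  r <- dagostino_pearson_test(x)
  expect_equal(r$statistic, 0.6151803225, tolerance = 1e-9)
  expect_equal(r$p.value, 0.7352165765, tolerance = 1e-9)
  r2 <- dagostino_pearson_test(x^3)
  expect_equal(r2$statistic, 3.1297434316, tolerance = 1e-9)
  expect_equal(r2$p.value, 0.2091148376, tolerance = 1e-9)
  expect_error(dagostino_pearson_test(rnorm(6)), "n >= 8")
})

test_that("gaussian gate passes normal data and rejects exponential data", {
  set.seed(1)
  expect_equal(as.character(gaussian_gate(rnorm(100))), "gaussian")
  rej <- 0L
  for (i in 1:100) {
    set.seed(i)
    rej <- rej + (gaussian_gate(rexp(50)) == "non_gaussian")
  }
  expect_gte(rej, 95L)
  expect_error(gaussian_gate(c(1, 2)), "n >= 3")
})

test_that("passing either normality test is enough for the gaussian label", {
  set.seed(5); x <- rt(25, df = 4)   # fails omnibus, passes Shapiro-Wilk
  expect_lt(dagostino_pearson_test(x)$p.value, 0.05)
  expect_gt(shapiro.test(x)$p.value, 0.05)
  expect_equal(as.character(gaussian_gate(x)), "gaussian")
  # below the omnibus minimum the decision rests on Shapiro-Wilk alone
  set.seed(2)
  expect_equal(as.character(gaussian_gate(rnorm(5))), "gaussian")
})

test_that("paired comparison: identity, constant shift, planted direction", {
  v <- c(10, 14, 9, 22, 31, 12, 8, 17, 25, 11)
  r <- paired_vessel_comparison(v, v)
  expect_equal(r$p_two_tailed, 1)
  expect_equal(r$statistic, 0)

  r <- paired_vessel_comparison(v + 5, v)
  expect_lt(r$p_two_tailed, 0.001)
  expect_equal(r$statistic, Inf)

  # noisy positive shift agrees with the closed-form paired t
  set.seed(8)
  a <- v + 5 + rnorm(10, 0, 2)
  r <- paired_vessel_comparison(a, v)
  d <- a - v
  t_cf <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$statistic, t_cf)
  expect_equal(r$p_two_tailed, 2 * pt(-abs(t_cf), 9))

  # planted peri-arteriolar excess is recovered in direction
  pos <- 0L
  for (i in 1:40) {
    co <- generate_cohort(seed = 300 + i)
    r <- paired_vessel_comparison(co$counts$periA_total, co$counts$periV_total)
    pos <- pos + (r$statistic > 0)
  }
  expect_gte(pos, 38L)
})

test_that("summary-statistics comparison reproduces a printed contrast", {
  r <- group_comparison_summary(19.78, 10.47, 9, 35.79, 13.18, 19)
  expect_equal(r$df, 26)
  expect_equal(round(r$p_two_tailed, 4), 0.0037)
  expect_equal(round(r$fold_change, 1), 1.8)
})

test_that("gated comparison routes to pooled t or Mann-Whitney correctly", {
  set.seed(21)
  x <- rnorm(15, 10, 2); y <- rnorm(20, 12, 2)
  # forced gaussian equals the closed-form pooled t
  r <- group_comparison(x, y, force_gate = "gaussian")
  sp <- sqrt((14 * var(x) + 19 * var(y)) / 33)
  t_cf <- (mean(y) - mean(x)) / (sp * sqrt(1 / 15 + 1 / 20))
  expect_equal(r$statistic, t_cf)
  expect_equal(r$p_two_tailed, 2 * pt(-abs(t_cf), 33))
  expect_equal(r$test_used, "unpaired_t")

  # forced non-gaussian: statistic equals the brute-force U (with ties)
  xi <- rpois(12, 6); yi <- rpois(14, 9)
  r <- group_comparison(xi, yi, force_gate = "non_gaussian")
  expect_equal(unname(r$statistic), oracle_U(yi, xi))
  expect_equal(r$test_used, "mann_whitney")

  # identical samples: p = 1 and FC = 1
  z <- c(4, 4, 5, 6, 7, 9)
  r <- group_comparison(z, z, force_gate = "gaussian")
  expect_equal(r$p_two_tailed, 1)
  expect_equal(r$fold_change, 1)

  # heavy-tailed data routes through the gate to Mann-Whitney
  set.seed(3)
  hx <- rexp(40)^2; hy <- rexp(40)^2 * 1.5
  r <- group_comparison(hx, hy)
  expect_equal(r$test_used, "mann_whitney")
  expect_equal(unname(r$statistic), oracle_U(hy, hx))
})

test_that("swapping group order flips t, preserves p, inverts FC", {
  set.seed(12)
  x <- rnorm(10, 8, 2); y <- rnorm(12, 11, 2)
  a <- group_comparison(x, y, force_gate = "gaussian")
  b <- group_comparison(y, x, force_gate = "gaussian")
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_two_tailed, b$p_two_tailed)
  expect_equal(a$fold_change, 1 / b$fold_change)
})

test_that("fold changes reproduce printed ratios and flag bad references", {
  expect_equal(round(fold_change(19.78, 10.47, 9, 35.79, 13.18, 19)$fc, 1), 1.8)
  expect_equal(round(fold_change(3.50, 3.13, 14, 10.46, 3.26, 13)$fc, 1), 3.0)
  expect_equal(fold_change(7, 1, 10, 7, 1, 10)$fc, 1.0)
  expect_warning(r <- fold_change(0, 1, 10, 5, 1, 10), "undefined")
  expect_true(r$unbounded)
  # Fieller interval contains the point estimate and is finite when the
  # reference mean is well separated from zero
  r <- fold_change(20, 4, 15, 30, 5, 15)
  expect_true(r$ci[1] < r$fc && r$fc < r$ci[2])
  expect_false(r$unbounded)
})

test_that("ANOVA with Tukey: null case, planted case, dominance, dropping", {
  g <- rep(c("a", "b", "c"), each = 10)
  v <- rep(1:10, 3)                       # identical groups
  r <- anova_tukey(v, g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_true(all(r$pairs$p_adj > 0.999))

  set.seed(17)
  v <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 5))
  r <- anova_tukey(v, g)
  expect_lt(r$pairs$p_adj[r$pairs$pair == "b-a"], 1)
  expect_gt(r$pairs$p_adj[r$pairs$pair == "b-a"], 0.05)
  expect_lt(r$pairs$p_adj[r$pairs$pair == "c-a"], 0.05)
  expect_lt(r$pairs$p_adj[r$pairs$pair == "c-b"], 0.05)

  # Tukey-adjusted p dominates the unadjusted pairwise p on the same data
  for (i in 1:10) {
    set.seed(400 + i)
    vv <- rnorm(30, rep(runif(3, 0, 2), each = 10))
    rr <- anova_tukey(vv, g)
    for (pr in seq_len(nrow(rr$pairs))) {
      lv <- strsplit(rr$pairs$pair[pr], "-")[[1]]
      expect_gte(rr$pairs$p_adj[pr] + 1e-12,
                 oracle_anova_pairwise_p(vv, g, lv))
    }
  }

  expect_warning(r <- anova_tukey(c(rnorm(5), rnorm(5), rnorm(5), 1),
                                  c(rep(c("a", "b", "c"), each = 5), "d")),
                 "n < 2")
  expect_error(anova_tukey(rnorm(10), rep(c("a", "b"), each = 5)),
               ">= 3 usable levels")
})

test_that("Holm step-down: worked example, superset of Bonferroni, oracle", {
  p <- c(0.001, 0.02, 0.03, 0.04)
  rej <- holm_bonferroni(p, 0.05)
  expect_equal(rej, c(TRUE, FALSE, FALSE, FALSE))   # thresholds 0.0125...
  expect_equal(rej, oracle_holm(p))
  set.seed(9)
  for (i in 1:50) {
    pp <- runif(sample(3:12, 1))^sample(1:3, 1)
    h <- holm_bonferroni(pp, 0.05)
    expect_equal(h, oracle_holm(pp))
    expect_equal(h, p.adjust(pp, "holm") <= 0.05)    # library cross-check
    bon <- pp <= 0.05 / length(pp)
    expect_true(all(h[bon]))                         # Holm superset
  }
})

test_that("correlation grid: exact linearity, planted rho, families, NA", {
  x <- 1:20
  counts <- data.frame(catA = x)
  clin <- data.frame(lin = 2 * x + 1)
  ct <- correlation_table(counts, clin)
  expect_equal(ct$r, 1)
  expect_lt(ct$p, 1e-12)

  # planted bivariate normal rho = -0.5 recovered within sampling bounds
  set.seed(66)
  z <- rnorm(200)
  y <- -0.5 * z + sqrt(1 - 0.25) * rnorm(200)
  ct <- correlation_table(data.frame(c1 = z), data.frame(v1 = y))
  expect_lt(abs(ct$r - (-0.5)), 0.12)

  # pairwise deletion and degenerate cells
  counts <- data.frame(a = c(1:8, NA, 10), b = rep(5, 10))
  clin <- data.frame(u = c(2 * (1:9), NA), w = c(rep(NA, 8), 1, 2))
  ct <- correlation_table(counts, clin)
  expect_equal(ct$n[ct$category == "a" & ct$clinical == "u"], 8)
  expect_equal(ct$note[ct$category == "b" & ct$clinical == "u"],
               "zero_variance")
  expect_equal(ct$note[ct$category == "a" & ct$clinical == "w"], "low_n")

  # column families correct flags independently per clinical variable
  set.seed(4)
  n <- 30
  cc <- data.frame(k1 = rnorm(n), k2 = rnorm(n), k3 = rnorm(n))
  cl <- data.frame(strong = cc$k1 * 2 + rnorm(n, 0, 0.1), pure = rnorm(n))
  ct <- correlation_table(cc, cl, family = "column")
  strong_rows <- ct[ct$clinical == "strong", ]
  expect_true(strong_rows$holm_significant[strong_rows$category == "k1"])
  ctg <- correlation_table(cc, cl, family = "global")
  expect_true(ctg$holm_significant[ctg$clinical == "strong" &
                                     ctg$category == "k1"])
})

test_that("cohort stratification matches the published grouping rules", {
  meta <- data.frame(MOCA = c(26, 27, 4, 32, NA),
                     CDR = c(0.5, 1, 2, NA, 1),
                     diagnosis = c("NC", "IC", "IC", "NC", NA))
  m <- stratify_cohort(meta, "moca")
  expect_equal(as.character(m[1]), "MOCA<=26")   # 26 falls in the lower group
  expect_equal(as.character(m[2]), "MOCA>26")
  expect_equal(attr(m, "n_excluded"), 1L)
  cdr_cohort <- data.frame(CDR = rep(c(0.5, 1, 2), c(11, 14, 3)))
  expect_equal(as.vector(table(stratify_cohort(cdr_cohort, "cdr"))),
               c(11, 14, 3))
  d <- stratify_cohort(meta, "diagnosis")
  expect_equal(levels(d), c("NC", "IC"))
  expect_error(stratify_cohort(meta, "bogus"))
})
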