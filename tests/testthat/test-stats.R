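# Independent oracles: aov() sums of squares, the Box/double-centring
# epsilon formula, exhaustive sign enumeration, and closed-form arithmetic.

test_that("one-way repeated-measures ANOVA matches a sums-of-squares oracle", {
  set.seed(11)
  d <- tidyr::expand_grid(s = factor(1:5), roi = factor(c("e", "u", "o")))
  d$y <- round(rnorm(nrow(d), 500, 80), 1)
  got <- rm_anova(d, subject = "s", value = "y", within = "roi")

  # Oracle 1: textbook sums of squares via cell means.
  Y <- matrix(d$y[order(d$s, d$roi)], nrow = 5, byrow = TRUE)
  grand <- mean(Y)
  ss_roi <- 5 * sum((colMeans(Y) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_roi - ss_subj
  F_oracle <- (ss_roi / 2) / (ss_err / 8)
  expect_equal(got$statistic, F_oracle, tolerance = 1e-8)

  # Oracle 2: epsilon by the double-centring (Box) formula.
  S <- stats::cov(Y)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps_oracle <- sum(diag(Sc))^2 / ((3 - 1) * sum(Sc^2))
  expect_equal(got$epsilon, eps_oracle, tolerance = 1e-8)
  expect_equal(got$df1, eps_oracle * 2, tolerance = 1e-8)
  expect_equal(got$p_value,
               pf(F_oracle, 2 * eps_oracle, 8 * eps_oracle,
                  lower.tail = FALSE), tolerance = 1e-8)

  # Effect sizes against their definitions.
  expect_equal(got$pes, ss_roi / (ss_roi + ss_err), tolerance = 1e-8)
  expect_equal(got$effect_size, ss_roi / (ss_roi + ss_subj + ss_err),
               tolerance = 1e-8)
})

test_that("two-way repeated-measures ANOVA matches aov stratum by stratum", {
  set.seed(12)
  d <- tidyr::expand_grid(s = factor(1:8), a = factor(c("x", "y")),
                          b = factor(c("1", "2", "3")))
  d$y <- rnorm(nrow(d))
  got <- rm_anova(d, subject = "s", value = "y", within = c("a", "b"))
  oracle <- summary(stats::aov(y ~ a * b + Error(s / (a * b)), data = d))
  f_of <- function(stratum) {
    tab <- oracle[[stratum]][[1]]
    tab$`F value`[1]
  }
  expect_equal(got$statistic[got$name == "a"], f_of("Error: s:a"),
               tolerance = 1e-8)
  expect_equal(got$statistic[got$name == "b"], f_of("Error: s:b"),
               tolerance = 1e-8)
  expect_equal(got$statistic[got$name == "a:b"], f_of("Error: s:a:b"),
               tolerance = 1e-8)
  # Two-level factor admits no sphericity correction.
  expect_equal(got$epsilon[got$name == "a"], 1)
  expect_true(all(got$epsilon >= 1 / 2 & got$epsilon <= 1))
})

test_that("degenerate ANOVA inputs are handled explicitly", {
  d <- tidyr::expand_grid(s = factor(1:6), w = factor(c("a", "b", "c")))
  d$y <- rep(rnorm(6), each = 3)    # identical across levels
  got <- rm_anova(d, "s", "y", "w")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  d2 <- d[-1, ]
  expect_error(rm_anova(d2, "s", "y", "w"), "balanced")
  d3 <- d
  d3$y[1] <- NA
  expect_error(rm_anova(d3, "s", "y", "w"), "missing")
})

test_that("paired t test matches closed-form arithmetic and flags zero variance", {
  x <- c(520, 480, 610, 545, 500, 570)
  y <- c(500, 470, 580, 540, 510, 560)
  got <- paired_tests(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(got$statistic, t_manual)
  expect_equal(got$effect_size, mean(d) / sd(d))
  expect_equal(got$p_value, t.test(x, y, paired = TRUE)$p.value)
  # Bonferroni multiplies and caps.
  got3 <- paired_tests(x, y, k_bonferroni = 3)
  expect_equal(got3$p_value, min(1, 3 * got$p_value))
  # Identical vectors: no effect, not an error.
  same <- paired_tests(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  # Constant nonzero differences: flagged.
  flag <- paired_tests(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_match(flag$correction, "degenerate")
  expect_true(is.na(flag$statistic))
})

test_that("wilcoxon signed-rank: closed forms, exhaustive enumeration, ties", {
  # n = 5, all positive, one-sided: V = 15, p = 1/32.
  got <- wilcoxon_signed_rank(c(0.3, 1.1, 0.7, 2.0, 0.5),
                              alternative = "greater")
  expect_equal(got$statistic, 15)
  expect_equal(got$p_value, 1 / 32)
  # Exact p equals brute-force enumeration over all 2^12 sign patterns.
  set.seed(13)
  x <- rnorm(12, 0.3)
  for (alt in c("two.sided", "greater", "less")) {
    got <- wilcoxon_signed_rank(x, alternative = alt)
    rk <- rank(abs(x))
    V <- sum(rk[x > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 12)))
    Vs <- drop(signs %*% rk)
    p_brute <- switch(alt,
      greater = mean(Vs >= V),
      less = mean(Vs <= V),
      two.sided = min(1, 2 * min(mean(Vs >= V), mean(Vs <= V))))
    expect_equal(got$p_value, p_brute)
    expect_equal(got$statistic, V)
  }
  # Near-symmetric signs: p close to 1.
  sym <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3, -0.5, 0.5))
  expect_gt(sym$p_value, 0.9)
  # Effect size agrees with |z|/sqrt(n).
  expect_true(got$effect_size >= 0 && got$effect_size <= 1)
  # All zero differences: flagged.
  expect_match(wilcoxon_signed_rank(rep(0, 6))$correction, "degenerate")
  # Ties fall back to the corrected normal approximation.
  tied <- wilcoxon_signed_rank(c(1, 1, 2, 2, 3, 3, -1, -2))
  expect_match(tied$correction, "normal_approx")
})

test_that("clustered goodness-of-fit test: null value, arithmetic, reduction", {
  # Every cluster exactly at pi: chi-square 0, p = 1.
  cl <- rep(1:6, each = 8)
  cat4 <- rep(rep(c("a", "b", "c", "d"), each = 2), 6)
  got0 <- clustered_gof(cl, cat4, pi0 = rep(0.25, 4),
                        levels = c("a", "b", "c", "d"))
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p_value, 1)
  expect_equal(got0$effect_size, 0)
  # Cramer's V definition arithmetic from the returned statistic.
  set.seed(14)
  cl2 <- rep(1:20, each = 30)
  cat2 <- sample(c("a", "b", "c", "d"), 600, replace = TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1))
  got <- clustered_gof(cl2, cat2, pi0 = rep(0.25, 4),
                       levels = c("a", "b", "c", "d"))
  expect_equal(got$effect_size, sqrt(got$statistic / (600 * 3)))
  expect_equal(got$df1, 3)
  # With two categories the quadratic form equals the squared proportion z.
  catb <- ifelse(cat2 == "a", "a", "b")
  gof2 <- clustered_gof(cl2, catb, pi0 = c(0.4, 0.6), levels = c("a", "b"))
  s_i <- tapply(catb == "a", cl2, sum)
  n_i <- tapply(catb, cl2, length)
  z <- clustered_prop_test(s_i, n_i, pi0 = 0.4)
  expect_equal(gof2$statistic, z$statistic^2, tolerance = 1e-10)
  expect_equal(gof2$p_value, z$p_value, tolerance = 1e-10)
})

test_that("clustered proportion test: nulls, arcsine bounds, classical reduction", {
  # All clusters at pi0.
  got0 <- clustered_prop_test(rep(5, 8), rep(10, 8), pi0 = 0.5)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p_value, 1)
  expect_equal(got0$effect_size, 0)
  # Cohen's h spans the arcsine range: p = 1 vs pi0 = 0 gives pi.
  got1 <- clustered_prop_test(c(10, 10), c(10, 10), pi0 = 0)
  expect_equal(got1$effect_size, pi)
  # Size-1 clusters reduce to the classical one-sample t test.
  set.seed(15)
  x <- rbinom(30, 1, 0.4)
  got <- clustered_prop_test(x, rep(1, 30), pi0 = 0.25)
  tt <- t.test(x, mu = 0.25)
  expect_equal(got$statistic, unname(tt$statistic), tolerance = 1e-6)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(c(got$ci_low, got$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-6)
  expect_error(clustered_prop_test(1, 2), "two clusters")
})

test_that("p values are uniform under matching nulls", {
  set.seed(16)
  # Wilcoxon under a symmetric null.
  p_w <- replicate(400, wilcoxon_signed_rank(rnorm(12))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(p_w, "punif")$p.value), 0.01)
  # Clustered proportion test under a beta-binomial null.
  p_c <- replicate(400, {
    p_i <- rbeta(34, 6, 6)
    clustered_prop_test(rbinom(34, 40, p_i), rep(40, 34), 0.5)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(p_c, "punif")$p.value), 0.01)
})
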