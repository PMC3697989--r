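test_that("normality screen accepts normal and rejects exponential samples", {
  set.seed(12)
  p_norm <- vapply(1:100, function(i)
    ks_normality(rnorm(500))$p_value, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- vapply(1:50, function(i)
    ks_normality(rexp(50))$p_value, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.8)
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  expect_error(ks_normality(rep(2, 10)), "constant")
})

test_that("one-way ANOVA matches the classical F and handles degeneracy", {
  # identical groups: F = 0
  same <- one_way_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$f, 0)
  set.seed(3)
  # strong separation
  v <- c(rnorm(8), rnorm(8), rnorm(8, 10))
  g <- rep(c("C", "F", "FT"), each = 8)
  strong <- one_way_anova(v, g)
  expect_lt(strong$p_value, 0.001)
  expect_equal(unname(strong$group_sem),
               unname(tapply(v, g, sd) / sqrt(8)))
  # oracle: reference implementation on random tables
  for (i in 1:20) {
    v <- rnorm(24, mean = sample(0:3, 1))
    a <- one_way_anova(v, g)
    ref <- anova(lm(v ~ g))
    expect_equal(a$f, ref$`F value`[1], tolerance = 1e-12)
    expect_equal(a$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")), ">= 2")
})

test_that("ANOVA F is invariant under affine transforms", {
  set.seed(4)
  v <- rnorm(24, rep(c(0, 1, 3), each = 8))
  g <- rep(c("C", "F", "FT"), each = 8)
  f1 <- one_way_anova(v, g)$f
  f2 <- one_way_anova(7 - 3.2 * v, g)$f
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("SNK flags exactly the separated group and respects step-down", {
  set.seed(5)
  g <- rep(c("C", "F", "FT"), each = 8)
  # identical groups: nothing significant
  same <- snk_posthoc(rep(1:8, 3) + rnorm(24, 0, 1e-8), g)
  expect_false(any(same$significant))
  v <- rnorm(24) + rep(c(0, 0, 10), each = 8)
  snk <- snk_posthoc(v, g)
  hit <- snk$significant
  involved <- snk$group1 == "FT" | snk$group2 == "FT"
  expect_true(all(hit[involved]))
  expect_false(any(hit[!involved]))
  # critical values grow with the span
  expect_true(all(diff(snk$q_crit[order(snk$span)]) >= 0))
  expect_true(attr(snk, "omnibus_significant"))
})

test_that("SNK critical value matches the studentized-range oracle", {
  q_pkg <- qtukey(0.95, 3, 21)
  q_oracle <- srange_quantile(0.95, 3, 21)
  expect_lt(abs(q_pkg - q_oracle), 0.01)
  # and the package uses exactly that quantile at span 3, df 21
  set.seed(6)
  v <- rnorm(24)
  g <- rep(c("C", "F", "FT"), each = 8)
  snk <- snk_posthoc(v, g)
  expect_equal(snk$q_crit[snk$span == 3], q_pkg)
})

test_that("repeated-measures ANOVA nests subjects and matches the paired t", {
  # one group, two times: F = t^2
  set.seed(8)
  before <- rnorm(8, 100, 5)
  after <- before - 4 + rnorm(8, 0, 2)
  d <- data.frame(subject = rep(1:8, 2), group = "F",
                  time = rep(c("before", "after"), each = 8),
                  value = c(before, after))
  rm1 <- repeated_measures(d)
  tt <- t.test(before, after, paired = TRUE)
  expect_equal(rm1$time$f, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(rm1$time$p_value, tt$p.value, tolerance = 1e-8)
  # zero mean change over time: F = 0 (balanced +/- perturbation keeps
  # the within-subject residual non-degenerate)
  d0 <- data.frame(subject = rep(1:8, 2), group = "F",
                   time = rep(c("before", "after"), each = 8),
                   value = c(before, before + rep(c(1, -1), 4)))
  expect_lt(repeated_measures(d0)$time$f, 1e-10)
})

test_that("a group-specific time shift produces an interaction", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    base <- rnorm(16, 100, 3)
    d <- data.frame(
      subject = rep(1:16, 2),
      group = rep(rep(c("C", "F"), each = 8), 2),
      time = rep(c("before", "after"), each = 16),
      value = c(base, base + rep(c(0, 15), each = 8) + rnorm(16, 0, 3)))
    repeated_measures(d)$group_time$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # missing pairs are dropped with a warning
  d <- data.frame(subject = rep(1:4, 2), group = "C",
                  time = rep(c("b", "a"), each = 4),
                  value = c(rnorm(7), NA))
  expect_warning(repeated_measures(d), "excluding")
})

test_that("Pearson correlation is symmetric, bounded and well calibrated", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(10)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson_cor(a, b)$r, pearson_cor(b, a)$r)
  r_null <- vapply(1:100, function(i)
    pearson_cor(rnorm(100), rnorm(100))$r, numeric(1))
  expect_gte(mean(abs(r_null) < 0.3), 0.95)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("an adiposity-fibrosis correlation of 0.89 is recovered at n = 24", {
  rho <- 0.89
  r_hat <- vapply(1:101, function(s) {
    set.seed(s)
    z <- rnorm(24)
    x <- 4 + 1.5 * z
    y <- 10 + 3 * (rho * z + sqrt(1 - rho^2) * rnorm(24))
    pearson_cor(x, y)$r
  }, numeric(1))
  expect_lt(abs(median(r_hat) - rho), 0.1)
})
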