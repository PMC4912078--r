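test_that("two-group balanced ANOVA F equals the squared pooled t statistic", {
  set.seed(71)
  d <- data.frame(g = rep(c("a", "b"), each = 8), y = rnorm(16))
  fa <- factorial_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(fa$table$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fa$table$df1[1], 1)
  expect_equal(fa$table$df2[1], 14)
})

test_that("factorial ANOVA matches a hand-worked sums-of-squares oracle", {
  set.seed(72)
  d <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"), rep = 1:3)
  d$y <- rnorm(nrow(d), mean = ifelse(d$a == "x", 0, 0.8))
  fa <- factorial_anova(d, "y", c("a", "b"))
  or <- oracle_two_way_anova(d$y, d$a, d$b)
  # balanced design: Type II equals the classical decomposition
  expect_equal(fa$table$F[fa$table$effect == "a"], or$F_a, tolerance = 1e-10)
  expect_equal(fa$table$F[fa$table$effect == "b"], or$F_b, tolerance = 1e-10)
  expect_equal(fa$table$F[fa$table$effect == "a:b"], or$F_ab, tolerance = 1e-10)
  expect_equal(fa$table$df2[1], or$df[4])
  # cell means carry n and a finite 95 percent CI
  expect_equal(sum(fa$cell_means$n), nrow(d))
  expect_true(all(fa$cell_means$lwr < fa$cell_means$mean))
  # Tukey table present for requested factors
  expect_true(!is.null(fa$tukey$a))
})

test_that("ANOVA flags degenerate designs", {
  d <- data.frame(a = rep(c("x", "y"), each = 4), y = rep(1.5, 8))
  fa <- factorial_anova(d, "y", "a")
  expect_true(is.na(fa$table$F[1]) || fa$table$F[1] == 0)
  d2 <- data.frame(a = rep("x", 5), y = rnorm(5))
  expect_error(factorial_anova(d2, "y", "a"), "2 observed levels")
  # structurally empty cell -> aliased interaction -> rejected
  d3 <- expand.grid(a = c("x", "y"), b = c("p", "q"), rep = 1:3)
  d3$y <- rnorm(nrow(d3))
  d3 <- d3[!(d3$a == "x" & d3$b == "q"), ]
  expect_error(factorial_anova(d3, "y", c("a", "b")), "rank-deficient")
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  set.seed(73)
  for (r in 1:5) {
    a <- rnorm(7 + r)
    b <- rnorm(9)
    mw <- mann_whitney(a, b)
    expect_equal(mw$U, oracle_u(a, b), tolerance = 1e-10)
  }
  # identical samples: U = n^2/2 and p in the null region
  x <- c(3, 1, 4, 1, 5)
  mw <- mann_whitney(x, x)
  expect_equal(mw$U, length(x)^2 / 2)
  expect_gt(mw$p, 0.9)
  # complete separation: U = 0 or na*nb
  expect_equal(mann_whitney(1:4, 11:15)$U, 0)
  expect_equal(mann_whitney(11:15, 1:4)$U, 20)
})

test_that("Kruskal-Wallis H reduces to the normalized U for two groups", {
  set.seed(74)
  a <- rnorm(9); b <- rnorm(12)
  kw <- kruskal_wallis_ranks(c(a, b), rep(c("a", "b"), c(9, 12)))
  u <- oracle_u(a, b)
  z2 <- (u - 9 * 12 / 2)^2 / (9 * 12 * (9 + 12 + 1) / 12)
  expect_equal(kw$H, z2, tolerance = 1e-10)
})

test_that("pairwise mean-rank comparisons flag only the shifted group", {
  set.seed(75)
  x <- c(rnorm(15), rnorm(15), rnorm(15, mean = 3))
  g <- rep(c("a", "b", "c"), each = 15)
  kw <- kruskal_wallis_ranks(x, g)
  expect_lt(kw$p, 0.01)
  pw <- kw$pairwise
  sig <- pw$p_adj < 0.05
  expect_true(all(sig[pw$group2 == "c" | pw$group1 == "c"]))
  expect_false(any(sig[pw$group1 == "a" & pw$group2 == "b"]))
  # fully tied data: H = 0, p = 1
  kw0 <- kruskal_wallis_ranks(rep(2, 12), rep(c("a", "b"), 6))
  expect_equal(kw0$p, 1)
  expect_equal(kw0$H, 0)
})

test_that("KS D matches the ECDF-scan oracle and ks.test", {
  set.seed(76)
  for (r in 1:5) {
    x <- rbinom(10, 5, 0.4)
    y <- rbinom(12, 5, 0.6)
    expect_equal(ks_statistic(x, y), oracle_ks_d(x, y), tolerance = 1e-12)
    expect_equal(ks_statistic(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(3, 3, 3)), 1)
})

test_that("the tinnitus KS battery compares groups and weeks with correction", {
  set.seed(77)
  counts <- expand.grid(animal = sprintf("A%02d", 1:20),
                        session = c("week1", "week3"))
  counts$group <- rep(c(rep("G", 11), rep("V", 9)), 2)
  counts$n_affected <- ifelse(counts$group == "V" | counts$session == "week1",
                              rbinom(nrow(counts), 3, 0.5), 0)
  cmp <- compare_tinnitus_distributions(counts)
  expect_s3_class(cmp, "distribution_comparison")
  # 2 between-group + 1 within-group per group
  expect_equal(sum(cmp$family == "between_group"), 2)
  expect_equal(sum(cmp$family == "within_G"), 1)
  expect_equal(sum(cmp$family == "within_V"), 1)
  expect_true(all(cmp$D >= 0 & cmp$D <= 1))
  expect_true(all(cmp$p_adj >= cmp$p))
  # identical distributions are never flagged
  same <- cmp[cmp$comparison == "V: week1 vs week3", ]
  expect_gt(same$p, 0.05)
  expect_error(compare_tinnitus_distributions(counts[0, ]), "comparison")
  # a group with < 2 animals is skipped with a warning
  small <- counts[!(counts$group == "V" & counts$animal != "A12"), ]
  w <- testthat::capture_warnings(cmp2 <- compare_tinnitus_distributions(small))
  expect_true(any(grepl("fewer than 2", w)))
  expect_true(all(cmp2$family == "within_G"))
})
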