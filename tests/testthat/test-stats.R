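test_that("exact Wilcoxon matches full enumeration, with and without ties", {
  t1 <- wilcoxon_rank_sum(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(t1$p.value, 1 / 3, tolerance = 1e-12)  # 2 * 1/6
  set.seed(14)
  for (i in 1:30) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE)  # deliberate ties
    y <- sample(1:5, n2, replace = TRUE)
    got <- wilcoxon_rank_sum(x, y, exact = TRUE)$p.value
    expect_equal(got, enumerate_wilcoxon_p(x, y), tolerance = 1e-12)
  }
  # independent cross-check against the base-R exact test (tie-free data)
  for (i in 1:20) {
    x <- rnorm(4)
    y <- rnorm(5)
    expect_equal(wilcoxon_rank_sum(x, y, exact = TRUE)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("identical samples give a null statistic and p = 1", {
  t0 <- wilcoxon_rank_sum(c(2, 2, 5), c(5, 2, 2), exact = TRUE)
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)
})

test_that("exact enumeration beyond the cap is refused with advice", {
  expect_error(wilcoxon_rank_sum(rnorm(15), rnorm(15), exact = TRUE),
               "exact = FALSE")
})

test_that("exact and asymptotic p agree for moderate samples", {
  set.seed(9)
  diffs <- replicate(50, {
    x <- rnorm(10)
    y <- rnorm(10, 0.4)
    abs(wilcoxon_rank_sum(x, y, exact = TRUE)$p.value -
          wilcoxon_rank_sum(x, y, exact = FALSE)$p.value)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("van Elteren reduces to the Wilcoxon statistic for one stratum", {
  set.seed(4)
  x <- rnorm(5)
  y <- rnorm(6, 0.8)
  ve <- van_elteren(c(x, y), rep(c("A", "B"), c(5, 6)), rep(1, 11))
  wz <- wilcoxon_rank_sum(x, y, exact = FALSE)
  expect_equal(unname(ve$statistic), unname(wz$statistic), tolerance = 1e-12)
  # p from the uncorrected standardized statistic
  expect_equal(ve$p.value, 2 * pnorm(-abs(unname(wz$statistic))),
               tolerance = 1e-12)
})

test_that("van Elteren is antisymmetric in the group labels", {
  set.seed(6)
  v <- rnorm(16)
  g <- rep(rep(c("A", "B"), each = 2), 4)
  s <- rep(1:4, each = 4)
  t1 <- van_elteren(v, g, s)
  t2 <- van_elteren(v, ifelse(g == "A", "B", "A"), s)
  expect_equal(unname(t1$statistic), -unname(t2$statistic), tolerance = 1e-12)
  expect_equal(t1$p.value, t2$p.value, tolerance = 1e-12)
})

test_that("single-group strata are dropped, empty designs fail", {
  v <- c(1, 2, 3, 4, 5)
  g <- c("A", "B", "A", "A", "A")
  s <- c(1, 1, 1, 2, 2)   # stratum 2 has only group A
  expect_warning(res <- van_elteren(v, g, s), "single group")
  expect_true(is.finite(res$statistic))
  expect_error(suppressWarnings(van_elteren(v[4:5], g[4:5], s[4:5])),
               "two levels|no stratum")
})

test_that("van Elteren normal approximation tracks exact stratified permutation", {
  # two small strata: full enumeration of within-stratum label assignments
  v <- list(c(0.3, 1.1, 0.8, 2.0, 1.4, 0.6), c(0.2, 0.9, 1.8, 1.5, 1.1, 0.4))
  g <- rep(rep(c("A", "B"), each = 3), 2)
  s <- rep(1:2, each = 6)
  obs <- van_elteren(unlist(v), g, s)
  splits <- combn(6, 3, simplify = FALSE)  # positions of group A per stratum
  stats_all <- c()
  for (p1 in splits) for (p2 in splits) {
    g1 <- replace(rep("B", 6), p1, "A")
    g2 <- replace(rep("B", 6), p2, "A")
    z <- van_elteren(unlist(v), c(g1, g2), s)$statistic
    stats_all <- c(stats_all, z)
  }
  p_exact <- mean(abs(stats_all) >= abs(obs$statistic) - 1e-9)
  # the permutation null is discrete: compare the normal approximation
  # against the exact mid-p, the usual discreteness bridge
  p_mid <- mean(abs(stats_all) > abs(obs$statistic) + 1e-9) +
    0.5 * mean(abs(abs(stats_all) - abs(obs$statistic)) <= 1e-9)
  expect_lt(abs(obs$p.value - p_mid), 0.05)
  # the built-in permutation p agrees with plain enumeration at these sizes
  perm <- van_elteren(unlist(v), g, s, permutation = TRUE, n_perm = 4000,
                      seed = 2)
  expect_lt(abs(perm$p.value.permutation - p_exact), 0.03)
})

test_that("trend test hits its extremes and cancellations", {
  # strictly increasing with dose: maximal statistic, minimal permutation p
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  d <- c(0, 0, 1, 1, 10, 10, 30, 30)
  up <- linear_by_linear_trend(v, d, permutation = TRUE, n_perm = 2000,
                               seed = 3)
  expect_gt(unname(up$statistic), 2)
  # perfectly ordered data sit at the edge of the permutation distribution
  expect_lt(up$p.value.permutation, 0.005)
  # two strata with equal and opposite trends cancel
  v2 <- c(1, 2, 3, 3, 2, 1)
  d2 <- c(0, 1, 10, 0, 1, 10)
  s2 <- rep(c("WT", "KO"), each = 3)
  both <- linear_by_linear_trend(v2, d2, strata = s2)
  expect_lt(abs(both$statistic), 1e-9)
  expect_error(linear_by_linear_trend(c(1, 1, 1, 1), c(0, 1, 10, 30)),
               "constant values")
})

test_that("rank scores change the weighting of unevenly spaced doses", {
  set.seed(8)
  v <- rnorm(16) + rep(c(0, 0.3, 0.6, 0.9), each = 4)
  d <- rep(c(0, 1, 10, 30), each = 4)
  t_num <- linear_by_linear_trend(v, d, score_type = "numeric")
  t_rnk <- linear_by_linear_trend(v, d, score_type = "rank")
  expect_false(isTRUE(all.equal(t_num$statistic, t_rnk$statistic)))
  expect_gt(unname(t_rnk$statistic), 0)
})

test_that("trend test maintains its type-I error under the null", {
  set.seed(11)
  doses <- rep(c(0, 1, 10, 30), each = 4)
  strat <- rep(c("WT", "KO"), times = 8)
  rej <- mean(replicate(2000, {
    linear_by_linear_trend(rnorm(16), doses, strata = strat)$p.value < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("log-link regression recovers known effects with robust inference", {
  set.seed(12)
  n <- 200
  x <- runif(n)
  g <- rbinom(n, 1, 0.5)
  beta <- c(0.5, 0.8, -0.6)
  y <- exp(beta[1] + beta[2] * x + beta[3] * g) + rnorm(n, 0, 0.05)
  d <- data.frame(y = y, x = x, g = g, id = seq_len(n))
  fit <- loglink_regression_clustered(y ~ x + g, d, cluster = d$id)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est - beta) < 3 * se))
  # one observation per cluster: robust SE equals HC sandwich
  hc <- sqrt(diag(sandwich::vcovHC(fit$model, type = "HC1")))
  cl <- sqrt(diag(sandwich::vcovCL(fit$model, cluster = d$id, type = "HC1")))
  expect_equal(unname(cl), unname(hc), tolerance = 1e-8)
})

test_that("duplicating whole clusters leaves coefficients unchanged", {
  set.seed(13)
  d <- data.frame(y = exp(rnorm(40, 1, 0.3)),
                  x = rnorm(40), id = rep(1:10, each = 4))
  f1 <- loglink_regression_clustered(y ~ x, d, cluster = d$id)
  d2 <- rbind(d, d)
  f2 <- loglink_regression_clustered(y ~ x, d2, cluster = c(d$id, d$id))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
})

test_that("log-link regression rejects bad designs by name", {
  d <- data.frame(y = exp(rnorm(10)), x = rnorm(10))
  d$x2 <- d$x
  expect_error(loglink_regression_clustered(y ~ x + x2, d, cluster = 1:10),
               "x2")
  d$yneg <- d$y - 10
  expect_error(loglink_regression_clustered(yneg ~ x, d, cluster = 1:10),
               "positive")
})

test_that("uptake regression recovers an exactly linear dose effect", {
  d <- expand.grid(genotype = c("WT", "KO"), dose = c(0, 1, 10, 30),
                   rep = 1:2)
  d$pct_id_g <- 8 - 0.15 * d$dose
  fit <- suppressWarnings(regression_dose_genotype(d))
  expect_equal(unname(fit$coefficients["dose", "Estimate"]), -0.15,
               tolerance = 1e-12)
  grow <- grep("genotype", rownames(fit$coefficients))
  expect_equal(unname(fit$coefficients[grow, "Estimate"]), 0,
               tolerance = 1e-12)
})
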