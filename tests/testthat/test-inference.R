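# Independent sums-of-squares oracle for one-way ANOVA, written from the
# textbook definition (no shared code with the implementation).
anova_ss_oracle <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  k <- length(groups); N <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

test_that("ANOVA: equal group means give F = 0, p = 1", {
  res <- one_way_anova(data.frame(label = c("a", "b"), n = c(5, 7),
                                  mean = c(2, 2), sd = c(1, 0.5)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # all-degenerate case: zero variance everywhere, equal means
  res0 <- one_way_anova(list(a = rep(3, 4), b = rep(3, 5)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("ANOVA raw and summary routes agree to 1e-10 and match the SS oracle", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), mean = rnorm(1)))
    names(groups) <- paste0("g", seq_len(k))
    raw <- one_way_anova(groups)
    summ <- one_way_anova(data.frame(
      label = names(groups),
      n = lengths(groups),
      mean = vapply(groups, mean, numeric(1)),
      sd = vapply(groups, sd, numeric(1))
    ))
    oracle <- anova_ss_oracle(groups)
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
    expect_equal(summ$statistic, oracle$f, tolerance = 1e-10)
    expect_equal(summ$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(raw$df1, k - 1)
    expect_equal(raw$df2, sum(lengths(groups)) - k)
  }
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("Welch test: identity, symmetry, and route agreement", {
  x <- rep(c(1, 2, 3), 2)
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(32)
  a <- rnorm(10, 0, 1); b <- rnorm(14, 0.7, 2.5)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$df, ba$df)

  summ <- welch_t(group_stats("a", length(a), mean(a), sd(a)),
                  group_stats("b", length(b), mean(b), sd(b)))
  expect_equal(summ$statistic, ab$statistic, tolerance = 1e-12)
  expect_equal(summ$df, ab$df, tolerance = 1e-12)
  expect_equal(summ$p_value, ab$p_value, tolerance = 1e-12)
})

test_that("Student test matches a hand-computed pooled t on a 3+3 toy", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  res <- student_t(a, b)
  # by hand: sp2 = (2*1 + 2*4)/4 = 2.5; t = -2 / sqrt(2.5 * 2/3)
  t_hand <- -2 / sqrt(2.5 * (2 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(student_t(a, a)$p_value, 1)
})

test_that("Student and Welch p-values converge for equal-variance groups", {
  set.seed(33)
  a <- rnorm(200, 0, 1); b <- rnorm(200, 0.15, 1)
  expect_lt(abs(student_t(a, b)$p_value - welch_t(a, b)$p_value), 0.005)
})

test_that("a single-treatment Dunnett family reduces to the pooled t-test", {
  set.seed(34)
  ctrl <- rnorm(6); trt <- rnorm(8, 0.9)
  dn <- dunnett_many_to_one(ctrl, list(t1 = trt))
  st <- student_t(trt, ctrl)
  expect_equal(dn$statistic, st$statistic, tolerance = 1e-10)
  expect_equal(dn$p_raw, st$p_value, tolerance = 1e-10)
  expect_equal(dn$p_adj, st$p_value, tolerance = 1e-4)
})

test_that("Dunnett adjusted p-values dominate the unadjusted ones", {
  set.seed(35)
  for (rep in 1:4) {
    k <- sample(2:5, 1)
    ctrl <- rnorm(sample(4:8, 1))
    trts <- lapply(seq_len(k), function(i) rnorm(sample(3:9, 1), rnorm(1)))
    names(trts) <- paste0("t", seq_len(k))
    dn <- dunnett_many_to_one(ctrl, trts)
    expect_true(all(dn$p_adj >= dn$p_raw - 1e-12))
    expect_true(all(dn$p_adj <= 1 & dn$p_adj >= 0))
    expect_true(all(dn$df > 0))
  }
  expect_error(dunnett_many_to_one(rnorm(3), list(a = 1)), ">= 2 observations")
})

test_that("Dunnett integration agrees with the equicorrelated multivariate t", {
  set.seed(36)
  ctrl <- rnorm(6)
  trts <- list(a = rnorm(8, 0.8), b = rnorm(5, -0.4), c = rnorm(7, 0.2))
  dn <- dunnett_many_to_one(ctrl, trts)
  n <- c(lengths(trts))
  lam <- sqrt(n / (n + 6))
  R <- outer(lam, lam); diag(R) <- 1
  nu <- 6 + sum(n) - 4
  for (i in seq_len(3)) {
    q <- abs(dn$statistic[i])
    ref <- 1 - mvtnorm::pmvt(lower = -rep(q, 3), upper = rep(q, 3),
                             corr = R, df = nu,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1]
    expect_equal(dn$p_adj[i], ref, tolerance = 1e-4)
  }
})

test_that("Dunnett Monte-Carlo route reproduces the integration route", {
  set.seed(37)
  ctrl <- rnorm(5)
  trts <- list(a = rnorm(5, 1), b = rnorm(5, 0.3))
  int <- dunnett_many_to_one(ctrl, trts)
  mc <- dunnett_many_to_one(ctrl, trts, method = "monte-carlo",
                            nsim = 100000, seed = 12)
  mc2 <- dunnett_many_to_one(ctrl, trts, method = "monte-carlo",
                             nsim = 100000, seed = 12)
  expect_equal(mc$p_adj, mc2$p_adj) # seeded determinism
  expect_equal(mc$p_adj, int$p_adj, tolerance = 0.01)
})

test_that("p-values are monotone decreasing in |statistic| at fixed df", {
  # pooled t with fixed group sizes: larger mean gap, larger |t|, smaller p
  gaps <- seq(0, 2, by = 0.25)
  res <- purrr::map_dfr(gaps, function(g) {
    student_t(group_stats("a", 6, g, 1), group_stats("b", 6, 0, 1))
  })
  expect_true(all(diff(abs(res$statistic)) > 0))
  expect_true(all(diff(res$p_value) < 1e-12))
})
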