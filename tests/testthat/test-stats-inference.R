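test_that("Pearson chi-squared matches closed form and known tables", {
  r <- pearsonChi2(matrix(c(28, 16, 14, 27), 2))
  expect_equal(r$statistic, 7.3839, tolerance = 1e-4)
  expect_equal(round(r$p.value, 3), 0.007)

  # independence: table proportional to outer product of margins
  tab <- outer(c(2, 3), c(4, 6))
  r0 <- pearsonChi2(tab)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  r3 <- pearsonChi2(matrix(c(0, 7, 3, 14, 9, 11), 3))
  expect_equal(r3$df, 2)
  expect_equal(r3$p.value, 0.0169, tolerance = 1e-2)

  expect_error(pearsonChi2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher exact 2x2 follows the probability-mass rule", {
  expect_equal(fisherExact2x2(matrix(1, 2, 2))$p.value, 1)
  expect_equal(fisherExact2x2(matrix(c(3, 0, 0, 3), 2))$p.value, 0.1)
  expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3)
  expect_equal(fisherExact2x2(matrix(c(3, 0, 0, 3), 2))$estimate, Inf)
})

test_that("exact tests agree with stats oracles on all small tables", {
  # every 2x2 table with total <= 12
  for (a in 0:6) for (b in 0:(12 - a)) for (cc in 0:(12 - a - b))
    for (d in 0:(12 - a - b - cc)) {
      tab <- matrix(c(a, cc, b, d), 2)
      if (sum(tab) == 0) next
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisherExact2x2(tab)$p.value,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    }
})

test_that("Freeman-Halton enumeration matches fisher.test and the 2x2", {
  t2 <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisherExactRxC(t2)$p.value, fisherExact2x2(t2)$p.value)

  t4 <- matrix(c(5, 13, 8, 9, 3, 6), 3)
  r <- fisherExactRxC(t4)
  expect_equal(round(r$p.value, 2), 0.04)
  expect_equal(r$p.value, stats::fisher.test(t4)$p.value,
               tolerance = 1e-10)

  # 2x3 toy with total 12 against the independent enumeration in stats
  t23 <- matrix(c(3, 1, 0, 2, 2, 4), 2)
  expect_equal(fisherExactRxC(t23)$p.value,
               stats::fisher.test(t23)$p.value, tolerance = 1e-10)

  expect_error(fisherExactRxC(matrix(150, 2, 2)), "Monte-Carlo")
})

test_that("Mann-Whitney U exact and approximate match wilcox.test", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1 / 3)
  expect_true(r$exact)

  # identical multisets: U = n1 n2 / 2 and p = 1
  r2 <- mannWhitney(c(5, 5, 5), c(5, 5))
  expect_equal(r2$statistic, 3)
  expect_equal(r2$p.value, 1)

  set.seed(1)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- rnorm(n1); y <- rnorm(n2)
    mine <- mannWhitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    for (alt in c("less", "greater"))
      expect_equal(mannWhitney(x, y, alt)$p.value,
                   stats::wilcox.test(x, y, alternative = alt,
                                      exact = TRUE)$p.value,
                   tolerance = 1e-12)
  }

  # tied / large samples: normal approximation with tie + continuity corr.
  set.seed(2)
  x <- sample(1:8, 30, replace = TRUE); y <- sample(2:9, 25, replace = TRUE)
  expect_equal(mannWhitney(x, y)$p.value,
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                   correct = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("Pearson correlation handles exact and generic cases", {
  x <- 1:10
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearsonCorrelation(x, -x)$estimate, -1)
  set.seed(3)
  y <- rnorm(10)
  ref <- stats::cor.test(x, y)
  mine <- pearsonCorrelation(x, y)
  expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(pearsonCorrelation(x, rep(1, 10)), "constant")
})

test_that("logistic IRLS reproduces the saturated 2x2 and glm", {
  x <- c(rep(1, 42), rep(0, 43))
  y <- c(rep(1, 28), rep(0, 14), rep(1, 16), rep(0, 27))
  f <- logisticFit(matrix(x, dimnames = list(NULL, "driver")), y)
  expect_equal(unname(f$or["driver"]), 28 * 27 / (14 * 16),
               tolerance = 1e-9)

  set.seed(4)
  X <- cbind(a = rnorm(200), b = rbinom(200, 1, 0.5))
  yy <- rbinom(200, 1, plogis(0.3 * X[, "a"] - 0.5 * X[, "b"]))
  f2 <- logisticFit(X, yy)
  g <- stats::glm(yy ~ X, family = binomial)
  expect_equal(unname(f2$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f2$se),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
  expect_false(f2$separation)

  # y independent of X: slopes near zero
  y0 <- rbinom(500, 1, 0.4)
  set.seed(5)
  f0 <- logisticFit(cbind(z = rnorm(500)), y0)
  expect_lt(abs(f0$coefficients["z"]), 0.25)

  # perfect separation is flagged, not silently returned
  xs <- c(rep(0, 10), rep(1, 10)); ys <- c(rep(0, 10), rep(1, 10))
  fs <- logisticFit(cbind(s = xs + rnorm(20, 0, 1e-6)), ys)
  expect_true(fs$separation)
})

test_that("logistic and Cox estimates are equivariant to rescaling", {
  set.seed(6)
  X <- cbind(a = rnorm(100))
  y <- rbinom(100, 1, plogis(X[, 1]))
  f1 <- logisticFit(X, y)
  f10 <- logisticFit(X * 10, y)
  expect_equal(unname(f1$coefficients["a"]),
               unname(f10$coefficients["a"] * 10), tolerance = 1e-6)

  tt <- rexp(100, exp(0.5 * X[, 1])); ev <- rbinom(100, 1, 0.8)
  c1 <- coxphFit(tt, ev, X)
  c10 <- coxphFit(tt, ev, X * 10)
  expect_equal(unname(c1$coefficients), unname(c10$coefficients * 10),
               tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(7)
  p <- runif(50)
  expect_equal(bhFdr(p), stats::p.adjust(p, "BH"))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Kaplan-Meier matches hand computation and survfit", {
  k <- kmEstimate(c(1, 2), c(1, 1))
  expect_equal(k$surv, c(0.5, 0))

  # all censored: no event times, curve stays at 1
  expect_length(kmEstimate(c(1, 2, 3), c(0, 0, 0))$time, 0)

  # no censoring: reduces to the empirical survival function
  set.seed(8)
  tt <- sort(sample(1:100, 20))
  k2 <- kmEstimate(tt, rep(1, 20))
  expect_equal(k2$surv, 1 - seq_along(tt) / 20)

  skip_if_not_installed("survival")
  ev <- rbinom(20, 1, 0.6)
  k3 <- kmEstimate(tt, ev)
  sf <- summary(survival::survfit(survival::Surv(tt, ev) ~ 1,
                                  conf.type = "log-log"))
  expect_equal(k3$surv, sf$surv, tolerance = 1e-12)
  expect_equal(k3$se, sf$std.err, tolerance = 1e-9)
  expect_equal(k3$lower, sf$lower, tolerance = 1e-9)
  expect_equal(k3$upper, sf$upper, tolerance = 1e-9)
})

test_that("log-rank statistic matches the O-E/V oracle", {
  # identical groups
  r0 <- logrankTest(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                    rep(1:2, each = 3))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)

  # six-subject worked example, hand-checkable risk sets
  tt <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 0, 1, 1, 0, 1)
  gr <- c("a", "a", "a", "b", "b", "b")
  mine <- logrankTest(tt, ev, gr)
  skip_if_not_installed("survival")
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)

  set.seed(9)
  tt <- rexp(90); ev <- rbinom(90, 1, 0.7); gr <- rep(1:3, 30)
  expect_equal(logrankTest(tt, ev, gr)$statistic,
               survival::survdiff(survival::Surv(tt, ev) ~ gr)$chisq,
               tolerance = 1e-9)
})

test_that("Cox partial likelihood matches the closed form and coxph", {
  cx <- coxphFit(c(1, 2, 3), c(1, 1, 1), matrix(c(1, 0, 1), ncol = 1))
  expect_equal(unname(cx$coefficients), -log(2) / 2, tolerance = 1e-8)
  expect_equal(unname(cx$hr), 2^-0.5, tolerance = 1e-8)

  set.seed(10)
  X <- cbind(a = rnorm(120), b = rbinom(120, 1, 0.4))
  tt <- rexp(120, exp(0.4 * X[, 1])); ev <- rbinom(120, 1, 0.75)
  # null covariate: HR near 1
  expect_lt(abs(log(coxphFit(tt, ev, X[, "b", drop = FALSE])$hr)), 0.5)

  skip_if_not_installed("survival")
  for (ties in c("efron", "breslow")) {
    mine <- coxphFit(tt, ev, X, ties = ties)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = ties)
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(unname(mine$se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
  # tied event times
  tt2 <- round(tt * 4) / 4 + 0.25
  mine2 <- coxphFit(tt2, ev, X)
  ref2 <- survival::coxph(survival::Surv(tt2, ev) ~ X, ties = "efron")
  expect_equal(unname(mine2$coefficients), unname(coef(ref2)),
               tolerance = 1e-7)
  # delayed entry
  entry <- runif(120, 0, 0.1)
  mine3 <- coxphFit(tt2 + 0.2, ev, X, entry = entry)
  ref3 <- survival::coxph(survival::Surv(entry, tt2 + 0.2, ev) ~ X,
                          ties = "efron")
  expect_equal(unname(mine3$coefficients), unname(coef(ref3)),
               tolerance = 1e-7)
  # no events: flagged
  expect_true(coxphFit(tt, rep(0, 120), X)$flagged)
})
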