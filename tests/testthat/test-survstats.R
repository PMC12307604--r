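test_that("Kaplan-Meier matches hand-computed worked examples", {
  # no events: S(t) = 1 everywhere
  km0 <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # n = 2, deaths at 1 and 2
  km2 <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km_survival_at(km2, c(1, 2)), c(0.5, 0))
  # n = 3: death at 1, censor at 2, death at 3
  km3 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_survival_at(km3, 1), 2 / 3)
  expect_equal(km_survival_at(km3, 3), 0)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(61)
  t <- rexp(50, 0.1)
  km <- km_estimate(t, rep(1, 50))
  at <- sort(t)
  expect_equal(km_survival_at(km, at), 1 - seq_len(50) / 50, tolerance = 1e-12)
})

test_that("Cox fits agree with the independent Newton-Raphson oracle", {
  set.seed(62)
  n <- 40
  X <- cbind(age = rnorm(n), grp = rbinom(n, 1, 0.5))
  eta <- X %*% c(0.6, -0.8)
  t0 <- rexp(n, exp(eta)); cens <- rexp(n, 0.25)
  time <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
  fit <- cox_fit(as.data.frame(X), time, ev)
  o <- cox_oracle(X, time, ev)
  expect_equal(fit$coef, unname(o$coef), tolerance = 1e-6)
  expect_equal(fit$se, unname(o$se), tolerance = 1e-6)
  expect_equal(attr(fit, "loglik"), o$loglik, tolerance = 1e-6)
})

test_that("Cox recovers a planted hazard ratio and flags degenerate covariates", {
  set.seed(63)
  n <- 1000
  g <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.1 * 3^g)      # true HR 3
  cens <- runif(n, 0, 30)
  time <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
  fit <- cox_fit(data.frame(g = g), time, ev)
  expect_gt(fit$hr, 2.4); expect_lt(fit$hr, 3.75)
  expect_true(fit$hr_lo < fit$hr & fit$hr < fit$hr_hi)
  expect_warning(cox_fit(data.frame(g = g, const = 1), time, ev),
                 "non-estimable")
})

test_that("log-rank matches a hand-computed observed-minus-expected fixture", {
  # groups A: death 1, death 3, censor 5; B: death 2, death 4, censor 6
  time <- c(1, 3, 5, 2, 4, 6)
  ev <- c(1, 1, 0, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, ev, grp)
  # hand computation: event times 1,2,3,4 with risk sets 6,5,4,3
  # O_A = 2; E_A = 3/6 + 2/5 + 2/4 + 1/3; V summed per time
  eA <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3
  v <- (3 * 3) / 36 + (2 * 3) / 25 + (2 * 2) / 16 + (1 * 2) / 9
  expect_equal(lr$statistic, (2 - eA)^2 / v, tolerance = 1e-10)
  # duplicated data across groups -> p ~ 1
  lr0 <- logrank_test(rep(time, 2), rep(ev, 2), rep(c("X", "Y"), each = 6))
  expect_gt(lr0$p, 0.99)
  # strong separation -> tiny p
  set.seed(64)
  t1 <- rexp(100, 1); t2 <- rexp(100, 0.05)
  lr2 <- logrank_test(c(t1, t2), rep(1, 200), rep(c("a", "b"), each = 100))
  expect_lt(lr2$p, 1e-6)
  expect_error(logrank_test(time, ev, rep("A", 6)), "2 non-empty groups")
})

test_that("AUC equals the Mann-Whitney pair probability", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  # brute-force pair enumeration oracle on random data with ties
  set.seed(65)
  y <- rbinom(60, 1, 0.5)
  s <- sample(1:10, 60, replace = TRUE)
  pos <- s[y == 1]; neg <- s[y == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(y, s), mean(pairs), tolerance = 1e-12)
  # invariant to monotone transforms of the score
  s2 <- rnorm(60)
  expect_equal(roc_auc(y, s2), roc_auc(y, exp(s2)), tolerance = 1e-12)
  # chance level at large n
  set.seed(66)
  expect_lt(abs(roc_auc(rbinom(5000, 1, 0.5), rnorm(5000)) - 0.5), 0.05)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both outcome classes")
})

test_that("Pearson correlation handles exact and fixture cases", {
  x <- rnorm(10)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(c(1, 2), c(1, 2)), "at least 3")
})

test_that("chi-squared association matches closed forms", {
  r0 <- chi2_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r1 <- chi2_association(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r1$statistic, 40)
  expect_error(chi2_association(matrix(c(0, 0, 5, 5), 2)), "zero row or column")
})
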