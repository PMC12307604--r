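# The planted-signal simulations here are small by design; the full-scale
# selection geometry (200 candidates, 10 planted, n = 600) is exercised by
# the acceptance suite.

sim_surv <- function(mv, loghr, baseline = 0.05, cens_max = 60, seed = 1) {
  set.seed(seed)
  eta <- drop(scale(mv, scale = FALSE) %*% loghr)
  t0 <- rexp(nrow(mv), baseline * exp(eta))
  cens <- runif(nrow(mv), 0, cens_max)
  list(time = pmin(t0, cens), event = as.integer(t0 <= cens))
}

test_that("EWAS recovers a lone planted coefficient", {
  set.seed(71)
  n <- 500
  mv <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(sprintf("s%03d", 1:n), c("hit", "n1", "n2")))
  sv <- sim_surv(mv, c(1, 0, 0), seed = 72)
  ew <- cox_ewas(mv, sv$time, sv$event)
  expect_s3_class(ew, "ewas_result")
  expect_equal(ew$coef[ew$probe_id == "hit"], 1, tolerance = 0.2)
  expect_lt(ew$p[ew$probe_id == "hit"], 1e-10)
})

test_that("EWAS p-values are uniform under the null", {
  set.seed(73)
  n <- 200; p <- 100
  mv <- matrix(rnorm(n * p), n, p,
               dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%03d", 1:p)))
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.6)
  ew <- cox_ewas(mv, time, event)
  frac <- mean(ew$p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), p, 0.05) / p
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("degenerate CpGs are flagged with p = 1", {
  set.seed(74)
  n <- 60
  mv <- cbind(const = rep(0.3, n), ok = rnorm(n))
  rownames(mv) <- sprintf("s%02d", 1:n)
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7)
  ew <- cox_ewas(mv, time, event)
  expect_true(ew$flagged[ew$probe_id == "const"])
  expect_equal(ew$p[ew$probe_id == "const"], 1)
  expect_false(ew$flagged[ew$probe_id == "ok"])
})

test_that("candidate selection applies a strict threshold, sorted by p", {
  ew <- structure(
    data.frame(probe_id = c("a", "b", "c"),
               coef = 1, se = 1, z = 1,
               p = c(1e-4, 1e-6, 1e-5), flagged = FALSE),
    class = c("ewas_result", "data.frame"))
  expect_identical(select_candidates(ew, 1e-5), "b")  # 1e-5 itself excluded
  expect_identical(select_candidates(ew, 1e-3), c("b", "c", "a"))
  expect_warning(out <- select_candidates(ew, 1e-10), "no CpG")
  expect_length(out, 0)
  expect_error(select_candidates(ew, 0), "alpha")
})

test_that("stability selection keeps planted probes and is seed-deterministic", {
  set.seed(75)
  n <- 250; p <- 30
  mv <- matrix(rnorm(n * p), n, p,
               dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%03d", 1:p)))
  loghr <- c(rep(1, 3), rep(0, p - 3))
  sv <- sim_surv(mv, loghr, seed = 76)
  sig <- stability_select(mv, sv$time, sv$event, n_iter = 40, seed = 5)
  expect_true(all(c("cg001", "cg002", "cg003") %in% sig$entries$probe_id))
  expect_lte(sum(!sig$entries$probe_id %in% c("cg001", "cg002", "cg003")), 1)
  sig2 <- stability_select(mv, sv$time, sv$event, n_iter = 40, seed = 5)
  expect_identical(sig$entries, sig2$entries)
  expect_identical(sig$cutoff, sig2$cutoff)
})

test_that("pure-noise candidates raise rather than fabricate a signature", {
  set.seed(77)
  n <- 120; p <- 15
  mv <- matrix(rnorm(n * p), n, p,
               dimnames = list(sprintf("s%03d", 1:n), sprintf("cg%03d", 1:p)))
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.5)
  expect_error(
    stability_select(mv, time, event, n_iter = 25, seed = 1),
    "selection frequency")
})

test_that("hazard scores are the stated linear combination", {
  sig <- structure(list(entries = data.frame(probe_id = c("cgA", "cgB"),
                                             coefficient = c(0.5, -0.3)),
                        cutoff = 0),
                   class = "cpg_signature")
  mv <- matrix(c(2, 1), 1, 2, dimnames = list("s1", c("cgA", "cgB")))
  expect_equal(unname(hazard_score(sig, mv)), 0.7)
  mv0 <- matrix(0, 1, 2, dimnames = list("s1", c("cgA", "cgB")))
  expect_equal(unname(hazard_score(sig, mv0)), 0)
  expect_error(hazard_score(sig, mv0[, 1, drop = FALSE]), "cgB")
  # linearity: score(aM1 + bM2) = a score(M1) + b score(M2)
  set.seed(78)
  m1 <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("cgA", "cgB")))
  m2 <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("cgA", "cgB")))
  expect_equal(hazard_score(sig, 2 * m1 + 3 * m2),
               2 * hazard_score(sig, m1) + 3 * hazard_score(sig, m2),
               tolerance = 1e-12)
})

test_that("dichotomization follows the strict > cutoff rule", {
  expect_identical(dichotomize(-2.0, -2.043), "high")
  expect_identical(dichotomize(-2.043, -2.043), "low")  # boundary -> low
  expect_error(dichotomize(1, Inf), "finite")
  # a median cutoff splits a cohort evenly
  set.seed(79)
  s <- rnorm(100)
  g <- dichotomize(s, median(s))
  expect_lte(abs(sum(g == "high") - sum(g == "low")), 1)
})
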