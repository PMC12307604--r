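# Coordinates for classifier tests are drawn directly in embedding space:
# the classifiers' contract is over coordinates, not methylomes.

make_coords <- function(n_per, k, sep = 4, d = 5, seed = 51) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d, sd = sep), k, d)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[i, ], "+")
  }))
  rownames(x) <- sprintf("s%04d", seq_len(n_per * k))
  list(coords = x, labels = rep(paste0("class_", seq_len(k)), each = n_per))
}

test_that("subtype classifier separates clustered coordinates almost perfectly", {
  cc <- make_coords(100, 6)
  set.seed(52)
  test_idx <- sample(600, 120)
  fit <- train_subtype(cc$coords[-test_idx, ], cc$labels[-test_idx], seed = 1)
  pred <- predict(fit, cc$coords[test_idx, ])
  acc <- mean(pred$top_label == cc$labels[test_idx])
  expect_gte(acc, 0.95)
  # probabilities normalized; gate consistent with the 0.5 rule
  probs <- as.matrix(pred[, fit$classes])
  expect_equal(unname(rowSums(probs)), rep(1, 120), tolerance = 1e-9)
  expect_identical(pred$confident, pred$confidence >= 0.5)
  expect_identical(pred$display_label[!pred$confident],
                   rep("Not confident", sum(!pred$confident)))
})

test_that("training is deterministic and degenerate label sets are handled", {
  cc <- make_coords(30, 3)
  f1 <- train_subtype(cc$coords, cc$labels, seed = 9)
  f2 <- train_subtype(cc$coords, cc$labels, seed = 9)
  expect_identical(f1$raw, f2$raw)
  expect_error(train_subtype(cc$coords[1:3, ], c("a", "a", "b")), "single sample")
  expect_error(train_subtype(cc$coords, cc$labels, vocabulary = c("x", "y")),
               "vocabulary")
  # one-class data yields the trivial always-that-class model
  one <- train_subtype(cc$coords[1:10, ], rep("only", 10))
  p <- predict(one, cc$coords[1:2, ])
  expect_identical(p$top_label, c("only", "only"))
  expect_equal(p$confidence, c(1, 1))
})

test_that("shuffled labels yield chance-level cross-validated kappa", {
  cc <- make_coords(40, 4)
  set.seed(53)
  fit <- train_subtype(cc$coords, sample(cc$labels), seed = 2)
  expect_lt(abs(fit$cv_metrics$cohens_kappa), 0.1)
})

test_that("a single informative coordinate gives perfect per-class recall", {
  set.seed(54)
  x <- cbind(c(rnorm(40, -5), rnorm(40, 5)), matrix(rnorm(80 * 4), 80, 4))
  rownames(x) <- sprintf("s%03d", 1:80)
  lab <- rep(c("lo", "hi"), each = 40)
  fit <- train_subtype(x, lab, seed = 3)
  pred <- predict(fit, x)
  m <- classification_metrics(lab, pred$top_label)
  expect_equal(unname(m$per_class_concordance), c(1, 1))
})

test_that("risk training applies the dead/alive labeling rule", {
  set.seed(55)
  n <- 200
  coords <- matrix(rnorm(n * 5), n, 5,
                   dimnames = list(sprintf("s%03d", 1:n), NULL))
  # hazard linked to the first coordinate (strong planted effect: the
  # true-score AUC for the 5-year label is ~0.88, leaving learnable margin)
  eta <- 1.5 * coords[, 1]
  t0 <- rexp(n, 0.02 * exp(eta))
  cens <- runif(n, 0, 200)
  os_time <- pmin(t0, cens); os_event <- as.integer(t0 <= cens)
  fit <- train_risk(coords, os_time, os_event, seed = 1)
  # censored-before-horizon samples were excluded and counted
  expect_identical(fit$n_excluded_censored,
                   sum(os_event == 0 & os_time < 60))
  # held-out check on fresh samples from the same generator
  set.seed(56)
  coords2 <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(sprintf("t%03d", 1:n), NULL))
  t2 <- rexp(n, 0.02 * exp(1.5 * coords2[, 1]))
  died5 <- as.integer(t2 <= 60)
  pred <- predict(fit, coords2)
  expect_gte(roc_auc(died5, pred$p_death_5y), 0.8)
  expect_identical(pred$group, ifelse(pred$p_death_5y >= 0.5, "high", "low"))
})

test_that("risk training rejects starved outcome classes", {
  coords <- matrix(rnorm(100), 20, 5)
  expect_error(train_risk(coords, rep(100, 20), rep(0, 20)), "at least 10")
})

test_that("metrics match an independent computation on a fixed confusion", {
  # counts [[8,1,1],[2,6,2],[0,0,10]]
  truth <- rep(c("a", "b", "c"), each = 10)
  pred <- c(rep("a", 8), "b", "c",
            "a", "a", rep("b", 6), "c", "c",
            rep("c", 10))
  m <- classification_metrics(truth, pred)
  expect_equal(m$accuracy, 24 / 30)
  expect_equal(unname(m$per_class_concordance), c(0.8, 0.6, 1.0))
  # kappa from the definition: p_e from marginal products
  p_o <- 24 / 30
  p_e <- (10 * 10 + 10 * 7 + 10 * 13) / 900
  expect_equal(m$cohens_kappa, (p_o - p_e) / (1 - p_e))
  # weighted F1 assembled by hand from per-class precision/recall
  prec <- c(8 / 10, 6 / 7, 10 / 13)
  rec <- c(0.8, 0.6, 1.0)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(m$weighted_f1, mean(f1))
  # and against caret's independent implementation
  cm <- caret::confusionMatrix(factor(pred), factor(truth))
  expect_equal(m$accuracy, unname(cm$overall["Accuracy"]), tolerance = 1e-12)
  expect_equal(m$cohens_kappa, unname(cm$overall["Kappa"]), tolerance = 1e-12)
})

test_that("metrics reject invalid inputs and behave at chance", {
  expect_error(classification_metrics(character(), character()), "empty")
  expect_error(classification_metrics(c("a", "b"), "a"), "mismatch")
  set.seed(57)
  t <- sample(letters[1:4], 4000, replace = TRUE)
  p <- sample(letters[1:4], 4000, replace = TRUE)
  expect_lt(abs(classification_metrics(t, p)$cohens_kappa), 0.05)
  perfect <- classification_metrics(t, t)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$weighted_f1, 1)
  expect_equal(perfect$cohens_kappa, 1)
})
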