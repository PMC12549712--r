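test_that("a perfect predictor scores 1 everywhere with degenerate CIs", {
  y <- factor(rep(c("HC", "HY1", "HY2"), each = 10), levels = c("HC", "HY1", "HY2"))
  probs <- matrix(0.001, 30, 3, dimnames = list(NULL, levels(y)))
  probs[cbind(1:30, as.integer(y))] <- 0.998
  m <- fixed_prob_model(probs)
  rep_ <- evaluate_classifier(m, array(0, c(30, 2, 2)), y, bootstrap_n = 200,
                              seed = 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(unname(rep_$per_class[, "auc"]), c(1, 1, 1))
  expect_equal(unname(rep_$ci["accuracy", ]), c(1, 1))
})

test_that("an uninformative predictor sits at chance AUC", {
  set.seed(2)
  y <- factor(sample(rep(c("HC", "HY1", "HY2"), each = 100)),
              levels = c("HC", "HY1", "HY2"))
  probs <- matrix(runif(900), 300, 3)
  probs <- probs / rowSums(probs)
  colnames(probs) <- levels(y)
  rep_ <- evaluate_classifier(fixed_prob_model(probs), array(0, c(300, 1, 1)),
                              y, bootstrap_n = 0)
  expect_equal(rep_$macro_auc, 0.5, tolerance = 0.07)
})

test_that("sensitivity and specificity match hand-computed counts", {
  # toy confusion: rows truth HC/HY1/HY2, predictions chosen by max prob
  y <- factor(c(rep("HC", 4), rep("HY1", 3), rep("HY2", 3)),
              levels = c("HC", "HY1", "HY2"))
  pred <- c("HC", "HC", "HY1", "HC", "HY1", "HY2", "HY1", "HY2", "HY2", "HC")
  probs <- matrix(0.05, 10, 3, dimnames = list(NULL, levels(y)))
  probs[cbind(1:10, match(pred, levels(y)))] <- 0.9
  rep_ <- evaluate_classifier(fixed_prob_model(probs), array(0, c(10, 1, 1)),
                              y, bootstrap_n = 0)
  # hand counts: HC 3/4 correct; HY1 2/3; HY2 2/3
  expect_equal(unname(rep_$per_class[, "sensitivity"]), c(3 / 4, 2 / 3, 2 / 3))
  # specificity: HC predicted for 1 non-HC of 6; HY1 for 1 non-HY1 of 7;
  # HY2 for 1 non-HY2 of 7
  expect_equal(unname(rep_$per_class[, "specificity"]), c(5 / 6, 6 / 7, 6 / 7))
  expect_equal(rep_$accuracy, 7 / 10)
  expect_equal(unname(rowSums(rep_$confusion)), c(4, 3, 3))
})

test_that("the rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (i in 1:5) {
    pos <- runif(40) > 0.5
    if (!any(pos) || all(pos)) next
    sc <- rnorm(40) + pos
    ours <- atlaspd:::.auc_ovr(sc, pos)
    ref <- as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("McNemar statistics follow the corrected formula and exact branch", {
  y <- rep("HC", 40)
  same <- rep("HC", 40)
  r0 <- mcnemar_test(same, same, y)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # b = 10, c = 2 with continuity correction -> chi^2 = 49/12
  truth <- rep("HC", 40)
  a <- truth; b <- truth
  b[1:10] <- "HY1"   # A right, B wrong: 10
  a[11:12] <- "HY1"  # A wrong, B right: 2
  r <- mcnemar_test(a, b, truth)
  expect_equal(r$b, 10)
  expect_equal(r$c, 2)
  expect_equal(r$statistic, 49 / 12, tolerance = 1e-12)
  expect_match(r$method, "exact")  # b + c = 12 < 25
  expect_equal(r$p_value, binom.test(10, 12, 0.5)$p.value, tolerance = 1e-12)
  # b = 2, c = 1: full enumeration of Binom(3, 1/2) gives p = 1
  a2 <- truth; b2 <- truth
  b2[1:2] <- "HY1"; a2[3] <- "HY1"
  r2 <- mcnemar_test(a2, b2, truth)
  expect_equal(r2$p_value, 1)
  # large-sample branch
  a3 <- truth; b3 <- truth
  b3[1:20] <- "HY1"; a3[21:30] <- "HY1"
  r3 <- mcnemar_test(a3, b3, truth)
  expect_equal(r3$statistic, (abs(20 - 10) - 1)^2 / 30)
  expect_equal(r3$p_value, pchisq(r3$statistic, 1, lower.tail = FALSE))
})

test_that("robustness curve reproduces clean accuracy at sigma zero", {
  toy <- toy_sequences(n_per_class = 5, Tn = 20, seed = 4)
  probs <- matrix(1 / 3, 15, 3, dimnames = list(NULL, levels(toy$y)))
  probs[, 1] <- 0.5  # constant "always HC" model
  m <- fixed_prob_model(probs)
  rc <- noise_robustness(m, toy$x, toy$y, sigmas = c(0, 0.2, 0.4), reps = 3,
                         seed = 1)
  clean <- mean(predict(m, toy$x, type = "class") == toy$y)
  expect_equal(rc$curve$accuracy[1], clean)
  # constant-prediction model: flat curve, area equals that accuracy
  expect_true(all(abs(rc$curve$accuracy - clean) < 1e-12))
  expect_equal(rc$auc_robustness, clean)
  expect_error(noise_robustness(m, toy$x, toy$y, sigmas = c(-0.1, 0)), "non-negative")
})

test_that("the robustness area matches trapezoid arithmetic", {
  expect_equal(atlaspd:::.robustness_auc(c(0, 0.5), c(1.0, 0.5)), 0.75)
  expect_equal(atlaspd:::.robustness_auc(c(0, 0.1, 0.3), c(1, 1, 0)),
               (0.1 * 1 + 0.2 * 0.5) / 0.3)
  expect_equal(atlaspd:::.robustness_auc(c(0, 1), c(0.8, 0.8)), 0.8)
})

test_that("effect-size arithmetic matches its closed forms", {
  expect_equal(cohens_d(0, 1, 10, 1, 1, 10), 1.0)
  expect_equal(cohens_d(5, 2, 30, 5, 3, 30), 0)
  expect_error(cohens_d(0, 0, 10, 1, 1, 10), "positive")
  expect_equal(cohens_f_from_eta2(0), 0)
  expect_equal(cohens_f_from_eta2(0.5), 1.0)
  expect_error(cohens_f_from_eta2(1), "eta2")
})

test_that("ANOVA power is monotone and inverts consistently", {
  pw <- vapply(seq(30, 300, by = 30), function(N) anova_power(0.3, 3, N),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  N <- anova_sample_size(0.25, 3, 0.05, 0.80)
  expect_gte(anova_power(0.25, 3, N), 0.80)
  expect_lt(anova_power(0.25, 3, N - 3), 0.80)
  expect_error(anova_power(0.3, 3, 2), "exceed")
})
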