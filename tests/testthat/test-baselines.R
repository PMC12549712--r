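test_that("summary featurisation yields 110 named per-channel statistics", {
  ds <- fixture("tiny_ds", function() {
    co <- simulate_cohort(2, design = block_design(sampling_hz = 10), seed = 51)
    build_dataset(co, chromophore = "hbo", target_hz = 1, seed = 1)
  })
  f <- featurize(ds)
  expect_equal(dim(f), c(6, 110))
  expect_true(all(grepl("^CH\\d{2}_", colnames(f))))
  expect_false(anyNA(f))
  # one-subject oracle: shifted task-block mean of the raw series
  fs <- ds$sampling_hz
  ph <- design_phases(block_design(sampling_hz = fs))
  shift <- round(5 * fs)
  task <- c(rep(FALSE, shift), ph == "task")[seq_len(dim(ds$data)[3])]
  v <- ds$data[1, 3, ]
  expect_equal(unname(f[1, "CH03_task_mean"]), mean(v[task]), tolerance = 1e-12)
  expect_equal(unname(f[1, "CH03_task_rest_diff"]),
               unname(f[1, "CH03_task_mean"] - f[1, "CH03_rest_mean"]),
               tolerance = 1e-12)
})

test_that("a zero-signal cohort has near-zero task contrasts", {
  eff <- group_effect_profile(fpc_amplitude_uM = c(HC = 0, HY1 = 0, HY2 = 0),
                              variability = 0)
  co <- simulate_cohort(1, design = block_design(sampling_hz = 10),
                        effects = eff, noise = noise_profile(scale = 0), seed = 3)
  ds <- build_dataset(co, chromophore = "hbo", target_hz = 1, zscore = FALSE,
                      quality_gate = FALSE, seed = 1)
  expect_equal(dim(ds$data)[1], 3)
  f <- featurize(ds)
  expect_lt(max(abs(f[, grep("task_rest_diff", colnames(f))])), 1e-9)
})

test_that("all four baselines separate an easy feature space", {
  set.seed(4)
  n <- 60
  y <- factor(rep(c("HC", "HY1", "HY2"), each = n / 3),
              levels = c("HC", "HY1", "HY2"))
  x <- matrix(rnorm(n * 2, sd = 0.2), n, 2)
  x[, 1] <- x[, 1] + as.integer(y) * 3
  colnames(x) <- c("f1", "f2")
  for (b in c("svm", "rf", "knn", "bpnn")) {
    fit <- fit_baseline(b, x, y, seed = 1)
    pred <- predict(fit, x, type = "class")
    expect_equal(mean(pred == y), 1, info = b)
    pr <- predict(fit, x)
    expect_equal(unname(rowSums(pr)), rep(1, n), tolerance = 1e-6, info = b)
    expect_equal(colnames(pr), levels(y), info = b)
  }
})

test_that("kNN returns probability one among identical-label neighbours", {
  x <- matrix(c(rep(0, 14), 5, 5), ncol = 2, byrow = FALSE)
  y <- factor(c(rep("HY1", 7), "HC"), levels = c("HC", "HY1", "HY2"))
  fit <- fit_baseline("knn", x, y, seed = 1)
  p <- predict(fit, matrix(c(0, 0), 1, 2))
  expect_equal(unname(p[1, "HY1"]), 1)
})

test_that("random-forest probabilities agree with traversing the dumped trees", {
  set.seed(6)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(c(rep("HC", 5), rep("HY1", 5)), levels = c("HC", "HY1", "HY2"))
  fit <- suppressWarnings(fit_baseline("rf", x, y, seed = 9))  # HY2 unused
  xq <- matrix(c(0.5, -0.5), 1, 2, dimnames = list(NULL, c("a", "b")))
  p <- predict(fit, xq)
  # oracle: walk every tree by hand via treeInfo on the scaled query
  xs <- atlaspd:::.scale_features(xq, fit$center, fit$scale)$x
  votes <- matrix(0, 1, 3, dimnames = list(NULL, fit$classes))
  rf <- fit$fit
  for (tr in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, tr)
    node <- 0
    repeat {
      row <- ti[ti$nodeID == node, ]
      if (row$terminal) break
      val <- xs[1, row$splitvarName]
      node <- if (val <= row$splitval) row$leftChild else row$rightChild
    }
    row <- ti[ti$nodeID == node, ]
    pred_cols <- grep("^pred\\.", names(ti), value = TRUE)
    votes[1, sub("^pred\\.", "", pred_cols)] <-
      votes[1, sub("^pred\\.", "", pred_cols)] + as.numeric(row[pred_cols])
  }
  votes <- votes / rf$num.trees
  expect_equal(as.numeric(p), as.numeric(votes[, colnames(p)]), tolerance = 1e-9)
})

test_that("cross-validation folds are disjoint, sized and reproducible", {
  set.seed(8)
  y <- factor(rep(c("HC", "HY1", "HY2"), each = 68))
  x <- matrix(rnorm(204 * 3), 204, 3)
  x[, 1] <- x[, 1] + as.integer(y)
  colnames(x) <- paste0("f", 1:3)
  cv <- cross_validate("rf", x, y, folds = 5, seed = 2)
  expect_equal(sort(cv$scores$n), c(40, 41, 41, 41, 41))
  expect_equal(sum(cv$scores$n), 204)
  expect_gt(cv$mean_accuracy, 0.5)
  cv2 <- cross_validate("rf", x, y, folds = 5, seed = 2)
  expect_identical(cv$fold, cv2$fold)
  expect_error(cross_validate("rf", x, y, folds = 1), "folds")
})

test_that("label shuffling drops every baseline into the chance band", {
  set.seed(11)
  n <- 90
  y <- factor(rep(c("HC", "HY1", "HY2"), each = n / 3),
              levels = c("HC", "HY1", "HY2"))
  x <- matrix(rnorm(n * 4, sd = 0.3), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  x[, 1] <- x[, 1] + as.integer(y)
  y_shuf <- sample(y)
  tr <- sample(n, 60); te <- setdiff(seq_len(n), tr)
  band <- qbinom(c(0.025, 0.975), length(te), 1 / 3)
  for (b in c("svm", "rf", "knn", "bpnn")) {
    fit <- fit_baseline(b, x[tr, ], y_shuf[tr], seed = 1)
    hits <- sum(predict(fit, x[te, ], type = "class") == y_shuf[te])
    expect_gte(hits, band[1])
    expect_lte(hits, band[2])
  }
})
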