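# Metrics, paired statistical comparison, noise robustness and power analysis.

# One-vs-rest AUC by the rank (Mann-Whitney) formula with midranks for ties.
.auc_ovr <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.metrics_from_probs <- function(probs, y, classes) {
  pred <- factor(classes[max.col(probs, ties.method = "first")], levels = classes)
  cm <- table(truth = factor(y, levels = classes), pred = pred)
  per <- lapply(seq_along(classes), function(k) {
    tp <- cm[k, k]; fn <- sum(cm[k, -k]); fp <- sum(cm[-k, k]); tn <- sum(cm[-k, -k])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    c(sensitivity = rec,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      precision = prec,
      f1 = if (is.na(rec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
      auc = .auc_ovr(probs[, k], y == classes[k]))
  })
  per <- do.call(rbind, per)
  rownames(per) <- classes
  list(confusion = cm,
       accuracy = mean(pred == y),
       macro_precision = mean(per[, "precision"], na.rm = TRUE),
       macro_recall = mean(per[, "sensitivity"], na.rm = TRUE),
       macro_f1 = mean(per[, "f1"], na.rm = TRUE),
       macro_auc = mean(per[, "auc"], na.rm = TRUE),
       per_class = per)
}

#' Evaluate a classifier on a labelled test set
#'
#' Computes the 3x3 confusion matrix, accuracy, macro precision/recall/F1,
#' per-class sensitivity, specificity and one-vs-rest ROC AUC (rank formula),
#' macro AUC, and percentile-bootstrap 95% confidence intervals for every
#' scalar (resampling test subjects with replacement). A class absent from
#' the test set has undefined AUC, reported as `NA`.
#'
#' @param model Any fit with a `predict(model, x)` method returning class
#'   probabilities (deep fits take the tensor; baseline fits take features).
#' @param x Test inputs matching the model.
#' @param y True labels.
#' @param bootstrap_n Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return An object of class `eval_report`.
#' @export
evaluate_classifier <- function(model, x, y, bootstrap_n = 1000, seed = 1) {
  classes <- c("HC", "HY1", "HY2")
  y <- factor(y, levels = classes)
  probs <- predict(model, x, type = "prob")
  m <- .metrics_from_probs(probs, y, classes)
  scalars <- c("accuracy", "macro_precision", "macro_recall", "macro_f1", "macro_auc")
  ci <- NULL
  if (bootstrap_n > 0) {
    set.seed(as.integer(seed))
    n <- length(y)
    boot <- matrix(NA_real_, bootstrap_n, length(scalars),
                   dimnames = list(NULL, scalars))
    for (b in seq_len(bootstrap_n)) {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- .metrics_from_probs(probs[idx, , drop = FALSE], y[idx], classes)
      boot[b, ] <- unlist(mb[scalars])
    }
    ci <- t(apply(boot, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
    colnames(ci) <- c("lower", "upper")
  }
  structure(c(m, list(ci = ci, n = length(y), bootstrap_n = bootstrap_n)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Test set: n = %d\n", x$n))
  cat(sprintf("accuracy %.3f | macro P %.3f R %.3f F1 %.3f | macro AUC %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$macro_auc))
  if (!is.null(x$ci))
    cat(sprintf("95%% CI accuracy [%.3f, %.3f] (bootstrap n=%d)\n",
                x$ci["accuracy", 1], x$ci["accuracy", 2], x$bootstrap_n))
  print(round(x$per_class, 3))
  invisible(x)
}

#' McNemar paired comparison of two classifiers
#'
#' Counts the discordant pairs (`b`: A right, B wrong; `c`: A wrong, B right)
#' and computes the continuity-corrected chi-squared statistic
#' `(|b - c| - 1)^2 / (b + c)` (correction configurable off); when
#' `b + c < 25` the p-value comes from the exact binomial distribution
#' instead. Optionally adds a percentile-bootstrap CI and superiority p for
#' the accuracy difference.
#'
#' @param preds_a,preds_b Aligned class predictions of the two models.
#' @param labels True labels.
#' @param correction Apply the continuity correction (default TRUE).
#' @param bootstrap_n Bootstrap resamples for the accuracy-difference CI
#'   (0 to skip).
#' @param seed Bootstrap seed.
#' @return An object of class `paired_comparison` with fields `b`, `c`,
#'   `statistic`, `p_value`, `method`, and (if bootstrapped) `diff_ci`,
#'   `p_superiority`.
#' @export
mcnemar_test <- function(preds_a, preds_b, labels, correction = TRUE,
                         bootstrap_n = 0, seed = 1) {
  stopifnot(length(preds_a) == length(preds_b),
            length(preds_a) == length(labels))
  ok_a <- preds_a == labels; ok_b <- preds_b == labels
  b <- sum(ok_a & !ok_b); cc <- sum(!ok_a & ok_b)
  if (b + cc == 0) {
    stat <- 0; p <- 1; method <- "chi-squared (no discordant pairs)"
  } else if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    stat <- (abs(b - cc) - if (correction) 1 else 0)^2 / (b + cc)
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - if (correction) 1 else 0)^2 / (b + cc)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- if (correction) "chi-squared with continuity correction" else "chi-squared"
  }
  out <- list(b = b, c = cc, statistic = stat, p_value = p, method = method)
  if (bootstrap_n > 0) {
    set.seed(as.integer(seed))
    n <- length(labels)
    diffs <- replicate(bootstrap_n, {
      idx <- sample.int(n, n, replace = TRUE)
      mean(ok_a[idx]) - mean(ok_b[idx])
    })
    out$diff_ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
    out$p_superiority <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  }
  structure(out, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("McNemar: b=%d c=%d, chi^2 = %.4f, p = %.4g (%s)\n",
              x$b, x$c, x$statistic, x$p_value, x$method))
  if (!is.null(x$diff_ci))
    cat(sprintf("accuracy difference 95%% CI [%.3f, %.3f], superiority p = %.4g\n",
                x$diff_ci[1], x$diff_ci[2], x$p_superiority))
  invisible(x)
}

# Normalised trapezoidal area of accuracy over the sigma grid: a model with
# constant accuracy a scores exactly a.
.robustness_auc <- function(sigmas, accuracy) {
  if (length(sigmas) < 2) return(accuracy[1])
  widths <- diff(sigmas)
  sum(widths * (utils::head(accuracy, -1) + utils::tail(accuracy, -1)) / 2) /
    (max(sigmas) - min(sigmas))
}

#' Gaussian-noise robustness curve
#'
#' Adds white Gaussian noise `N(0, sigma^2)` (in the units of the normalised
#' input) to the test inputs at each level of the sigma grid and measures
#' classification accuracy, averaged over `reps` seeded draws; `sigma = 0`
#' reproduces the clean accuracy exactly (no draw). Robustness is summarised
#' as the trapezoidal area under the accuracy curve normalised by the sigma
#' range (`AUC_robustness`), so a model holding accuracy 1 everywhere scores 1.
#'
#' @param model A fitted classifier (deep or baseline).
#' @param x Test inputs (tensor for deep fits, features for baselines).
#' @param y True labels.
#' @param sigmas Noise grid, strictly increasing from 0
#'   (default `c(0, 0.1, 0.2, 0.3, 0.4, 0.5)`).
#' @param reps Noise draws per level (default 20).
#' @param seed Seed.
#' @return An object of class `robustness_curve`: data frame `curve`
#'   (sigma, accuracy, sd), scalar `auc_robustness`, and `clean_accuracy`.
#' @export
noise_robustness <- function(model, x, y, sigmas = seq(0, 0.5, by = 0.1),
                             reps = 20, seed = 1) {
  if (any(sigmas < 0)) stop("noise levels must be non-negative")
  if (is.unsorted(sigmas, strictly = TRUE)) stop("sigma grid must be strictly increasing")
  classes <- c("HC", "HY1", "HY2")
  y <- factor(y, levels = classes)
  if (inherits(x, "fnirs_dataset")) x <- x$data
  set.seed(as.integer(seed))
  acc <- sdv <- numeric(length(sigmas))
  for (i in seq_along(sigmas)) {
    s <- sigmas[i]
    if (s == 0) {
      pred <- predict(model, x, type = "class")
      acc[i] <- mean(pred == y); sdv[i] <- 0
    } else {
      a <- numeric(reps)
      for (r in seq_len(reps)) {
        xn <- x + array(stats::rnorm(length(x), 0, s), dim(x))
        pred <- predict(model, xn, type = "class")
        a[r] <- mean(pred == y)
      }
      acc[i] <- mean(a); sdv[i] <- stats::sd(a)
    }
  }
  structure(list(curve = data.frame(sigma = sigmas, accuracy = acc, sd = sdv),
                 auc_robustness = .robustness_auc(sigmas, acc),
                 clean_accuracy = acc[1], reps = reps),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("Noise robustness (reps=%d): AUC_robustness = %.3f\n",
              x$reps, x$auc_robustness))
  print(round(x$curve, 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.robustness_curve <- function(x, ...) {
  plot(x$curve$sigma, x$curve$accuracy, type = "b", ylim = c(0, 1),
       xlab = expression(sigma), ylab = "accuracy",
       main = sprintf("AUC_robustness = %.3f", x$auc_robustness))
  graphics::abline(h = 1 / 3, col = "grey", lty = 3)
  invisible(x)
}

# ---- effect sizes and ANOVA power ------------------------------------------

#' Cohen's d for two independent groups
#'
#' `(mean2 - mean1) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 First group summary statistics.
#' @param mean2,sd2,n2 Second group summary statistics.
#' @return Cohen's d.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("cohens_d: standard deviations must be positive")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("cohens_d: pooled standard deviation is zero")
  (mean2 - mean1) / sp
}

#' Cohen's f from eta squared
#'
#' `f = sqrt(eta2 / (1 - eta2))`.
#'
#' @param eta2 Eta squared in `[0, 1)`.
#' @return Cohen's f.
#' @export
cohens_f_from_eta2 <- function(eta2) {
  if (eta2 < 0 || eta2 >= 1) stop("eta2 must be in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' One-way ANOVA power from the noncentral F distribution
#'
#' Power of the k-group one-way ANOVA at total sample size `N` for effect
#' size Cohen's f: noncentrality `lambda = f^2 N`, degrees of freedom
#' `(k - 1, N - k)`.
#'
#' @param f Cohen's f (> 0).
#' @param k Number of groups (>= 2).
#' @param N Total sample size (> k).
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @export
anova_power <- function(f, k = 3, N, alpha = 0.05) {
  if (f <= 0) stop("f must be positive")
  if (k < 2) stop("k must be >= 2")
  if (N <= k) stop("N must exceed the number of groups")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df2 <- N - k
  crit <- stats::qf(1 - alpha, k - 1, df2)
  stats::pf(crit, k - 1, df2, ncp = f^2 * N, lower.tail = FALSE)
}

#' Minimum total sample size for a one-way ANOVA
#'
#' Smallest total `N` (equal allocation across `k` groups) whose power under
#' the noncentral F distribution reaches the target. With `f = 0.30`,
#' `k = 3`, `alpha = 0.05` and power 0.80 this returns 111.
#'
#' @param f Cohen's f (> 0).
#' @param k Number of groups.
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param max_n Search bound.
#' @return Minimum total N.
#' @export
anova_sample_size <- function(f, k = 3, alpha = 0.05, power = 0.80,
                              max_n = 1e6) {
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  for (N in (k + 1):max_n)
    if (anova_power(f, k, N, alpha) >= power) return(N)
  stop("anova_sample_size: target power unattainable below max_n")
}
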