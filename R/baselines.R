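# Classical comparators: SVM, random forest, distance-weighted kNN and a
# two-hidden-layer back-propagation network, all consuming per-subject
# feature vectors and emitting class probabilities through the same
# predict() contract as the deep models.

#' Per-subject feature matrix for the classical models
#'
#' The classical comparators cannot consume the raw channels x time series;
#' `mode = "summary"` (the package's own featurisation, clearly a design
#' choice) computes per channel the task-block mean, rest mean, task-rest
#' difference, standard deviation and linear slope (5 x 22 = 110 features).
#' Task windows are shifted by `shift_s` seconds to account for haemodynamic
#' delay. `mode = "flatten"` concatenates the (optionally decimated) series.
#'
#' @param dataset An `fnirs_dataset`, or an `N x C x T` array with `design`
#'   and labels supplied separately.
#' @param mode `"summary"` or `"flatten"`.
#' @param design Block design (taken from the dataset if available).
#' @param shift_s Haemodynamic shift applied to the task mask, seconds.
#' @param flatten_hz Decimation rate for `mode = "flatten"`.
#' @return A numeric matrix `N x F` with named columns, class
#'   `feature_matrix`, labels (if known) in attribute `labels`.
#' @export
featurize <- function(dataset, mode = c("summary", "flatten"), design = NULL,
                      shift_s = 5, flatten_hz = 1) {
  mode <- match.arg(mode)
  labels <- NULL
  if (inherits(dataset, "fnirs_dataset")) {
    x <- dataset$data; design <- dataset$design; labels <- dataset$labels
    fs <- dataset$sampling_hz; channels <- dataset$channel_ids
  } else {
    x <- dataset
    if (is.null(design)) stop("featurize: design required for array input")
    fs <- dim(x)[3] / design$total_s
    channels <- sprintf("CH%02d", seq_len(dim(x)[2]))
  }
  n <- dim(x)[1]; nch <- dim(x)[2]; nt <- dim(x)[3]
  if (mode == "flatten") {
    fac <- max(1L, as.integer(round(fs / flatten_hz)))
    keep <- seq(1, nt, by = fac)
    out <- matrix(NA_real_, n, nch * length(keep))
    for (s in seq_len(n)) out[s, ] <- as.numeric(t(x[s, , keep]))
    colnames(out) <- paste0(rep(channels, each = length(keep)), "_t",
                            rep(seq_along(keep), nch))
  } else {
    # phase masks at the dataset rate, task shifted by the haemodynamic delay
    ph_design <- block_design(design$pre_task_s, design$rest_before_s,
                              design$task_s, design$rest_after_s,
                              design$n_cycles, design$total_s, fs)
    ph <- design_phases(ph_design)
    shift <- round(shift_s * fs)
    task <- c(rep(FALSE, shift), ph == "task")[seq_len(nt)]
    rest <- !task & c(rep(TRUE, shift), ph %in% c("rest1", "rest2", "residual"))[seq_len(nt)]
    tt <- seq_len(nt) / fs
    stats_names <- c("task_mean", "rest_mean", "task_rest_diff", "sd", "slope")
    out <- matrix(NA_real_, n, nch * 5)
    colnames(out) <- paste0(rep(channels, each = 5), "_", rep(stats_names, nch))
    for (s in seq_len(n)) for (i in seq_len(nch)) {
      v <- x[s, i, ]
      tm <- mean(v[task]); rm_ <- mean(v[rest])
      sl <- stats::cov(tt, v) / stats::var(tt)
      out[s, (i - 1) * 5 + 1:5] <- c(tm, rm_, tm - rm_, stats::sd(v), sl)
    }
  }
  structure(out, labels = labels, mode = mode, class = c("feature_matrix", "matrix"))
}

.scale_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"), center = center, scale = scale)
}

#' Fit a classical baseline classifier
#'
#' The four comparators with their fixed hyperparameters: SVM (RBF kernel,
#' `C = 0.8`, `gamma = "scale"` i.e. `1/(F * var(X))`, pairwise-coupled
#' probabilities), random forest (80 trees, depth 8, minimum node size 8),
#' k-nearest neighbours (`k = 7`, inverse-distance weights) and a
#' back-propagation network (hidden layers 80 and 40, L2 `alpha = 0.02`,
#' 180 iterations). Features are standardised on the training data only; the
#' scaling is stored with the fit.
#'
#' @param name `"svm"`, `"rf"`, `"knn"` or `"bpnn"`.
#' @param features Numeric feature matrix (`N x F`), e.g. from [featurize()].
#' @param labels Class labels.
#' @param seed Seed (forest bootstrap, network initialisation).
#' @return An object of class
#'   `c("baseline_<name>", "baseline_fit", "fnirs_classifier")` whose
#'   `predict` method returns class probabilities.
#' @export
fit_baseline <- function(name = c("svm", "rf", "knn", "bpnn"), features, labels,
                         seed = 1) {
  name <- match.arg(name)
  y <- factor(labels, levels = c("HC", "HY1", "HY2"))
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("fit_baseline: features must be finite")
  sc <- .scale_features(x)
  xs <- sc$x
  set.seed(as.integer(seed))
  fit <- switch(name,
    svm = {
      gam <- 1 / (ncol(xs) * max(stats::var(as.numeric(xs)), 1e-12))
      e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                 cost = 0.8, gamma = gam, probability = TRUE)
    },
    rf = ranger::ranger(x = xs, y = y, num.trees = 80, max.depth = 8,
                        min.node.size = 8, probability = TRUE, seed = seed,
                        num.threads = 1),
    knn = list(x = xs, y = y, k = 7),
    bpnn = .fit_mlp(xs, as.integer(y), hidden = c(80, 40), alpha = 0.02,
                    max_iter = 180, n_classes = nlevels(y))
  )
  structure(list(name = name, fit = fit, center = sc$center, scale = sc$scale,
                 classes = levels(y)),
            class = c(paste0("baseline_", name), "baseline_fit", "fnirs_classifier"))
}

#' Fit a classical baseline directly on the dataset tensor
#'
#' Convenience wrapper around [featurize()] + [fit_baseline()] that stores
#' the featurisation recipe with the fit, so the returned classifier accepts
#' the `N x channels x time` tensor in `predict()` (and hence works with the
#' tensor-level interpretability tools such as [permutation_importance()]).
#'
#' @param name Baseline name, see [fit_baseline()].
#' @param dataset An `fnirs_dataset` (or tensor plus `design`).
#' @param labels Class labels; taken from the dataset if omitted.
#' @param mode,design,shift_s Passed to [featurize()].
#' @param seed Seed for the underlying fit.
#' @return A `baseline_fit` whose `predict` method featurises tensor input
#'   with the stored recipe.
#' @export
fit_baseline_tensor <- function(name, dataset, labels = NULL,
                                mode = "summary", design = NULL, shift_s = 5,
                                seed = 1) {
  if (inherits(dataset, "fnirs_dataset")) {
    if (is.null(labels)) labels <- dataset$labels
    if (is.null(design)) design <- dataset$design
  }
  f <- featurize(dataset, mode = mode, design = design, shift_s = shift_s)
  fit <- fit_baseline(name, f, labels, seed = seed)
  fit$recipe <- list(mode = mode, design = design, shift_s = shift_s)
  fit
}

#' @export
predict.baseline_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fnirs_dataset") ||
      (is.array(newdata) && length(dim(newdata)) == 3)) {
    if (is.null(object$recipe))
      stop("this baseline was fitted on features; tensor input needs fit_baseline_tensor()")
    newdata <- featurize(newdata, mode = object$recipe$mode,
                         design = object$recipe$design,
                         shift_s = object$recipe$shift_s)
  }
  x <- .scale_features(as.matrix(newdata), object$center, object$scale)$x
  pr <- switch(object$name,
    svm = attr(stats::predict(object$fit, x, probability = TRUE), "probabilities"),
    rf = stats::predict(object$fit, data = x, num.threads = 1)$predictions,
    knn = .predict_knn(object$fit, x),
    bpnn = .predict_mlp(object$fit, x)
  )
  # align to the full class set (a class absent from training gets 0)
  if (is.null(colnames(pr))) colnames(pr) <- object$classes
  full <- matrix(0, nrow(pr), length(object$classes),
                 dimnames = list(NULL, object$classes))
  keep <- intersect(colnames(pr), object$classes)
  full[, keep] <- pr[, keep, drop = FALSE]
  pr <- full
  pr <- pr / rowSums(pr)
  if (type == "class") factor(object$classes[max.col(pr, ties.method = "first")],
                              levels = object$classes)
  else pr
}

# distance-weighted kNN with exact-match short-circuit
.predict_knn <- function(fit, x) {
  k <- fit$k
  n <- nrow(x)
  classes <- levels(fit$y)
  pr <- matrix(0, n, length(classes))
  for (i in seq_len(n)) {
    d2 <- colSums((t(fit$x) - x[i, ])^2)
    nn <- order(d2)[seq_len(min(k, length(d2)))]
    dd <- sqrt(d2[nn])
    if (any(dd == 0)) {
      hit <- nn[dd == 0]
      tab <- table(factor(fit$y[hit], levels = classes))
      pr[i, ] <- as.numeric(tab) / sum(tab)
    } else {
      w <- 1 / dd
      for (j in seq_along(nn)) {
        cl <- as.integer(fit$y[nn[j]])
        pr[i, cl] <- pr[i, cl] + w[j]
      }
      pr[i, ] <- pr[i, ] / sum(pr[i, ])
    }
  }
  colnames(pr) <- classes
  pr
}

# two-hidden-layer MLP (ReLU, Adam, L2) -- nnet only offers one hidden layer
.fit_mlp <- function(x, y_int, hidden, alpha, max_iter, n_classes,
                     lr = 1e-3) {
  dims <- c(ncol(x), hidden, n_classes)
  params <- list()
  for (l in seq_len(length(dims) - 1))
    params[[paste0("l", l)]] <- .init_linear(dims[l], dims[l + 1])
  opt <- .adam_new(params)
  n <- nrow(x)
  batch <- min(200L, n)
  for (it in seq_len(max_iter)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1, n)]
      xb <- x[idx, , drop = FALSE]; yb <- y_int[idx]
      acts <- list(xb); pre <- list()
      a <- xb
      for (l in seq_len(length(dims) - 1)) {
        z <- .linear_fwd(params[[l]], a)
        pre[[l]] <- z
        a <- if (l < length(dims) - 1) pmax(z, 0) else z
        acts[[l + 1]] <- a
      }
      probs <- .softmax_rows(a)
      dz <- probs
      dz[cbind(seq_along(yb), yb)] <- dz[cbind(seq_along(yb), yb)] - 1
      dz <- dz / length(yb)
      grads <- list()
      for (l in rev(seq_len(length(dims) - 1))) {
        bw <- .linear_bwd(params[[l]], acts[[l]], dz)
        grads[[paste0("l", l)]] <- bw$grads
        if (l > 1) dz <- bw$dx * (pre[[l - 1]] > 0)
      }
      st <- .adam_step(params, grads[names(params)], opt, lr, l2 = alpha / 2)
      params <- st$params; opt <- st$state
    }
  }
  list(params = params, dims = dims)
}

.predict_mlp <- function(fit, x) {
  a <- x
  nl <- length(fit$dims) - 1
  for (l in seq_len(nl)) {
    z <- .linear_fwd(fit$params[[l]], a)
    a <- if (l < nl) pmax(z, 0) else z
  }
  .softmax_rows(a)
}

#' Stratified k-fold cross-validation of a baseline
#'
#' Runs stratified `folds`-fold cross-validation (remainders rotated across
#' folds so sizes are as equal as possible) with feature standardisation
#' fitted inside each training fold, then refits on all data for the final
#' model.
#'
#' @param name Baseline name, see [fit_baseline()].
#' @param features Feature matrix.
#' @param labels Class labels.
#' @param folds Number of folds (>= 2).
#' @param seed Fold-assignment seed.
#' @return List with `scores` (data frame: fold, n, accuracy, macro_f1),
#'   `mean_accuracy`, `fold` assignment vector, and `final_fit` (refit on all
#'   data).
#' @export
cross_validate <- function(name, features, labels, folds = 5, seed = 1) {
  if (folds < 2) stop("cross_validate: folds must be >= 2")
  y <- factor(labels, levels = c("HC", "HY1", "HY2"))
  x <- as.matrix(features)
  fold <- .stratified_folds(y, folds, seed)
  res <- data.frame(fold = integer(0), n = integer(0), accuracy = numeric(0),
                    macro_f1 = numeric(0))
  for (k in seq_len(folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    fit <- fit_baseline(name, x[tr, , drop = FALSE], y[tr], seed = seed)
    pred <- predict(fit, x[te, , drop = FALSE], type = "class")
    cm <- table(truth = y[te], pred = factor(pred, levels = levels(y)))
    res <- rbind(res, data.frame(fold = k, n = length(te),
                                 accuracy = mean(pred == y[te]),
                                 macro_f1 = .macro_f1(cm)))
  }
  list(scores = res, mean_accuracy = mean(res$accuracy), fold = fold,
       final_fit = fit_baseline(name, x, y, seed = seed))
}

.macro_f1 <- function(cm) {
  f1 <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}
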