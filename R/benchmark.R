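#' The twelve-classifier suite
#'
#' Returns the twelve classifier configurations benchmarked against each
#' feature set, mirroring the common "preset" variants of classical learners:
#' a CART decision tree (DT), linear discriminant analysis (LDA), kernel
#' naive Bayes (KNB), six support vector machines (linear, quadratic, cubic,
#' and fine/medium/coarse Gaussian: LSVM, QSVM, CSVM, FGSVM, MGSVM, CGSVM)
#' and three k-nearest-neighbour variants (fine/medium/coarse: FKNN with
#' k = 1, MKNN with k = 10, CKNN with k = 100). Gaussian kernel scales are
#' `sqrt(P)/4`, `sqrt(P)` and `4*sqrt(P)` for `P` features; SVMs are
#' one-vs-one with box constraint 1 on z-scored features.
#'
#' @param overrides Named list of per-model hyperparameter overrides, e.g.
#'   `list(FKNN = list(k = 3))`.
#' @return A tibble of class `classifier_suite` with columns `id`, `family`
#'   and `hyperparameters` (list column), in the canonical reporting order.
#' @export
#' @examples
#' make_classifier_suite()$id
make_classifier_suite <- function(overrides = list()) {
  spec <- function(id, family, ...) {
    tibble(id = id, family = family, hyperparameters = list(list(...)))
  }
  out <- dplyr::bind_rows(
    spec("DT", "tree", criterion = "gini", cp = 1e-4, minsplit = 2),
    spec("LDA", "lda"),
    spec("KNB", "kernel_nb", bandwidth = "silverman"),
    spec("LSVM", "svm", kernel = "linear", cost = 1),
    spec("QSVM", "svm", kernel = "polynomial", degree = 2, cost = 1),
    spec("CSVM", "svm", kernel = "polynomial", degree = 3, cost = 1),
    spec("FGSVM", "svm", kernel = "radial", scale_factor = 0.25, cost = 1),
    spec("MGSVM", "svm", kernel = "radial", scale_factor = 1, cost = 1),
    spec("CGSVM", "svm", kernel = "radial", scale_factor = 4, cost = 1),
    spec("FKNN", "knn", k = 1),
    spec("MKNN", "knn", k = 10),
    spec("CKNN", "knn", k = 100)
  )
  for (id in names(overrides)) {
    i <- match(id, out$id)
    if (is.na(i)) abort(sprintf("Unknown classifier id '%s'.", id))
    out$hyperparameters[[i]] <- utils::modifyList(out$hyperparameters[[i]],
                                                  overrides[[id]])
  }
  class(out) <- c("classifier_suite", class(out))
  out
}

#' Evaluation protocol
#'
#' Stratified 80:20 outer split with stratified 10-fold cross-validation
#' inside the training partition. Feature standardisation (z-scoring) is
#' fitted on training data only — the outer training partition for the
#' held-out estimate, and the in-fold training rows for each CV fold — so no
#' test information leaks into the scaling.
#'
#' @param train_fraction Fraction of rows used for training (default 0.8; the
#'   remaining 20% form the held-out validation set).
#' @param cv_folds Number of cross-validation folds (>= 2, default 10).
#' @param stratified Stratify split and folds by class (default `TRUE`).
#' @param seed Integer seed controlling the split, fold assignment and any
#'   randomised learner internals.
#' @param standardize Z-score features from training statistics.
#' @return A list of class `eval_protocol`.
#' @export
eval_protocol <- function(train_fraction = 0.8, cv_folds = 10,
                          stratified = TRUE, seed = 1, standardize = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).")
  }
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  structure(
    list(train_fraction = train_fraction,
         test_fraction = 1 - train_fraction, cv_folds = cv_folds,
         stratified = stratified, seed = seed, standardize = standardize),
    class = "eval_protocol"
  )
}

# Coerce a feature table to a numeric matrix, dropping metadata columns.
feature_matrix <- function(features) {
  df <- as.data.frame(features)
  drop <- intersect(c("signal_id", "class", "window_index"), names(df))
  df <- df[setdiff(names(df), drop)]
  m <- as.matrix(df)
  if (!is.numeric(m)) abort("Feature columns must be numeric.")
  m
}

# Stratified index split: per class, shuffle and take the first
# round(frac * n) rows for training.
stratified_split <- function(labels, frac, stratified = TRUE) {
  idx <- seq_along(labels)
  if (!stratified) {
    tr <- sample(idx, round(frac * length(idx)))
    return(list(train = sort(tr), test = sort(setdiff(idx, tr))))
  }
  tr <- unlist(lapply(split(idx, labels), function(ii) {
    ii <- sample(ii)
    ii[seq_len(round(frac * length(ii)))]
  }), use.names = FALSE)
  list(train = sort(tr), test = sort(setdiff(idx, tr)))
}

# Stratified fold assignment over the given indices.
stratified_folds <- function(labels, idx, k, stratified = TRUE) {
  fold <- integer(length(idx))
  if (!stratified) {
    fold <- sample(rep_len(seq_len(k), length(idx)))
  } else {
    for (cl in unique(labels[idx])) {
      ii <- which(labels[idx] == cl)
      fold[sample(ii)] <- rep_len(seq_len(k), length(ii))
    }
  }
  fold
}

# Fit scaling on the training rows only; returns transformed train/test.
standardize_fit <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  keep <- sdv > 1e-12
  if (!any(keep)) abort("All features are constant in the training split.")
  list(train = scale(xtr[, keep, drop = FALSE], mu[keep], sdv[keep]),
       test = scale(xte[, keep, drop = FALSE], mu[keep], sdv[keep]))
}

# Hand-rolled kernel naive Bayes: per class and feature, a Gaussian KDE with
# Silverman's bandwidth; prediction maximises the log posterior.
fit_kernel_nb <- function(x, y) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    bw <- apply(xi, 2, function(v) {
      h <- 0.9 * min(sd(v), stats::IQR(v) / 1.34) * length(v)^(-1 / 5)
      if (!is.finite(h) || h <= 0) h <- max(sd(v), 1e-6) * length(v)^(-1 / 5)
      if (!is.finite(h) || h <= 0) h <- 1e-6
      h
    })
    list(x = xi, bw = bw, prior = mean(y == cl))
  })
  names(models) <- classes
  structure(list(models = models, classes = classes), class = "aewear_knb")
}

predict_kernel_nb <- function(fit, newx) {
  ll <- sapply(fit$models, function(m) {
    s <- rep(log(m$prior), nrow(newx))
    for (j in seq_len(ncol(newx))) {
      # KDE evaluated for all test points at once: outer difference against
      # the class's training values for this feature
      d <- outer(newx[, j], m$x[, j], "-") / m$bw[j]
      dens <- rowMeans(stats::dnorm(d)) / m$bw[j]
      s <- s + log(pmax(dens, 1e-300))
    }
    s
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  factor(fit$classes[max.col(ll, ties.method = "first")],
         levels = fit$classes)
}

# Fit one classifier spec and predict test labels.
fit_predict <- function(x_train, y_train, x_test, spec) {
  hp <- spec$hyperparameters[[1]]
  fam <- spec$family
  if (fam == "tree") {
    df <- data.frame(.y = y_train, x_train, check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = hp$cp, minsplit = hp$minsplit, xval = 0))
    nd <- data.frame(x_test, check.names = FALSE)
    factor(predict(fit, nd, type = "class"), levels = levels(y_train))
  } else if (fam == "lda") {
    # pooled-covariance linear discriminant; when the feature count
    # approaches the training size the pooled covariance is singular, so
    # project onto the leading principal components first (pseudo-linear
    # discriminant, the standard behaviour of preset LDA implementations)
    max_rank <- nrow(x_train) - nlevels(y_train) - 1L
    if (ncol(x_train) > max_rank) {
      pc <- prcomp(x_train, center = TRUE, scale. = FALSE)
      cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      k <- min(which(cumvar >= 0.999)[1], max_rank, na.rm = TRUE)
      keep <- seq_len(k)
      rot <- pc$rotation[, keep, drop = FALSE]
      ctr <- pc$center
      x_train <- sweep(x_train, 2, ctr) %*% rot
      x_test <- sweep(x_test, 2, ctr) %*% rot
    }
    # near-duplicate features (e.g. RMS/SSI/VAR) trigger a collinearity
    # warning that is expected here and handled by lda's internal tolerance
    fit <- withCallingHandlers(
      MASS::lda(x_train, grouping = y_train),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    predict(fit, x_test)$class
  } else if (fam == "kernel_nb") {
    predict_kernel_nb(fit_kernel_nb(x_train, y_train), x_test)
  } else if (fam == "svm") {
    p <- ncol(x_train)
    args <- list(x = x_train, y = y_train, type = "C-classification",
                 kernel = hp$kernel, cost = hp$cost, scale = FALSE)
    if (hp$kernel == "polynomial") {
      args$degree <- hp$degree
      args$gamma <- 1 / p
      args$coef0 <- 1
    }
    if (hp$kernel == "radial") {
      args$gamma <- 1 / (hp$scale_factor * sqrt(p))^2
    }
    fit <- do.call(e1071::svm, args)
    predict(fit, x_test)
  } else if (fam == "knn") {
    k <- min(hp$k, nrow(x_train))
    class::knn(x_train, x_test, cl = y_train, k = k)
  } else {
    abort(sprintf("Unknown classifier family '%s'.", fam))
  }
}

#' Train and evaluate one classifier under the validation protocol
#'
#' Performs the stratified 80:20 split, reports held-out accuracy on the 20%
#' partition, and mean stratified 10-fold CV accuracy computed entirely
#' within the 80% training partition (test rows never enter any fold).
#'
#' @param features Feature table (tibble/data.frame; metadata columns
#'   `signal_id`, `class`, `window_index` are dropped automatically) or
#'   numeric matrix. All entries must be finite.
#' @param labels Class labels, one per row.
#' @param spec One row of [make_classifier_suite()].
#' @param protocol An [eval_protocol()].
#' @return One-row tibble: `model`, `holdout_accuracy`, `cv_accuracy`
#'   (percent).
#' @export
train_evaluate <- function(features, labels, spec, protocol = eval_protocol()) {
  x <- feature_matrix(features)
  if (!all(is.finite(x))) abort("Non-finite feature values.")
  y <- factor(labels)
  if (nrow(x) != length(y)) abort("Row count mismatch features vs labels.")
  withr::with_seed(protocol$seed, {
    split <- stratified_split(y, protocol$train_fraction, protocol$stratified)
    if (any(table(y[split$train]) < 2)) {
      abort("Each class needs >= 2 training samples.",
            class = "aewear_stratification_error")
    }
    fold <- stratified_folds(y, split$train, protocol$cv_folds,
                             protocol$stratified)
    prep <- function(tr_idx, te_idx) {
      if (protocol$standardize) {
        standardize_fit(x[tr_idx, , drop = FALSE], x[te_idx, , drop = FALSE])
      } else {
        list(train = x[tr_idx, , drop = FALSE],
             test = x[te_idx, , drop = FALSE])
      }
    }
    d <- prep(split$train, split$test)
    pred <- fit_predict(d$train, y[split$train], d$test, spec)
    holdout <- 100 * mean(pred == y[split$test])
    cv_acc <- purrr::map_dbl(seq_len(protocol$cv_folds), function(f) {
      tr <- split$train[fold != f]
      te <- split$train[fold == f]
      if (length(te) == 0) return(NA_real_)
      d <- prep(tr, te)
      100 * mean(fit_predict(d$train, y[tr], d$test, spec) == y[te])
    })
    tibble(model = spec$id, holdout_accuracy = holdout,
           cv_accuracy = mean(cv_acc, na.rm = TRUE))
  })
}

#' Aggregate twelve per-model accuracies as mean and population SD
#'
#' The dispersion uses the population formula (divide by N, not N - 1); this
#' is the convention that reproduces the reported "mean +/- std" row from a
#' column of twelve per-model accuracies.
#'
#' @param accuracies Numeric vector of exactly 12 accuracies in `[0, 100]`.
#' @return A tibble with columns `mean_accuracy` and `std_accuracy`.
#' @export
#' @examples
#' aggregate_accuracies(c(82, 100, 78, 94, 94, 96, 90, 96, 92, 96, 80, 82))
aggregate_accuracies <- function(accuracies) {
  if (length(accuracies) != 12) {
    abort("Expected exactly 12 per-model accuracies.")
  }
  if (any(accuracies < 0 | accuracies > 100)) {
    abort("Accuracies must lie in [0, 100].")
  }
  m <- mean(accuracies)
  tibble(mean_accuracy = m,
         std_accuracy = sqrt(mean((accuracies - m)^2)))
}

#' Benchmark both feature sets across the twelve classifiers
#'
#' Runs [train_evaluate()] for every classifier on the handcrafted feature
#' table and on the scattering (DWS) feature table, aligned to the same
#' windows and labels, and aggregates each column of twelve accuracies as
#' mean and population SD.
#'
#' @param handcrafted,dws Feature tables over the same windows (equal row
#'   counts, same order).
#' @param labels Class labels, one per window. Defaults to the `class`
#'   column of `handcrafted` when present.
#' @param protocol An [eval_protocol()].
#' @param suite A [make_classifier_suite()].
#' @return An object of class `ae_benchmark`: list with `results` (tibble:
#'   `feature_set`, `model`, `holdout_accuracy`, `cv_accuracy`) and
#'   `aggregate` (per feature set and accuracy kind).
#' @export
run_benchmark <- function(handcrafted, dws, labels = NULL,
                          protocol = eval_protocol(),
                          suite = make_classifier_suite()) {
  if (is.null(labels)) {
    if (!"class" %in% names(handcrafted)) {
      abort("Provide `labels` or a `class` column.")
    }
    labels <- handcrafted$class
  }
  if (nrow(handcrafted) != nrow(dws)) {
    abort("`handcrafted` and `dws` must describe the same windows.")
  }
  if (nrow(handcrafted) != length(labels)) {
    abort("Row count mismatch features vs labels.")
  }
  sets <- list(handcrafted = handcrafted, dws = dws)
  results <- purrr::imap(sets, function(tbl, nm) {
    purrr::map(seq_len(nrow(suite)),
               ~ train_evaluate(tbl, labels, suite[.x, ], protocol)) |>
      dplyr::bind_rows() |>
      dplyr::mutate(feature_set = nm, .before = 1)
  }) |>
    dplyr::bind_rows()
  agg <- results |>
    tidyr::pivot_longer(c("holdout_accuracy", "cv_accuracy"),
                        names_to = "metric", values_to = "accuracy") |>
    dplyr::group_by(.data$feature_set, .data$metric) |>
    dplyr::summarise(aggregate_accuracies(.data$accuracy), .groups = "drop")
  structure(list(results = results, aggregate = agg, protocol = protocol),
            class = "ae_benchmark")
}

#' @export
print.ae_benchmark <- function(x, ...) {
  cat("<ae_benchmark>\n")
  print(tidyr::pivot_wider(x$results, names_from = "feature_set",
                           values_from = c("holdout_accuracy",
                                           "cv_accuracy")))
  cat("\nAggregate (mean +/- population SD):\n")
  print(x$aggregate)
  invisible(x)
}

#' @rdname run_benchmark
#' @param x An `ae_benchmark`.
#' @param ... Unused.
#' @export
tidy.ae_benchmark <- function(x, ...) x$results

#' @rdname run_benchmark
#' @export
glance.ae_benchmark <- function(x, ...) {
  tidyr::pivot_wider(x$aggregate, names_from = c("feature_set", "metric"),
                     values_from = c("mean_accuracy", "std_accuracy"))
}

#' @rdname run_benchmark
#' @param object An `ae_benchmark`.
#' @export
autoplot.ae_benchmark <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$model, levels = make_classifier_suite()$id),
    y = .data$holdout_accuracy, fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Held-out accuracy (%)",
                  fill = "Feature set") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
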