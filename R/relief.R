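#' ReliefF feature weighting and ranking
#'
#' Multiclass ReliefF: every instance is visited (no sampling, so the result
#' is deterministic); for each instance the `k` nearest same-class hits and,
#' for every other class, the `k` nearest misses are found by Manhattan
#' distance on range-normalised features. Weights are updated with
#' range-normalised feature differences, miss contributions weighted by the
#' class prior renormalised over the other classes,
#' `P(C) / (1 - P(class(i)))`. Features that differ between near misses and
#' agree between near hits receive large weights.
#'
#' Distance ties are broken by row order, and range normalisation makes the
#' weights invariant to positive rescaling of any feature column.
#'
#' @param features Feature table (metadata columns `signal_id`, `class`,
#'   `window_index` are dropped) or numeric matrix; all values finite.
#' @param labels Class labels, one per row. Defaults to the `class` column.
#' @param k_neighbors Number of hits/misses per class (default 10). Every
#'   class must have more than `k_neighbors` members.
#' @return An object of class `ae_relief`: list with `weights` (named
#'   numeric), `ranking` (feature names by descending weight), `k_neighbors`,
#'   `n_sampled`.
#' @export
#' @examples
#' x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' x[, 1] <- x[, 1] + rep(c(0, 6), each = 10)
#' relieff_weights(x, rep(c("u", "v"), each = 10), k_neighbors = 3)$ranking
relieff_weights <- function(features, labels = NULL, k_neighbors = 10) {
  if (is.null(labels)) {
    if (!"class" %in% colnames(features)) {
      abort("Provide `labels` or a `class` column.")
    }
    labels <- features$class
  }
  x <- feature_matrix(features)
  if (!all(is.finite(x))) abort("Non-finite feature values.")
  y <- factor(labels)
  n <- nrow(x)
  if (length(y) != n) abort("Row count mismatch features vs labels.")
  counts <- table(y)
  if (any(counts <= k_neighbors)) {
    abort(sprintf(
      "Every class needs more than k_neighbors = %d members (smallest has %d); use a smaller k.",
      k_neighbors, min(counts)))
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- Inf            # constant features contribute zero diff
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  priors <- as.numeric(counts) / n
  names(priors) <- names(counts)
  w <- numeric(ncol(x))
  k <- k_neighbors
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(xn, 2, xn[i, ])))
    d[i] <- Inf
    for (cl in levels(y)) {
      members <- which(y == cl & d < Inf)
      nb <- members[order(d[members])[seq_len(k)]]
      diffs <- colMeans(abs(sweep(xn[nb, , drop = FALSE], 2, xn[i, ])))
      if (cl == as.character(y[i])) {
        w <- w - diffs / n
      } else {
        w <- w + priors[[cl]] / (1 - priors[[as.character(y[i])]]) * diffs / n
      }
    }
  }
  names(w) <- colnames(x)
  structure(
    list(weights = w, ranking = names(sort(w, decreasing = TRUE)),
         k_neighbors = k_neighbors, n_sampled = n),
    class = "ae_relief"
  )
}

#' @export
print.ae_relief <- function(x, ...) {
  cat(sprintf("<ae_relief: %d features, k = %d, %d instances>\n",
              length(x$weights), x$k_neighbors, x$n_sampled))
  print(utils::head(tidy(x), 10))
  invisible(x)
}

#' @rdname relieff_weights
#' @param x An `ae_relief`.
#' @param ... Unused.
#' @export
tidy.ae_relief <- function(x, ...) {
  tibble(feature = x$ranking,
         weight = as.numeric(x$weights[x$ranking]),
         rank = seq_along(x$ranking))
}

#' @rdname relieff_weights
#' @param object An `ae_relief`.
#' @export
autoplot.ae_relief <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$weight,
    y = stats::reorder(.data$feature, .data$weight))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$feature),
                          colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ReliefF weight", y = NULL) +
    ggplot2::theme_minimal()
}
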