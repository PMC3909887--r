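#' Numerically stable softmax
#'
#' `softmax(q)_i = exp(q_i) / sum_j exp(q_j)`, computed with
#' max-subtraction so very large inputs do not overflow. The output is a
#' probability vector: every component in (0, 1), summing to 1.
#'
#' @param q finite numeric vector (non-empty).
#' @return Probability vector of the same length.
#' @export
#' @examples
#' softmax(c(log(3), 0))   # 0.75 0.25
softmax <- function(q) {
  if (length(q) == 0L) stop("empty input to softmax")
  if (any(!is.finite(q))) stop("non-finite input to softmax")
  z <- exp(q - max(q))
  z / sum(z)
}

#' Softmax competitive-layer classifier
#'
#' Linear map plus softmax over the ten number classes. Created untrained
#' (zero weights give the uniform distribution) or by [train_classifier()].
#'
#' @param input_dim feature dimension d.
#' @param n_classes number of classes.
#' @param seed optional seed for uniform(-0.5, 0.5) initialization.
#' @return Object of class `softmax_classifier` with `weights` (d x
#'   n_classes), `bias` (length n_classes) and `input_dim`.
#' @export
softmax_classifier <- function(input_dim, n_classes = 10, seed = NULL) {
  n_par <- input_dim * n_classes + n_classes
  p <- if (is.null(seed)) rep(0, n_par)
       else with_seed(seed, stats::runif(n_par, -0.5, 0.5))
  clf <- structure(list(input_dim = input_dim, n_classes = n_classes),
                   class = "softmax_classifier")
  set_clf_params(clf, p)
}

clf_params <- function(clf) c(as.numeric(clf$weights), clf$bias)

set_clf_params <- function(clf, p) {
  d <- clf$input_dim; k <- clf$n_classes
  clf$weights <- matrix(p[seq_len(d * k)], d, k)
  clf$bias <- p[d * k + seq_len(k)]
  clf
}

#' Classify a feature vector
#'
#' @param clf a `softmax_classifier`.
#' @param x feature vector of length `input_dim`.
#' @return Probability vector over the classes (sums to 1). The predicted
#'   class is the argmax, ties broken toward the lower class index.
#' @export
classify <- function(clf, x) {
  stopifnot(inherits(clf, "softmax_classifier"))
  if (length(x) != clf$input_dim)
    stop("feature length ", length(x), " != input_dim ", clf$input_dim)
  softmax(as.numeric(crossprod(clf$weights, x)) + clf$bias)
}

#' Predicted class (argmax, low-index tie break)
#'
#' @param clf a `softmax_classifier`.
#' @param x feature vector.
#' @return Integer class index.
#' @export
predict_class <- function(clf, x) {
  p <- classify(clf, x)
  which.max(p)  # which.max already prefers the first (lowest) index on ties
}

# residuals/Jacobian of softmax outputs vs one-hot targets over all samples
clf_residuals <- function(clf, X, labels) {
  r <- numeric(nrow(X) * clf$n_classes)
  for (s in seq_len(nrow(X))) {
    p <- classify(clf, X[s, ])
    tgt <- numeric(clf$n_classes); tgt[labels[s]] <- 1
    r[(s - 1) * clf$n_classes + seq_len(clf$n_classes)] <- p - tgt
  }
  r
}

clf_jacobian <- function(clf, X, labels) {
  d <- clf$input_dim; k <- clf$n_classes
  J <- matrix(0, nrow(X) * k, d * k + k)
  Ik <- diag(k)
  for (s in seq_len(nrow(X))) {
    x <- X[s, ]
    p <- classify(clf, x)
    dpdq <- diag(p) - tcrossprod(p)            # softmax derivative
    dqdW <- kronecker(Ik, matrix(x, 1, d))     # dq_i/dvec(W)
    J[(s - 1) * k + seq_len(k), ] <- dpdq %*% cbind(dqdW, Ik)
  }
  J
}

#' Train the competitive classifier on a representation dataset
#'
#' Levenberg-Marquardt minimization of the mean squared error between the
#' softmax outputs and the one-hot targets over the ten per-number feature
#' rows (the protocol evaluates training fit on this one-exemplar-per-class
#' set, not held-out generalization). A snapshot of the classifier is kept
#' after every accepted epoch; if training stops early the final classifier
#' fills the remaining epochs.
#'
#' @param dataset a `representation_dataset` (rows labeled 1..10).
#' @param epochs accepted-epoch cap (the protocol uses 10).
#' @param config an [lma_config()]; its `max_epochs` is overridden by
#'   `epochs`.
#' @param seed integer seed for the uniform(-0.5, 0.5) initialization.
#' @return A trained `softmax_classifier` with fields `snapshots` (one
#'   classifier per epoch 1..`epochs`), `perf` and `epochs_run`.
#' @export
train_classifier <- function(dataset, epochs = 10, config = lma_config(),
                             seed = 1) {
  stopifnot(inherits(dataset, "representation_dataset"))
  if (epochs < 1) stop("epochs must be >= 1")
  labels <- dataset$labels
  if (anyDuplicated(labels)) stop("duplicate labels in dataset")
  X <- dataset$features
  clf <- softmax_classifier(ncol(X), length(labels), seed = seed)
  config$max_epochs <- epochs
  model <- residual_model(
    residual = function(p) clf_residuals(set_clf_params(clf, p), X, labels),
    jacobian = function(p) clf_jacobian(set_clf_params(clf, p), X, labels)
  )
  fit <- lma_train(model, clf_params(clf), config, snapshots = TRUE)
  out <- set_clf_params(clf, fit$params)
  snaps <- lapply(fit$snapshots, function(p) set_clf_params(clf, p))
  if (length(snaps) < epochs) {
    last <- if (length(snaps)) snaps[[length(snaps)]] else out
    snaps <- c(snaps, rep(list(last), epochs - length(snaps)))
  }
  out$snapshots <- snaps
  out$perf <- fit$perf
  out$epochs_run <- fit$epoch
  out
}

# per-class true-class likelihood of one classifier on the dataset rows
true_class_likelihoods <- function(clf, dataset) {
  vapply(seq_along(dataset$labels), function(s) {
    classify(clf, dataset$features[s, ])[dataset$labels[s]]
  }, numeric(1))
}

misclassification_count <- function(clf, dataset) {
  sum(vapply(seq_along(dataset$labels), function(s) {
    predict_class(clf, dataset$features[s, ]) != dataset$labels[s]
  }, logical(1)))
}

#' Repeated-runs classification evaluation
#'
#' The evaluation protocol behind the five-dataset comparison: the
#' classifier is retrained `n_runs` times from different seeded random
#' initializations (run r uses seed `base_seed + r`), each for `epochs`
#' Levenberg-Marquardt epochs. For every run and class the likelihood the
#' trained classifier assigns to the true class is recorded, along with
#' per-epoch curves.
#'
#' @param dataset a `representation_dataset`.
#' @param n_runs number of runs (>= 2; the headline protocol uses 100).
#' @param epochs epochs per run (the protocol uses 10).
#' @param base_seed integer; run r uses `base_seed + r`.
#' @param config an [lma_config()].
#' @return An object of class `classification_report`: list with
#'   `variant`, `per_class_median`, `per_class_std`, `avg_median`,
#'   `per_epoch_avg_likelihood` (mean true-class likelihood over classes
#'   and runs, epochs 1..`epochs`), `per_epoch_median_misclassifications`
#'   (median over runs of the per-epoch argmax error count), `n_runs`,
#'   `seeds`, and `run_likelihoods` (n_runs x 10 matrix of final
#'   true-class likelihoods, kept for paired tests).
#' @export
evaluate_runs <- function(dataset, n_runs = 100, epochs = 10, base_seed = 0,
                          config = lma_config()) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  k <- length(dataset$labels)
  seeds <- base_seed + seq_len(n_runs)
  lik_final <- matrix(NA_real_, n_runs, k)
  lik_epoch <- array(NA_real_, c(n_runs, epochs, k))
  mis_epoch <- matrix(NA_integer_, n_runs, epochs)
  for (r in seq_len(n_runs)) {
    clf <- train_classifier(dataset, epochs = epochs, config = config,
                            seed = seeds[r])
    for (e in seq_len(epochs)) {
      snap <- clf$snapshots[[e]]
      lik_epoch[r, e, ] <- true_class_likelihoods(snap, dataset)
      mis_epoch[r, e] <- misclassification_count(snap, dataset)
    }
    lik_final[r, ] <- lik_epoch[r, epochs, ]
  }
  per_class_median <- apply(lik_final, 2, stats::median)
  per_class_std <- apply(lik_final, 2, stats::sd)
  structure(list(
    variant = dataset$variant,
    per_class_median = per_class_median,
    per_class_std = per_class_std,
    avg_median = mean(per_class_median),
    per_epoch_avg_likelihood = apply(lik_epoch, 2, mean),
    per_epoch_median_misclassifications = apply(mis_epoch, 2, stats::median),
    n_runs = n_runs, seeds = seeds,
    run_likelihoods = lik_final
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> variant %s, %d runs\n",
              format(x$variant), x$n_runs))
  cat("  per-class medians:",
      paste(sprintf("%.3f", x$per_class_median), collapse = " "), "\n")
  cat(sprintf("  average median likelihood: %.4f\n", x$avg_median))
  invisible(x)
}

#' Paired per-class tests between two evaluation reports
#'
#' Two-sided paired t-tests, class by class, on the final true-class
#' likelihoods of two repeated-runs reports whose runs are paired by seed
#' index. No multiple-testing correction is applied; p-values are reported
#' per class. Degenerate pairings (zero-variance differences) yield p = 1
#' when the differences are all zero and p = 0 otherwise.
#'
#' @param report_a,report_b `classification_report`s with equal `n_runs`.
#' @param alpha significance level for the per-class flags.
#' @return Object of class `pairwise_test_result`: list with
#'   `variant_pair`, `per_class_p`, `per_class_significant`.
#' @export
pairwise_tests <- function(report_a, report_b, alpha = 0.05) {
  if (report_a$n_runs != report_b$n_runs)
    stop("reports have different run counts")
  A <- report_a$run_likelihoods
  B <- report_b$run_likelihoods
  p <- vapply(seq_len(ncol(A)), function(cl) {
    d <- A[, cl] - B[, cl]
    if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
    stats::t.test(A[, cl], B[, cl], paired = TRUE)$p.value
  }, numeric(1))
  structure(list(variant_pair = c(report_a$variant, report_b$variant),
                 per_class_p = p,
                 per_class_significant = p < alpha),
            class = "pairwise_test_result")
}

#' Serialize a classification report
#'
#' CSV layout mirrors the published comparison table: one row per class
#' with median/std-dev columns, plus an `avg` row.
#'
#' @param reports list of `classification_report`s.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  cols <- list(class = c(1:10, "avg"))
  for (rep_ in reports) {
    cols[[sprintf("median_v%d", rep_$variant)]] <-
      c(rep_$per_class_median, rep_$avg_median)
    cols[[sprintf("std_v%d", rep_$variant)]] <-
      c(rep_$per_class_std, mean(rep_$per_class_std))
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
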