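#' Train the full counting system
#'
#' End-to-end system build: trains the lateralized motor controller and
#' the auditory memory on the in-package tables, collects the five
#' representation datasets, fits the associative mappings on the raw motor
#' and auditory hidden representations, and trains a classifier on the
#' fingers-and-words dataset (variant 5) for use by the addition
#' procedure.
#'
#' @param seed base integer seed. Sequence memories use `seed`
#'   (right hand), `seed + 100` (left hand) and `seed + 200` (auditory);
#'   the associative fit uses `seed + 300` and the classifier
#'   `seed + 400`, so each component's initialization is independent but
#'   fully determined by `seed`.
#' @param config an [lma_config()].
#' @param classifier_epochs classifier training epochs.
#' @return Object of class `counting_system`: list with `mcm`, `auditory`,
#'   `datasets`, `aw`, `classifier`, `mfcc`, `seed`.
#' @export
train_number_system <- function(seed = 1, config = lma_config(),
                                classifier_epochs = 10) {
  mfcc <- mfcc_table()
  mcm <- motor_controller_memory(config = config, seed = seed)
  auditory <- auditory_memory(mfcc, config = config, seed = seed + 200L)
  datasets <- build_representation_datasets(mcm, auditory, mfcc)
  aw <- train_transfer(datasets[[1]]$raw, datasets[[3]]$raw,
                       seed = seed + 300L, target_error = 1e-20)
  classifier <- train_classifier(datasets[[5]], epochs = classifier_epochs,
                                 config = config, seed = seed + 400L)
  structure(list(mcm = mcm, auditory = auditory, datasets = datasets,
                 aw = aw, classifier = classifier, mfcc = mfcc, seed = seed),
            class = "counting_system")
}

#' @export
print.counting_system <- function(x, ...) {
  cat("<counting_system>\n")
  cat(sprintf("  motor right/left perf: %.2e / %.2e\n",
              x$mcm$right$train_perf, x$mcm$left$train_perf))
  cat(sprintf("  auditory perf: %.2e\n", x$auditory$train_perf))
  cat(sprintf("  associative error (f2w/w2f): %.2e / %.2e\n",
              x$aw$train_error[1], x$aw$train_error[2]))
  invisible(x)
}

#' Run the five-dataset classification comparison
#'
#' Repeats the classifier evaluation protocol ([evaluate_runs()]) for the
#' requested representation datasets and assembles the per-class
#' median/std-dev comparison table. The sequence memories are trained once
#' and shared across all classifier runs.
#'
#' @param system a [train_number_system()] result (or `NULL` to train one
#'   from `seed`).
#' @param variants subset of 1..5.
#' @param n_runs classifier retrainings per variant (protocol: 100).
#' @param epochs epochs per run (protocol: 10).
#' @param seed base seed; run r of every variant uses `seed + r` for the
#'   classifier initialization.
#' @param out_dir optional directory for CSV output (`table3.csv`,
#'   `curves.csv`); refuses to overwrite an existing directory unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into an existing `out_dir`.
#' @return List of `classification_report`s (named `v1` .. `v5`) with the
#'   composite data frame attached as attribute `table`.
#' @export
run_table3 <- function(system = NULL, variants = 1:5, n_runs = 100,
                       epochs = 10, seed = 0, out_dir = NULL,
                       overwrite = FALSE) {
  stopifnot(all(variants %in% 1:5))
  if (is.null(system)) system <- train_number_system(seed = seed + 1L)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && !overwrite)
      stop("output directory exists; use overwrite = TRUE to reuse it")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  reports <- lapply(variants, function(v) {
    evaluate_runs(system$datasets[[v]], n_runs = n_runs, epochs = epochs,
                  base_seed = seed)
  })
  names(reports) <- paste0("v", variants)
  tab <- data.frame(class = c(1:10, "avg"))
  for (rep_ in reports) {
    tab[[sprintf("median_v%d", rep_$variant)]] <-
      c(rep_$per_class_median, rep_$avg_median)
    tab[[sprintf("std_v%d", rep_$variant)]] <-
      c(rep_$per_class_std, mean(rep_$per_class_std))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(tab, file.path(out_dir, "table3.csv"), row.names = FALSE)
    utils::write.csv(learning_curves_frame(reports),
                     file.path(out_dir, "curves.csv"), row.names = FALSE)
  }
  attr(reports, "table") <- tab
  reports
}

learning_curves_frame <- function(reports) {
  do.call(rbind, lapply(reports, function(rep_) {
    data.frame(variant = rep_$variant,
               epoch = seq_along(rep_$per_epoch_avg_likelihood),
               avg_likelihood = rep_$per_epoch_avg_likelihood,
               median_misclassifications =
                 rep_$per_epoch_median_misclassifications)
  }))
}

#' Per-epoch learning curves
#'
#' Average true-class likelihood and median misclassification count per
#' training epoch, for each requested dataset, across repeated runs.
#'
#' @inheritParams run_table3
#' @return Data frame with columns `variant`, `epoch`, `avg_likelihood`,
#'   `median_misclassifications`.
#' @export
run_learning_curves <- function(system = NULL, variants = 1:5, n_runs = 100,
                                epochs = 10, seed = 0) {
  reports <- run_table3(system = system, variants = variants,
                        n_runs = n_runs, epochs = epochs, seed = seed)
  learning_curves_frame(reports)
}

#' Agglomerative clustering of number representations
#'
#' Complete-linkage clustering on Euclidean distances between the ten
#' per-number feature vectors, with the dendrogram's leaf order chosen —
#' by exhaustive enumeration of the 2^9 subtree flips — to minimize the
#' sum of consecutive-leaf distances. The `adjacency_score` (mean absolute
#' numeric difference between consecutive leaves) quantifies how closely
#' the representation geometry mirrors the number line: 1 means the leaves
#' run in counting order.
#'
#' @param dataset a `representation_dataset` (or bare 10 x d matrix).
#' @return Object of class `clustering_result`: list with `variant`,
#'   `linkage` (the `hclust` tree), `leaf_order`, `adjacency_score`,
#'   `degenerate` flag (duplicate rows present).
#' @export
cluster_representations <- function(dataset) {
  feats <- if (inherits(dataset, "representation_dataset")) dataset$features
           else as.matrix(dataset)
  variant <- if (inherits(dataset, "representation_dataset")) dataset$variant
             else NA_integer_
  n <- nrow(feats)
  D <- as.matrix(stats::dist(feats))
  degenerate <- any(D[upper.tri(D)] == 0)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  # leaves of each merge node, in order, for a given flip assignment
  leaves_of <- function(node, flips) {
    if (node < 0) return(-node)
    kids <- hc$merge[node, ]
    l <- leaves_of(kids[1], flips)
    r <- leaves_of(kids[2], flips)
    if (flips[node]) c(r, l) else c(l, r)
  }
  n_merges <- nrow(hc$merge)
  best <- NULL
  best_cost <- Inf
  for (mask in 0:(2^n_merges - 1)) {
    flips <- as.logical(bitwAnd(mask, 2^(seq_len(n_merges) - 1)))
    ord <- leaves_of(n_merges, flips)
    cost <- sum(D[cbind(ord[-n], ord[-1])])
    if (cost < best_cost) {
      best_cost <- cost
      best <- ord
    }
  }
  structure(list(variant = variant, linkage = hc, leaf_order = best,
                 adjacency_score = mean(abs(diff(best))),
                 degenerate = degenerate),
            class = "clustering_result")
}

#' Narrated two-operand addition demonstration
#'
#' Runs [add_numbers()] and prints the five-step narrative of the
#' procedure with the switch states traversed at each step.
#'
#' @param system a trained [train_number_system()].
#' @param a,b operands (sum at most 10).
#' @param quiet suppress printing.
#' @return The `addition_trace`, invisibly.
#' @export
run_addition_demo <- function(system, a, b, quiet = FALSE) {
  trace <- add_numbers(a, b, system)
  if (!quiet) {
    say <- function(...) cat(sprintf(...), "\n", sep = "")
    say("Addition of %d + %d:", trace$operand_a, trace$operand_b)
    say("1. Operand %d heard; both networks count up to it [start_all -> counting].",
        trace$operand_a)
    say("2. Plus heard; auditory network reset, motor memory holds %d [reset_auditory].",
        trace$operand_a)
    say("3. Operand %d heard; both networks count again - auditory to %d, motor on to %d [counting].",
        trace$operand_b, trace$operand_b, trace$operand_a + trace$operand_b)
    say("4. Total transferred from the fingers network to the auditory network via w1 [transfer_fingers_to_words].")
    say("5. Result emitted to the competitive classifier: class %d (likelihood %.3f) [output_to_classifier].",
        trace$result_class, trace$result_likelihood)
  }
  invisible(trace)
}

#' Serialize a representation dataset to CSV
#'
#' Label column plus one feature column per dimension.
#'
#' @param dataset a `representation_dataset`.
#' @param path output CSV path.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(label = dataset$labels, dataset$features)
  utils::write.csv(df, path, row.names = FALSE)
}
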