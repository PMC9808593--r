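#' @title Repeated holdout validation and transfer experiments
#' @description Evaluation protocol for the handedness trees: repeated
#'   random 70/30 holdout with accuracy aggregated over iterations, the
#'   quadruplex-to-duplex transfer experiment (progressively mixing duplex
#'   samples into the quadruplex training set), single-angle classifiers,
#'   and first-split statistics over iterations. Every source of randomness
#'   is an explicit seed; iteration `i` runs under seed `base_seed + i`, so
#'   reports are reproducible bit for bit.
#' @name validation
NULL

accuracy <- function(tree, ds) {
  mean(predict(tree, ds) == ds$label)
}

#' Random 70/30 holdout split
#'
#' The test set holds `ceiling((1 - train_fraction) * N)` samples drawn
#' uniformly at random, the training set the remainder — for a 213-sample
#' table that is the 149/64 split. Train and test partition the dataset.
#'
#' @param ds a `torsion_dataset` with at least two samples of each class.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (the repeated protocols seed each iteration themselves).
#' @return list with elements `train` and `test`.
#' @export
holdout_split <- function(ds, train_fraction = 0.7, seed = NULL) {
  n <- nrow(ds)
  if (min(table(factor(ds$label, levels = c(0L, 1L)))) < 2L) {
    stop("holdout_split() needs at least 2 samples of each class", call. = FALSE)
  }
  # epsilon guards the ceiling against binary-fraction noise (0.3 * 10 -> 3)
  draw <- function() sample.int(n, ceiling((1 - train_fraction) * n - 1e-9))
  test_idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(train = ds[-test_idx, , drop = FALSE], test = ds[test_idx, , drop = FALSE])
}

root_split <- function(tree) {
  if (is_leaf(tree)) {
    data.frame(feature = NA_character_, threshold = NA_real_)
  } else {
    data.frame(feature = tree$feature, threshold = tree$threshold,
               stringsAsFactors = FALSE)
  }
}

new_report <- function(acc, splits, n_iterations, base_seed) {
  structure(
    list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
         n_iterations = n_iterations, base_seed = base_seed,
         first_splits = splits),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d iterations, accuracy %.3f +/- %.3f (seed %d)\n",
              x$n_iterations, x$mean, x$sd, x$base_seed))
  invisible(x)
}

#' Repeated random holdout validation
#'
#' For each iteration: split 70/30, grow a tree on the training set, prune
#' it, and score accuracy (correct / total) on the held-out set. The root
#' split (feature, threshold) of each iteration's pruned tree is recorded
#' for [first_split_statistics()].
#'
#' @param ds a `torsion_dataset`.
#' @param n_iterations number of random splits (the reference protocol uses
#'   1000).
#' @param base_seed iteration `i` runs under `base_seed + i`.
#' @param train_fraction,ccp_alpha,features forwarded to the split and tree.
#' @return a `validation_report`: per-iteration accuracies, mean, sd, and
#'   first-split records.
#' @export
repeated_holdout <- function(ds, n_iterations = 1000, base_seed = 1,
                             train_fraction = 0.7, ccp_alpha = 0.04,
                             features = ANGLE_NAMES) {
  acc <- numeric(n_iterations)
  splits <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    sp <- holdout_split(ds, train_fraction, seed = base_seed + i)
    stopifnot(nrow(sp$train) + nrow(sp$test) == nrow(ds))
    tree <- prune_tree(grow_tree(sp$train, features = features), ccp_alpha)
    acc[i] <- accuracy(tree, sp$test)
    splits[[i]] <- root_split(tree)
  }
  new_report(acc, do.call(rbind, c(splits, list(make.row.names = FALSE))),
             n_iterations, base_seed)
}

#' Quadruplex-to-duplex transfer experiment
#'
#' For each `k` and each iteration: the quadruplex set is split 70/30 (same
#' seeds as [repeated_holdout()], so `k = 0` reproduces it exactly), `k`
#' duplex samples are drawn uniformly without replacement and appended to
#' the training set, and the tree is scored both on the quadruplex test
#' split and on every duplex sample *not* drawn into training.
#'
#' @param g4 quadruplex `torsion_dataset` (the classifier's home task).
#' @param dh duplex `torsion_dataset` (Z-DNA + B-DNA pool); must exceed
#'   `max(k_values)`.
#' @param k_values numbers of duplex samples mixed into training.
#' @param n_iterations,base_seed,train_fraction,ccp_alpha as in
#'   [repeated_holdout()].
#' @return a `transfer_table` data frame: `k`, `g4_accuracy`, `dh_accuracy`
#'   (percent, averaged over iterations) and their standard deviations.
#' @export
transfer_experiment <- function(g4, dh, k_values = c(0, 10, 20, 30, 40, 50),
                                n_iterations = 1000, base_seed = 1,
                                train_fraction = 0.7, ccp_alpha = 0.04) {
  if (max(k_values) >= nrow(dh)) {
    stop("k exceeds the duplex pool size", call. = FALSE)
  }
  rows <- lapply(k_values, function(k) {
    g4_acc <- numeric(n_iterations)
    dh_acc <- numeric(n_iterations)
    for (i in seq_len(n_iterations)) {
      picks <- with_seed(base_seed + i, {
        test_idx <- sample.int(nrow(g4),
                               ceiling((1 - train_fraction) * nrow(g4) - 1e-9))
        dh_idx <- if (k > 0) sample.int(nrow(dh), k) else integer()
        list(test_idx = test_idx, dh_idx = dh_idx)
      })
      train <- rbind(as.data.frame(g4[-picks$test_idx, , drop = FALSE])[, .dataset_header],
                     as.data.frame(dh[picks$dh_idx, , drop = FALSE])[, .dataset_header])
      tree <- prune_tree(grow_tree(train), ccp_alpha)
      g4_acc[i] <- accuracy(tree, g4[picks$test_idx, , drop = FALSE])
      dh_eval <- dh[setdiff(seq_len(nrow(dh)), picks$dh_idx), , drop = FALSE]
      dh_acc[i] <- accuracy(tree, dh_eval)
    }
    data.frame(k = k,
               g4_accuracy = 100 * mean(g4_acc), g4_sd = 100 * stats::sd(g4_acc),
               dh_accuracy = 100 * mean(dh_acc), dh_sd = 100 * stats::sd(dh_acc))
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            n_iterations = n_iterations, base_seed = base_seed,
            class = c("transfer_table", "data.frame"))
}

#' Single-angle classifiers
#'
#' Runs the repeated-holdout protocol once per torsion angle with the tree
#' restricted to that single feature, under identical iteration seeds, so
#' the seven mean accuracies are directly comparable.
#'
#' @inheritParams repeated_holdout
#' @return data frame `angle`, `mean_accuracy`, `sd` (accuracy fractions),
#'   in canonical angle order.
#' @export
single_angle_assessment <- function(ds, n_iterations = 1000, base_seed = 1,
                                    train_fraction = 0.7, ccp_alpha = 0.04) {
  rows <- lapply(ANGLE_NAMES, function(ang) {
    rep <- repeated_holdout(ds, n_iterations, base_seed, train_fraction,
                            ccp_alpha, features = ang)
    data.frame(angle = ang, mean_accuracy = rep$mean, sd = rep$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' First-split statistics over holdout iterations
#'
#' Which angle do the pruned trees choose at the root, how often, and at
#' what average threshold?
#'
#' @param report a `validation_report` with first-split records.
#' @return list `feature` (modal root feature; ties broken by canonical
#'   angle order), `fraction` (of iterations with a root split choosing it)
#'   and `mean_threshold` over those iterations.
#' @export
first_split_statistics <- function(report) {
  fs <- report$first_splits
  fs <- fs[!is.na(fs$feature), , drop = FALSE]
  if (is.null(fs) || nrow(fs) == 0L) {
    stop("report contains no first-split records", call. = FALSE)
  }
  counts <- table(factor(fs$feature, levels = ANGLE_NAMES))
  modal <- names(counts)[which.max(counts)]       # first max = canonical order
  sel <- fs$feature == modal
  list(feature = modal,
       fraction = sum(sel) / nrow(fs),
       mean_threshold = mean(fs$threshold[sel]))
}
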