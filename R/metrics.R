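# Evaluation statistics and 5-fold cross-validation.

#' Area under the ROC curve
#'
#' Rank-based AUC under the Mann-Whitney convention: the probability that a
#' random positive outscores a random negative, with ties counted half.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive); both classes required.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC requires both positive and negative labels")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification accuracy at a threshold
#'
#' @param scores Numeric vector.
#' @param labels Binary vector.
#' @param threshold Scores `>= threshold` are called positive (default 0.5).
#' @return Fraction of correct calls.
#' @export
accuracy <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) abort("empty input")
  stopifnot(length(scores) == length(labels))
  mean((scores >= threshold) == (labels == 1))
}

#' Precision and recall from confusion counts
#'
#' Precision = TP/(TP+FP); recall = TP/(TP+FN). A zero denominator leaves
#' the statistic `NA` and flags it undefined rather than coercing to 0.
#'
#' @param tp,fp,tn,fn Nonnegative integer confusion counts.
#' @return A one-row tibble: `precision`, `recall`,
#'   `precision_defined`, `recall_defined`.
#' @export
precision_recall <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  tibble(
    precision = if (p_def) tp / (tp + fp) else NA_real_,
    recall = if (r_def) tp / (tp + fn) else NA_real_,
    precision_defined = p_def, recall_defined = r_def
  )
}

#' Relative change between two percentages
#'
#' The signed percentage change `(new - old) / old * 100`, rounded to one
#' decimal for display — the arithmetic behind "precision 9.6% improved to
#' 13.8% (+43.8%)" style statements.
#'
#' @param old,new Percentages; `old` must be nonzero.
#' @return Signed percentage change, one-decimal rounded.
#' @export
relative_change <- function(old, new) {
  if (any(old == 0)) abort("relative change undefined for old = 0")
  round((new - old) / old * 100, 1)
}

#' Random k-fold partition
#'
#' @param n Number of records (`n >= k`).
#' @param seed Integer seed.
#' @param k Number of folds (default 5).
#' @return Integer vector of fold ids in `1..k`, one per record; fold sizes
#'   differ by at most 1.
#' @export
five_fold_split <- function(n, seed, k = 5L) {
  if (n < k) abort(sprintf("need at least %d records for %d folds", k, k))
  withr::local_seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation of the classifier
#'
#' Randomly partitions the pairs into `k` non-overlapping folds; each fold
#' serves once as the validation set while the remainder trains the model
#' (with per-epoch best-validation-accuracy checkpointing, as in
#' [hla_train()]). Per-fold AUC and accuracy on the validation fold are
#' averaged for the final result.
#'
#' @param pairs Labeled pair tibble (`allele`, `peptide`, `label`).
#' @param pseudo Pseudo-sequence table.
#' @param config A [training_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split.
#' @param stratified Stratify the split by label (off by default; the
#'   default split is plain random).
#' @return An object of class `cv_result`: `folds` (tibble: fold, auc,
#'   accuracy, n_validation) and `summary` (one-row tibble of means).
#' @export
cross_validate <- function(pairs, pseudo, config = training_config(),
                           k = 5L, seed = config$seed, stratified = FALSE) {
  pairs <- as_tibble(pairs)
  check_pair_frame(pairs)
  n <- nrow(pairs)
  fold <- if (stratified) {
    f <- integer(n)
    withr::local_seed(seed)
    for (cl in unique(pairs$label)) {
      idx <- which(pairs$label == cl)
      f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    f
  } else {
    five_fold_split(n, seed, k)
  }
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- pairs[fold != i, ]
    va <- pairs[fold == i, ]
    if (length(unique(tr$label)) < 2L) {
      abort(sprintf("training fold %d contains a single class", i))
    }
    fit <- hla_train(tr, pseudo, config, validation = va)
    sc <- hla_predict(va, fit, pseudo)$score
    rows[[i]] <- tibble(
      fold = i,
      auc = if (length(unique(va$label)) == 2L) auc(sc, va$label) else NA_real_,
      accuracy = accuracy(sc, va$label),
      best_val_accuracy = fit$best_val_accuracy,
      n_validation = nrow(va)
    )
  }
  folds <- dplyr::bind_rows(rows)
  structure(
    list(folds = folds,
         summary = dplyr::summarise(folds,
                                    mean_auc = mean(.data$auc, na.rm = TRUE),
                                    mean_accuracy = mean(.data$accuracy)),
         fold_assignment = fold),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds | mean AUC %.3f | mean accuracy %.3f\n",
              nrow(x$folds), x$summary$mean_auc, x$summary$mean_accuracy))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) x$summary
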