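# ROC/AUC, stratified folds, and cross-validated evaluation of the
# scoring-card training pipeline.

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Computed exactly as the fraction of (positive, negative) score pairs in
#' which the positive outscores the negative, ties counting one half — the
#' rank-based Mann-Whitney statistic, equivalent to trapezoidal ROC
#' integration but exact under ties.
#'
#' @param pos_scores,neg_scores Numeric score vectors for the two classes.
#' @return A number in \eqn{[0, 1]}.
#' @export
#' @examples
#' auc(c(3, 1), c(2, 0)) # 3 of 4 pairs ordered correctly
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  if (np == 0L || nn == 0L) {
    abort("both score vectors must be non-empty", class = "scmseq_eval_error")
  }
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Stratified k-fold assignment
#'
#' Partitions each class separately into `k` near-equal parts (sizes within
#' a class differ by at most 1), so every fold keeps the class ratio of the
#' full dataset. The assignment is a deterministic function of `seed`.
#'
#' @param data A labeled dataset tibble.
#' @param k Number of folds; between 2 and the smaller class size.
#' @param seed Integer seed for the shuffle.
#' @return An integer vector of fold ids (1..k), one per row of `data`.
#' @export
stratified_folds <- function(data, k, seed = 1L) {
  check_labeled(data)
  k <- as.integer(k)
  n_pos <- sum(data$label == "positive")
  n_neg <- sum(data$label == "negative")
  if (k < 2L || k > min(n_pos, n_neg)) {
    abort(
      paste0("k must lie in [2, ", min(n_pos, n_neg), "] (smaller class size); got ", k),
      class = "scmseq_config_error"
    )
  }
  folds <- integer(nrow(data))
  withr::with_seed(seed, {
    for (lab in c("positive", "negative")) {
      idx <- which(data$label == lab)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

confusion_counts <- function(truth, predicted) {
  list(
    tp = sum(truth == "positive" & predicted == "positive"),
    tn = sum(truth == "negative" & predicted == "negative"),
    fp = sum(truth == "negative" & predicted == "positive"),
    fn = sum(truth == "positive" & predicted == "negative")
  )
}

# accuracy/sensitivity/specificity from counts; 0/0 reported as NA
metrics_from_counts <- function(cn) {
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  tibble(
    tp = cn$tp, tn = cn$tn, fp = cn$fp, fn = cn$fn,
    accuracy = rate(cn$tp + cn$tn, cn$tp + cn$tn + cn$fp + cn$fn),
    sensitivity = rate(cn$tp, cn$tp + cn$fn),
    specificity = rate(cn$tn, cn$tn + cn$fp)
  )
}

#' Confusion-matrix metrics for classified sequences
#'
#' @param data A tibble holding `label` (truth) and `predicted` columns, as
#'   produced by piping a labeled dataset through [classify()].
#' @return A one-row tibble with TP/TN/FP/FN counts, accuracy, sensitivity
#'   and specificity (fractions; undefined rates are `NA`, never silently 0).
#' @export
classification_metrics <- function(data) {
  check_labeled(data)
  if (!"predicted" %in% names(data)) {
    abort("`data` must have a `predicted` column (see `classify()`)",
      class = "scmseq_type_error"
    )
  }
  metrics_from_counts(confusion_counts(data$label, data$predicted))
}

#' Cross-validate the scoring-card training pipeline
#'
#' For each of `k` stratified folds, the full training pipeline is re-run on
#' the remaining folds — initial card from composition differences, optional
#' GA refinement, threshold calibration — and the held-out fold is scored
#' and classified with the resulting card. This is the honest protocol: the
#' held-out sequences contribute nothing to the card they are evaluated
#' with. Set `optimize = FALSE` (or `config$generations = 0`) to evaluate
#' the unrefined initial card per fold.
#'
#' @param data A labeled dataset tibble.
#' @param k Number of folds (default 10).
#' @param config A [ga_config()] for the per-fold refinement.
#' @param seed Seed for the fold assignment; per-fold GA seeds are derived
#'   from it.
#' @param optimize Logical; run the GA per fold (default `TRUE`).
#' @return An object of class `scm_cv`: list with `folds` (per-fold metric
#'   tibble: accuracy, sensitivity, specificity, AUC, counts) and `summary`
#'   (mean and sd of each metric). Access them with [tidy()] and [glance()].
#' @export
cross_validate <- function(data, k = 10L, config = ga_config(), seed = 1L,
                           optimize = TRUE) {
  check_labeled(data)
  config <- validate_ga_config(config)
  folds <- stratified_folds(data, k, seed = seed)
  data <- as_tibble(data)

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- data[folds != f, ]
    test <- data[folds == f, ]
    fold_config <- config
    fold_config$seed <- as.integer((seed * 131L + f) %% .Machine$integer.max)
    fold_config$cv_folds <- min(
      fold_config$cv_folds,
      sum(train$label == "positive"), sum(train$label == "negative")
    )
    card <- if (optimize && config$generations > 0L) {
      ga_optimize(train, config = fold_config)$card
    } else {
      calibrate_threshold(initial_card(train), train)
    }
    pred <- classify(test, card)
    cn <- confusion_counts(pred$label, pred$predicted)
    dplyr::bind_cols(
      tibble(fold = f),
      metrics_from_counts(cn),
      tibble(auc = auc(
        pred$score[pred$label == "positive"],
        pred$score[pred$label == "negative"]
      ))
    )
  })

  metric_cols <- c("accuracy", "sensitivity", "specificity", "auc")
  summary <- dplyr::bind_rows(
    dplyr::summarise(per_fold, dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE))) |>
      dplyr::mutate(statistic = "mean", .before = 1),
    dplyr::summarise(per_fold, dplyr::across(dplyr::all_of(metric_cols), ~ sd(.x, na.rm = TRUE))) |>
      dplyr::mutate(statistic = "sd", .before = 1)
  )

  structure(
    list(folds = per_fold, summary = summary, k = k, optimized = optimize && config$generations > 0L),
    class = "scm_cv"
  )
}

#' @export
print.scm_cv <- function(x, ...) {
  m <- x$summary[x$summary$statistic == "mean", ]
  s <- x$summary[x$summary$statistic == "sd", ]
  cat(sprintf(
    "<scm_cv> %d-fold, %s card: accuracy %.2f%% +/- %.2f, AUC %.3f\n",
    x$k, if (x$optimized) "GA-refined" else "initial",
    100 * m$accuracy, 100 * s$accuracy, m$auc
  ))
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x An `scm_cv` object from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @method tidy scm_cv
#' @export
tidy.scm_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x An `scm_cv` object.
#' @param ... Unused.
#' @return A one-row tibble of mean and sd for accuracy, sensitivity,
#'   specificity and AUC.
#' @method glance scm_cv
#' @export
glance.scm_cv <- function(x, ...) {
  m <- x$summary[x$summary$statistic == "mean", -1]
  s <- x$summary[x$summary$statistic == "sd", -1]
  names(s) <- paste0(names(s), "_sd")
  dplyr::bind_cols(tibble(k = x$k), m, s)
}
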