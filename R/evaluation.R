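# Evaluation: nested LOOCV, the deliberately biased non-nested variant,
# confusion-matrix metrics, and the permutation significance test.

#' Build a 2x2 confusion matrix from actual and predicted labels
#'
#' Cases are the positive class: `tp`/`fn` split the actual cases by
#' predicted label, `fp`/`tn` the actual controls.
#'
#' @param actual,predicted label vectors, see [as_labels()].
#' @return object of class `confusion` with integer fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(actual, predicted) {
  actual <- as_labels(actual)
  predicted <- as_labels(predicted)
  if (length(actual) != length(predicted)) stop("length mismatch")
  new_confusion(tp = sum(actual == "case" & predicted == "case"),
                fn = sum(actual == "case" & predicted == "control"),
                fp = sum(actual == "control" & predicted == "case"),
                tn = sum(actual == "control" & predicted == "control"))
}

#' @rdname confusion_matrix
#' @param tp,fn,fp,tn non-negative counts (e.g. transcribed from a
#'   published confusion table).
#' @export
new_confusion <- function(tp, fn, fp, tn) {
  cm <- list(tp = as.integer(tp), fn = as.integer(fn),
             fp = as.integer(fp), tn = as.integer(tn))
  if (any(unlist(cm) < 0)) stop("confusion counts must be non-negative")
  structure(cm, class = "confusion")
}

#' Derived classification metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, sensitivity (recall)
#' `tp/(tp+fn)` and specificity `tn/(tn+fp)`, reported both as raw
#' proportions and as percentages rounded half-up to two decimals. A
#' metric whose denominator is zero is reported as `NA`, never silently 0.
#'
#' @param cm a `confusion` object ([confusion_matrix()] / [new_confusion()]).
#' @return object of class `eval_metrics`: list with `cm`, `proportions`
#'   and `percent` (named vectors: accuracy, precision, sensitivity,
#'   specificity).
#' @examples
#' metrics(new_confusion(tp = 187, fn = 115, fp = 137, tn = 184))$percent
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  prop <- c(accuracy = (cm$tp + cm$tn) / total,
            precision = ratio(cm$tp, cm$tp + cm$fp),
            sensitivity = ratio(cm$tp, cm$tp + cm$fn),
            specificity = ratio(cm$tn, cm$tn + cm$fp))
  structure(list(cm = cm, proportions = prop, percent = as_percent(prop)),
            class = "eval_metrics")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual case", "actual control"),
                              c("pred case", "pred control")))
  print(m)
  invisible(x)
}

#' @export
print.eval_metrics <- function(x, ...) {
  print(x$cm)
  p <- x$percent
  cat(sprintf("accuracy %.2f%%, precision %s, sensitivity %s, specificity %s\n",
              p["accuracy"],
              ifelse(is.na(p["precision"]), "NA",
                     sprintf("%.2f%%", p["precision"])),
              ifelse(is.na(p["sensitivity"]), "NA",
                     sprintf("%.2f%%", p["sensitivity"])),
              ifelse(is.na(p["specificity"]), "NA",
                     sprintf("%.2f%%", p["specificity"]))))
  invisible(x)
}

#' Accuracy of the trivial majority-class predictor
#'
#' The baseline every classifier must beat: always predict the more common
#' class. For 321 controls and 302 cases this is 321/623, i.e. 51.52%.
#'
#' @param labels per-subject phenotype.
#' @return the baseline accuracy as a proportion (use [as_percent()] for
#'   the two-decimal percentage).
#' @export
majority_baseline <- function(labels) {
  labels <- as_labels(labels)
  if (length(labels) == 0) stop("empty label vector")
  max(table(labels)) / length(labels)
}

# Shared LOOCV engine. mode = "nested" re-selects features inside every
# outer fold; mode = "biased" commits to one full-data selection first and
# only the k-selection remains per-fold, reproducing the feature-selection
# leakage that inflates apparent accuracy.
loocv_engine <- function(gm, labels, m, k_grid, r, seed, mode,
                         keep_fold_log) {
  labels <- as_labels(labels, names(labels))
  check_aligned(gm, labels)
  n <- nrow(gm)
  fold_seeds <- derive_seeds(seed, n)

  if (mode == "biased") {
    sel <- select_top_m(gm, labels, m)         # leakage: sees all subjects
    gm <- gm[, sel$selected_idx, drop = FALSE]
    m_inner <- ncol(gm)                        # inner selection is vacuous
  } else {
    m_inner <- m
  }

  predicted <- character(n)
  fold_log <- if (keep_fold_log) vector("list", n) else NULL
  for (j in seq_len(n)) {
    fit <- best_knn_fit(gm[-j, , drop = FALSE], labels[-j], m = m_inner,
                        k_grid = k_grid, r = r, seed = fold_seeds[j])
    predicted[j] <- as.character(
      predict(fit$model, gm[j, fit$selected$selected_idx, drop = FALSE]))
    if (keep_fold_log) {
      fold_log[[j]] <- list(held_out = rownames(gm)[j],
                            chosen_k = fit$trace$chosen_k,
                            selected_snps = fit$model$snp_ids)
    }
  }
  met <- metrics(confusion_matrix(labels, predicted))
  structure(list(cm = met$cm,
                 proportions = met$proportions,
                 percent = met$percent,
                 predictions = stats::setNames(as_labels(predicted),
                                               rownames(gm)),
                 fold_log = fold_log,
                 mode = mode,
                 params = list(m = m, k_grid = k_grid, r = r, seed = seed)),
            class = "loocv_result")
}

#' Nested leave-one-out cross-validation of the full pipeline
#'
#' For each subject j, the *entire* learning procedure — MeanDiff top-m
#' selection and BestKNN k-selection — is re-run on the other N-1 subjects
#' only, and the resulting classifier predicts subject j. The accumulated
#' confusion matrix over the N folds estimates how the pipeline would
#' perform on novel subjects: no information about the held-out subject
#' ever reaches feature selection or parameter tuning.
#'
#' @param gm subjects x SNPs genotype matrix (QC already applied).
#' @param labels per-subject phenotype; each class needs at least `r + 1`
#'   subjects.
#' @param m MeanDiff panel size (default 500).
#' @param k_grid candidate neighbour counts (default `c(1, 3, 5, 7)`).
#' @param r internal fold count of BestKNN (default 10).
#' @param seed RNG seed (per-fold internal fold assignments).
#' @param keep_fold_log store per-fold chosen k and selected SNPs (default
#'   TRUE; disable to save memory in long permutation runs).
#' @return object of class `loocv_result`: confusion matrix, metric
#'   proportions and percentages, per-subject predictions, per-fold log,
#'   `mode` (`"nested"` here) and the parameters used.
#' @export
nested_loocv <- function(gm, labels, m = 500, k_grid = c(1, 3, 5, 7),
                         r = 10, seed = 1, keep_fold_log = TRUE) {
  loocv_engine(gm, labels, m, k_grid, r, seed, "nested", keep_fold_log)
}

#' The deliberately biased (non-nested) LOOCV variant
#'
#' Performs MeanDiff selection ONCE on the full dataset, then leave-one-out
#' cross-validates KNN over that fixed SNP panel (k is still chosen per
#' fold, so feature-selection leakage is the only difference from
#' [nested_loocv()]). On high-dimensional null data this produces wildly
#' optimistic apparent accuracy; the result is flagged `mode = "biased"`
#' and must never be reported as an unbiased estimate.
#'
#' @inheritParams nested_loocv
#' @return a `loocv_result` with `mode = "biased"`.
#' @export
biased_loocv <- function(gm, labels, m = 500, k_grid = c(1, 3, 5, 7),
                         r = 10, seed = 1, keep_fold_log = TRUE) {
  loocv_engine(gm, labels, m, k_grid, r, seed, "biased", keep_fold_log)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("%s LOOCV over %d subjects%s\n",
              if (x$mode == "nested") "Nested" else "BIASED (non-nested)",
              length(x$predictions),
              if (x$mode == "biased") " -- apparent accuracy only" else ""))
  print(x$cm)
  n_case <- x$cm$tp + x$cm$fn
  n_ctl <- x$cm$fp + x$cm$tn
  cat(sprintf("accuracy %.2f%% (majority baseline %.2f%%)\n",
              x$percent["accuracy"],
              as_percent(max(n_case, n_ctl) / (n_case + n_ctl))))
  invisible(x)
}

#' Permutation test of nested-LOOCV accuracy
#'
#' Estimates the significance of the observed nested-LOOCV accuracy by
#' destroying the genotype-phenotype link: the labels are permuted
#' uniformly at random (class counts preserved) and the *whole*
#' learn-and-evaluate pipeline — selection, k-tuning, nested LOOCV — is
#' re-run on each permuted dataset. The p-value uses the add-one estimator
#' `(#\{permuted >= observed\} + 1) / (B + 1)`, which is never zero and
#' counts ties conservatively; with zero exceedances at B = 100 this gives
#' 1/101 < 0.01.
#'
#' @inheritParams nested_loocv
#' @param B number of permutations (default 100).
#' @return object of class `perm_test`: `observed_accuracy`,
#'   `permuted_accuracies` (length B), `exceed_count`, `p_value`, `B`.
#' @export
permutation_test <- function(gm, labels, m = 500, k_grid = c(1, 3, 5, 7),
                             r = 10, B = 100, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  labels <- as_labels(labels, names(labels))
  seeds <- derive_seeds(seed, 2 * B + 1)
  obs <- nested_loocv(gm, labels, m, k_grid, r, seed = seeds[1],
                      keep_fold_log = FALSE)$proportions["accuracy"]
  perm_acc <- numeric(B)
  for (b in seq_len(B)) {
    perm <- with_seed(seeds[2 * b], sample.int(length(labels)))
    plab <- stats::setNames(labels[perm], names(labels))
    perm_acc[b] <- nested_loocv(gm, plab, m, k_grid, r,
                                seed = seeds[2 * b + 1],
                                keep_fold_log = FALSE
    )$proportions["accuracy"]
  }
  exceed <- sum(perm_acc >= obs)
  structure(list(observed_accuracy = unname(obs),
                 permuted_accuracies = perm_acc,
                 exceed_count = exceed,
                 p_value = (exceed + 1) / (B + 1),
                 B = B),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed accuracy %.2f%%, %d/%d permuted runs >= observed, p = %.4f\n",
              100 * x$observed_accuracy, x$exceed_count, x$B, x$p_value))
  invisible(x)
}

#' Sensitivity of nested-LOOCV accuracy to the MeanDiff panel size
#'
#' Re-runs [nested_loocv()] for each panel size in `m_grid` (default 500
#' to 1500 in steps of 100) to assess robustness of the estimate to m.
#'
#' @inheritParams nested_loocv
#' @param m_grid panel sizes to evaluate.
#' @return data.frame with columns `m` and `accuracy` (proportion).
#' @export
m_sweep <- function(gm, labels, m_grid = seq(500, 1500, by = 100),
                    k_grid = c(1, 3, 5, 7), r = 10, seed = 1) {
  acc <- vapply(m_grid, function(m) {
    nested_loocv(gm, labels, m = m, k_grid = k_grid, r = r, seed = seed,
                 keep_fold_log = FALSE)$proportions[["accuracy"]]
  }, numeric(1))
  data.frame(m = m_grid, accuracy = acc)
}
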