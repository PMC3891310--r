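# BestKNN: choose k by internal r-fold CV with per-fold feature
# re-selection, then refit on all data.

#' Stratified cross-validation fold assignment
#'
#' Partitions subjects into `r` disjoint, exhaustive folds, stratified by
#' class: within each class the subjects are shuffled (seeded) and dealt
#' out cyclically, so per-class fold sizes differ by at most one.
#'
#' @param labels per-subject phenotype, see [as_labels()].
#' @param r fold count, `2 <= r <= length(labels)`.
#' @param seed RNG seed for the within-class shuffle.
#' @return integer vector of fold indices in `1..r`, aligned to `labels`.
#' @export
make_folds <- function(labels, r, seed = 1) {
  labels <- as_labels(labels, names(labels))
  r <- as.integer(r)
  if (r < 2 || r > length(labels)) {
    stop("fold count r = ", r, " out of range [2, ", length(labels), "]")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      if (length(idx) == 0) next
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(r), length(idx))
    }
  })
  fold
}

#' Fit a classifier with internally cross-validated k (BestKNN)
#'
#' For each of `r` stratified folds and each candidate k, the top-`m` SNPs
#' are re-selected by MeanDiff on the fold's training complement alone, a
#' KNN is fitted there, and accuracy is scored on the held-out fold. Each
#' k's score is the mean of its r fold accuracies; the chosen k is the
#' high-watermark (smallest k on ties). The final classifier is then
#' fitted on all subjects using the top-`m` SNPs of the full dataset and
#' the chosen k. With the default grid and r this evaluates 4 x 10
#' selection+fit configurations before the final fit.
#'
#' Per-fold feature re-selection is what makes the internal estimate
#' honest: the held-out fold never influences which SNPs its classifier
#' uses.
#'
#' @param gm subjects x SNPs genotype matrix (QC already applied: complete).
#' @param labels per-subject phenotype.
#' @param m number of SNPs selected by MeanDiff (default 500).
#' @param k_grid candidate neighbour counts (default `c(1, 3, 5, 7)`).
#' @param r internal fold count (default 10). Each class needs at least
#'   `r` members so every training complement contains both classes.
#' @param seed RNG seed (fold assignment).
#' @return list of class `best_knn` with `model` (the final [knn_fit()]
#'   classifier), and `trace` (class `k_trace`): `fold_acc` matrix
#'   [k x fold], `scores` per k, `chosen_k`, `folds`, `fold_selected`
#'   (per-fold selected SNP ids), `seed`.
#' @export
best_knn_fit <- function(gm, labels, m = 500, k_grid = c(1, 3, 5, 7),
                         r = 10, seed = 1) {
  labels <- as_labels(labels, names(labels))
  check_aligned(gm, labels)
  if (anyNA(gm)) stop("BestKNN requires complete genotypes (run QC first)")
  counts <- table(labels)
  if (any(counts < r)) {
    stop("each class needs at least r = ", r, " subjects (have ",
         counts[["case"]], " cases / ", counts[["control"]], " controls)")
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1)) stop("k_grid entries must be >= 1")

  folds <- make_folds(labels, r, seed)
  fold_acc <- matrix(NA_real_, length(k_grid), r,
                     dimnames = list(paste0("k", k_grid), NULL))
  fold_selected <- vector("list", r)
  for (i in seq_len(r)) {
    test <- folds == i
    train_x <- gm[!test, , drop = FALSE]
    train_y <- labels[!test]
    sel <- select_top_m(train_x, train_y, m)
    fold_selected[[i]] <- sel$selected_ids
    tr <- train_x[, sel$selected_idx, drop = FALSE]
    te <- gm[test, sel$selected_idx, drop = FALSE]
    maj <- if (sum(train_y == "case") > sum(train_y == "control")) {
      "case"
    } else {
      "control"
    }
    pred <- knn_predict_multi(tr, train_y, maj, te, k_grid)
    truth <- as.character(labels[test])
    fold_acc[, i] <- rowMeans(pred == matrix(truth, length(k_grid),
                                             length(truth), byrow = TRUE))
  }
  scores <- rowMeans(fold_acc)
  chosen_k <- k_grid[which.max(scores)]  # which.max: first (smallest) on ties

  final_sel <- select_top_m(gm, labels, m)
  model <- knn_fit(gm[, final_sel$selected_idx, drop = FALSE], labels,
                   chosen_k)
  trace <- structure(list(fold_acc = fold_acc,
                          scores = stats::setNames(scores,
                                                   paste0("k", k_grid)),
                          k_grid = k_grid,
                          chosen_k = chosen_k,
                          folds = folds,
                          fold_selected = fold_selected,
                          seed = seed),
                     class = "k_trace")
  structure(list(model = model, trace = trace, selected = final_sel),
            class = "best_knn")
}

#' @export
print.best_knn <- function(x, ...) {
  cat("BestKNN fit\n")
  cat("  internal CV scores:",
      paste(sprintf("%s=%.3f", names(x$trace$scores), x$trace$scores),
            collapse = ", "), "\n")
  cat("  chosen k:", x$trace$chosen_k, "| final SNP panel:",
      length(x$model$snp_ids), "SNPs\n")
  invisible(x)
}
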