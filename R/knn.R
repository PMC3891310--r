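# K-nearest-neighbour classifier over genotype codes.

#' Squared Euclidean distance between two genotype profiles
#'
#' `sum((p - q)^2)` over an m-tuple of genotype codes. With integer codes
#' the computation is exact in double precision.
#'
#' @param p,q numeric vectors of equal length.
#' @return the squared Euclidean (L2^2) distance.
#' @export
sq_euclidean <- function(p, q) {
  if (length(p) != length(q)) {
    stop("profiles differ in length (", length(p), " vs ", length(q), ")")
  }
  sum((p - q)^2)
}

# All pairwise squared Euclidean distances between rows of `a` (t x m) and
# rows of `b` (n x m). Exact for small-integer codes.
sq_euclidean_cross <- function(a, b) {
  ra <- rowSums(a^2)
  rb <- rowSums(b^2)
  d <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

#' Fit (store) a KNN genotype classifier
#'
#' KNN is a lazy learner: fitting stores the reduced training matrix, its
#' labels and the neighbour count. Prediction ranks training subjects by
#' squared Euclidean distance and takes the majority vote of the k nearest.
#'
#' @param x training subjects x m genotype matrix, restricted to the
#'   selected SNPs (columns must be named with SNP ids).
#' @param labels per-subject phenotype, see [as_labels()].
#' @param k neighbour count, `1 <= k <= nrow(x)`.
#' @return object of class `knn_model` with fields `snp_ids`, `x`, `labels`,
#'   `k` and `majority` (the training majority class, used only to resolve
#'   vote ties, which cannot occur for binary labels with odd k).
#' @export
knn_fit <- function(x, labels, k) {
  if (!is.matrix(x)) stop("training data must be a matrix")
  labels <- as_labels(labels, names(labels))
  check_aligned(x, labels)
  k <- as.integer(k)
  if (k < 1 || k > nrow(x)) {
    stop("k = ", k, " out of range [1, ", nrow(x), "]")
  }
  counts <- table(labels)
  majority <- if (counts[["case"]] > counts[["control"]]) "case" else "control"
  structure(list(snp_ids = colnames(x), x = x, labels = labels, k = k,
                 majority = majority),
            class = "knn_model")
}

# Predict with one stored neighbour ordering for several values of k at
# once (k-selection scores 4 k's per fold; the distance sort dominates, so
# share it). Returns a character matrix [length(ks) x nrow(newdata)].
# Tie-breaks: equal distances at the k-th position are resolved by
# ascending training-subject index; vote ties go to `majority`.
knn_predict_multi <- function(train_x, train_labels, majority, newdata, ks) {
  d <- sq_euclidean_cross(newdata, train_x)
  n_train <- nrow(train_x)
  is_case <- train_labels == "case"
  out <- matrix(NA_character_, length(ks), nrow(newdata))
  for (t in seq_len(nrow(newdata))) {
    ord <- order(d[t, ], seq_len(n_train))
    case_votes <- cumsum(is_case[ord])
    for (i in seq_along(ks)) {
      k <- ks[i]
      cv <- case_votes[k]
      out[i, t] <- if (2 * cv > k) "case"
      else if (2 * cv < k) "control"
      else majority
    }
  }
  out
}

#' Predict phenotype labels for new subjects
#'
#' @param object a [knn_fit()] model.
#' @param newdata subjects x m matrix over the model's SNPs (a single
#'   profile may be given as a vector). No missing values.
#' @param ... unused.
#' @return factor of predicted labels (`control`/`case`).
#' @export
predict.knn_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != ncol(object$x)) {
    stop("newdata has ", ncol(newdata), " SNPs; model expects ",
         ncol(object$x))
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$snp_ids)) {
    stop("newdata SNP ids do not match the model's selected SNPs")
  }
  if (anyNA(newdata)) stop("newdata contains missing genotypes")
  pred <- knn_predict_multi(object$x, object$labels, object$majority,
                            newdata, object$k)
  as_labels(pred[1, ], rownames(newdata))
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("KNN classifier: k = %d, %d training subjects, %d SNPs\n",
              x$k, nrow(x$x), ncol(x$x)))
  invisible(x)
}
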