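# MeanDiff univariate feature ranking and top-m selection.

#' MeanDiff score of each SNP
#'
#' The MeanDiff of a SNP is the absolute difference between the mean
#' genotype code (1/2/3) of the cases and of the controls. It is 0 for a
#' SNP whose code distribution is identical in the two groups, at most 2
#' for codes in \{1,2,3\}, and invariant to swapping the class labels.
#' Inputs must be complete: the missing-call filter in [apply_qc()] runs
#' first.
#'
#' @param gm subjects x SNPs genotype matrix (or a single column vector).
#' @param labels per-subject phenotype, see [as_labels()].
#' @return named numeric vector of scores, one per SNP.
#' @export
meandiff <- function(gm, labels) {
  if (!is.matrix(gm)) gm <- matrix(gm, ncol = 1)
  labels <- as_labels(labels, names(labels))
  check_aligned(gm, labels)
  if (anyNA(gm)) stop("MeanDiff requires complete genotypes (run QC first)")
  if (!all(LABEL_LEVELS %in% labels)) {
    stop("MeanDiff requires both cases and controls")
  }
  mu_case <- colMeans(gm[labels == "case", , drop = FALSE])
  mu_ctl <- colMeans(gm[labels == "control", , drop = FALSE])
  abs(mu_case - mu_ctl)
}

#' Select the top-m SNPs by MeanDiff
#'
#' Scores every SNP with [meandiff()] and keeps the `m` largest. Ties at
#' the selection boundary are broken by ascending SNP (column) index, so
#' the selection is deterministic.
#'
#' @param gm subjects x SNPs genotype matrix.
#' @param labels per-subject phenotype.
#' @param m number of SNPs to keep (default 500); clamped to the SNP count
#'   with a warning if larger.
#' @return object of class `feature_ranking`: list with `scores` (named,
#'   input order), `selected_ids` (the m winners, ranked by decreasing
#'   score), `selected_idx` (their column indices) and `m`.
#' @export
select_top_m <- function(gm, labels, m = 500) {
  if (!is.matrix(gm) || ncol(gm) == 0) stop("empty genotype matrix")
  if (m < 1) stop("m must be at least 1")
  if (m > ncol(gm)) {
    warning("m = ", m, " exceeds SNP count ", ncol(gm), "; clamping")
    m <- ncol(gm)
  }
  scores <- meandiff(gm, labels)
  ord <- order(-scores, seq_along(scores))
  idx <- ord[seq_len(m)]
  structure(list(scores = scores,
                 selected_ids = colnames(gm)[idx],
                 selected_idx = idx,
                 m = m),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("MeanDiff ranking:", length(x$scores), "SNPs scored,", x$m,
      "selected\n")
  top <- utils::head(x$selected_idx, 5)
  cat("  top scores:", paste(sprintf("%s=%.4g", names(x$scores)[top],
                                     x$scores[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Write a feature ranking as TSV
#'
#' Columns: `snp_id`, `meandiff`, `selected` (0/1).
#'
#' @param ranking a [select_top_m()] result.
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(snp_id = names(ranking$scores),
                   meandiff = ranking$scores,
                   selected = as.integer(seq_along(ranking$scores) %in%
                                           ranking$selected_idx))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
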