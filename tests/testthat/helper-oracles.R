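# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (elementwise loops, full sorts) so they cannot share a
# defect with the vectorised implementation paths they check.

# Exhaustive KNN: per-test-point loop, elementwise squared distance, full
# sort with index tie-break, hand-counted vote with majority fallback.
oracle_knn <- function(train_x, train_y, test_x, k) {
  train_y <- as.character(train_y)
  maj <- if (sum(train_y == "case") > sum(train_y == "control")) {
    "case"
  } else {
    "control"
  }
  apply(test_x, 1, function(pt) {
    d <- apply(train_x, 1, function(tr) sum((pt - tr)^2))
    nb <- train_y[order(d, seq_along(d))][seq_len(k)]
    votes_case <- sum(nb == "case")
    if (votes_case * 2 > k) "case"
    else if (votes_case * 2 < k) "control"
    else maj
  })
}

# Exhaustive top-m: per-column mean-difference loop, full decreasing sort.
oracle_top_m <- function(gm, labels, m) {
  labels <- as.character(labels)
  s <- vapply(seq_len(ncol(gm)), function(j) {
    abs(mean(gm[labels == "case", j]) - mean(gm[labels == "control", j]))
  }, numeric(1))
  order(-s, seq_along(s))[seq_len(m)]
}

# A complete (no missing calls) random genotype matrix with labels.
random_instance <- function(n_case, n_control, p, seed) {
  withr::with_seed(seed, {
    n <- n_case + n_control
    gm <- matrix(sample(1:3, n * p, replace = TRUE), n, p,
                 dimnames = list(sprintf("S%03d", seq_len(n)),
                                 sprintf("snp%04d", seq_len(p))))
    labels <- as_labels(rep(c("case", "control"), c(n_case, n_control)),
                        rownames(gm))
    list(gm = gm, labels = labels)
  })
}
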