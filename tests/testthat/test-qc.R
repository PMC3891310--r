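test_that("minor allele frequency counts variant alleles correctly", {
  expect_equal(minor_allele_frequency(rep(1L, 10)), 0)
  # hand count: variant alleles 0+1+2+1 = 4 of 8
  expect_equal(minor_allele_frequency(c(1L, 2L, 3L, 2L)), 0.5)
  # variant allele is the major one: minor frequency is 1 - 1 = 0
  expect_equal(minor_allele_frequency(c(3L, 3L, 3L, 3L)), 0)
  # missing calls are excluded from the denominator: 1 variant of 6 alleles
  expect_equal(minor_allele_frequency(c(1L, 2L, NA, NA, 1L)), 1 / 6)
  expect_error(minor_allele_frequency(c(NA_integer_, NA_integer_)),
               "missing")
})

test_that("HWE chi-square statistic matches hand-derived counts", {
  # exact HWE proportions at q = 0.5
  g <- rep(c(1L, 2L, 3L), c(25, 50, 25))
  res <- hwe_test(g)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  # counts (50, 0, 50): expected (25, 50, 25), chi2 = 25 + 50 + 25 = 100
  res2 <- hwe_test(rep(c(1L, 3L), c(50, 50)))
  expect_equal(res2$chi2, 100)
  expect_lt(res2$p, 1e-20)
  # monomorphic column fits trivially
  res3 <- hwe_test(rep(1L, 100))
  expect_equal(res3$chi2, 0)
  expect_equal(res3$p, 1)
  expect_error(hwe_test(rep(NA_integer_, 5)), "non-missing")
})

test_that("HWE statistic agrees with stats::chisq.test as the oracle", {
  set.seed(17)
  for (i in 1:20) {
    g <- sample(1:3, 200, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    obs <- tabulate(g, 3L)
    q <- (obs[2] + 2 * obs[3]) / (2 * sum(obs))
    exp_p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    ref <- suppressWarnings(stats::chisq.test(obs, p = exp_p))
    mine <- hwe_test(g)
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
    # same statistic, but our p uses 1 df (allele frequency estimated)
    expect_equal(mine$p, stats::pchisq(mine$chi2, 1, lower.tail = FALSE))
  }
})

make_clean_matrix <- function(p = 6) {
  # each class carries exact HWE counts at q = 0.3 -- (49, 42, 9) per 100
  # subjects -- so the control-only HWE test sees a perfect fit
  col <- rep(rep(c(1L, 2L, 3L), c(49, 42, 9)), 2)
  gm <- matrix(rep(col, p), ncol = p,
               dimnames = list(sprintf("S%03d", 1:200),
                               sprintf("snp%04d", 1:p)))
  labels <- as_labels(rep(c("case", "control"), each = 100),
                      rownames(gm))
  list(gm = gm, labels = labels)
}

test_that("clean common variants in perfect HWE all survive", {
  cl <- make_clean_matrix()
  qc <- apply_qc(cl$gm, cl$labels)
  expect_equal(ncol(qc$genotypes), ncol(cl$gm))
  expect_true(all(qc$report$passed))
  expect_true(all(qc$report$failed_filters == ""))
})

test_that("a single missing call removes a SNP regardless of MAF and HWE", {
  cl <- make_clean_matrix()
  cl$gm[1, 2] <- NA
  qc <- apply_qc(cl$gm, cl$labels)
  expect_false("snp0002" %in% colnames(qc$genotypes))
  row <- qc$report[qc$report$snp_id == "snp0002", ]
  expect_equal(row$failed_filters, "missing")
  expect_equal(row$n_missing, 1L)
  # diagnostics still computed on the available calls
  expect_false(is.na(row$maf))
  expect_false(is.na(row$hwe_p))
})

test_that("boundary convention: MAF exactly at the threshold survives", {
  cl <- make_clean_matrix(p = 2)
  # exact MAF 0.05: 20 variant alleles of 400, heterozygotes split evenly
  # across the classes so the control HWE fit stays unremarkable
  cl$gm[, 2] <- rep(rep(c(1L, 2L), c(90, 10)), 2)
  qc <- apply_qc(cl$gm, cl$labels)
  expect_true(qc$report$passed[2])
  expect_equal(qc$report$maf[2], 0.05)
})

test_that("planted QC violations are caught at n = 2000 (simulator truth)", {
  d <- simulate_genotypes(sim_config(
    n_cases = 1000, n_controls = 1000, n_snps = 200,
    maf_range = c(0.1, 0.5),
    n_missing_snps = 10, missing_rate = 0.02,
    n_low_maf = 10, low_maf_value = 0.01,
    n_hwe_violating = 10, hwe_inbreeding_f = 0.8, seed = 7))
  qc <- apply_qc(d$genotypes, d$labels)
  removed <- qc$report$snp_id[!qc$report$passed]
  expect_true(all(d$truth$missing %in% removed))
  expect_gte(sum(d$truth$low_maf %in% removed), 9)
  expect_gte(sum(d$truth$hwe_violating %in% removed), 9)
})

test_that("QC is idempotent and the report partitions the SNP set", {
  d <- simulate_genotypes(sim_config(n_cases = 100, n_controls = 100,
                                     n_snps = 150, n_missing_snps = 5,
                                     n_low_maf = 5, seed = 13))
  qc <- apply_qc(d$genotypes, d$labels)
  expect_equal(sum(qc$report$passed) + sum(!qc$report$passed),
               ncol(d$genotypes))
  qc2 <- apply_qc(qc$genotypes, d$labels)
  expect_identical(qc2$genotypes, qc$genotypes)
  expect_true(all(qc2$report$passed))
})

test_that("degenerate inputs raise informative errors", {
  cl <- make_clean_matrix()
  expect_error(apply_qc(cl$gm, rep("case", 200)), "control")
  cl$gm[1, ] <- NA
  expect_error(apply_qc(cl$gm, cl$labels), "no SNPs survive")
})
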