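# SNP-level quality control: missing calls, HWE in controls, MAF.

#' Minor allele frequency of one genotype column
#'
#' Counts variant alleles over the non-missing calls (code 1 contributes 0,
#' code 2 one, code 3 two) and returns the frequency of the rarer allele,
#' `min(f, 1 - f)`, always in `[0, 0.5]`.
#'
#' @param genotypes integer vector of codes 1/2/3 with `NA` for missing.
#' @return minor allele frequency.
#' @export
minor_allele_frequency <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) stop("MAF undefined: all calls missing")
  f <- sum(g - 1L) / (2 * length(g))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test for one genotype column
#'
#' Pearson chi-square goodness-of-fit (1 degree of freedom) of the observed
#' genotype counts against the HWE-expected counts at the allele frequency
#' estimated from the same sample. Monomorphic columns fit HWE perfectly by
#' construction and return `chi2 = 0, p = 1`. No continuity correction is
#' applied. Conventionally assessed in controls only (case genotype
#' frequencies at a true risk locus deviate from HWE even in a well-typed
#' SNP); [apply_qc()] enforces that restriction.
#'
#' @param genotypes integer vector of codes 1/2/3 with `NA` for missing.
#' @return list with `chi2` and `p`.
#' @export
hwe_test <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) stop("HWE test undefined: no non-missing genotypes")
  obs <- tabulate(g, nbins = 3L)
  n <- sum(obs)
  q <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (q == 0 || q == 1) return(list(chi2 = 0, p = 1))
  expd <- n * hwe_probs(q)
  chi2 <- sum((obs - expd)^2 / expd)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Apply the three SNP-level quality-control filters
#'
#' Removes every SNP that (1) has one or more missing calls anywhere, or
#' (2) deviates from Hardy-Weinberg equilibrium in controls at
#' `hwe_alpha`, or (3) has minor allele frequency below `maf_min` computed
#' over all subjects. The three filters are evaluated independently on the
#' available (non-missing) calls — a SNP's report row lists every filter it
#' fails, and a single missing call fails the SNP regardless of its other
#' statistics. Filters are applied in one pass over the original matrix;
#' statistics are not re-estimated after removals.
#'
#' @param gm subjects x SNPs genotype matrix (codes 1/2/3, `NA` missing).
#' @param labels per-subject phenotype, see [as_labels()]. HWE is assessed
#'   in the control subjects only.
#' @param maf_min MAF threshold; SNPs with `maf < maf_min` are removed
#'   (a SNP exactly at the threshold survives).
#' @param hwe_alpha nominal HWE p-value threshold (removal if `p < hwe_alpha`).
#' @return list of class `qc_result` with `genotypes` (the filtered matrix,
#'   SNP order preserved) and `report` (data.frame: `snp_id`, `n_missing`,
#'   `maf`, `hwe_chi2`, `hwe_p`, `failed_filters` — comma-joined subset of
#'   `missing,hwe,maf`, empty string if the SNP survived — and `passed`).
#' @export
apply_qc <- function(gm, labels, maf_min = 0.05, hwe_alpha = 0.001) {
  check_genotypes(gm)
  labels <- as_labels(labels, names(labels))
  check_aligned(gm, labels)
  if (!any(labels == "control")) {
    stop("HWE filter requires at least one control subject")
  }
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_alpha > 0, hwe_alpha <= 1)

  n_missing <- colSums(is.na(gm))

  count3 <- function(x) {
    rbind(colSums(x == 1L, na.rm = TRUE),
          colSums(x == 2L, na.rm = TRUE),
          colSums(x == 3L, na.rm = TRUE))
  }

  # MAF over all subjects
  obs_all <- count3(gm)
  n_called <- colSums(obs_all)
  f_var <- ifelse(n_called > 0,
                  (obs_all[2, ] + 2 * obs_all[3, ]) / (2 * n_called), NA_real_)
  maf <- pmin(f_var, 1 - f_var)

  # HWE in controls
  obs_ctl <- count3(gm[labels == "control", , drop = FALSE])
  n_ctl <- colSums(obs_ctl)
  q_ctl <- ifelse(n_ctl > 0, (obs_ctl[2, ] + 2 * obs_ctl[3, ]) / (2 * n_ctl),
                  NA_real_)
  e1 <- n_ctl * (1 - q_ctl)^2
  e2 <- n_ctl * 2 * q_ctl * (1 - q_ctl)
  e3 <- n_ctl * q_ctl^2
  hwe_chi2 <- rep(NA_real_, ncol(gm))
  poly <- !is.na(q_ctl) & q_ctl > 0 & q_ctl < 1
  hwe_chi2[poly] <- (obs_ctl[1, poly] - e1[poly])^2 / e1[poly] +
    (obs_ctl[2, poly] - e2[poly])^2 / e2[poly] +
    (obs_ctl[3, poly] - e3[poly])^2 / e3[poly]
  hwe_chi2[!is.na(q_ctl) & !poly] <- 0  # monomorphic in controls
  hwe_p <- ifelse(is.na(hwe_chi2), NA_real_,
                  stats::pchisq(hwe_chi2, df = 1, lower.tail = FALSE))

  fail_missing <- n_missing > 0
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  fail_maf <- !is.na(maf) & maf < maf_min

  failed <- mapply(function(m, h, f) {
    paste(c("missing", "hwe", "maf")[c(m, h, f)], collapse = ",")
  }, fail_missing, fail_hwe, fail_maf)
  passed <- !(fail_missing | fail_hwe | fail_maf)

  report <- data.frame(snp_id = colnames(gm),
                       n_missing = as.integer(n_missing),
                       maf = maf,
                       hwe_chi2 = hwe_chi2,
                       hwe_p = hwe_p,
                       failed_filters = failed,
                       passed = passed,
                       row.names = NULL,
                       stringsAsFactors = FALSE)
  if (!any(passed)) {
    stop("no SNPs survive quality control; nothing left to analyse")
  }
  structure(list(genotypes = gm[, passed, drop = FALSE],
                 report = report,
                 thresholds = list(maf_min = maf_min, hwe_alpha = hwe_alpha)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("SNP quality control (maf_min =", x$thresholds$maf_min,
      ", hwe_alpha =", x$thresholds$hwe_alpha, ")\n")
  cat(sprintf("  %d of %d SNPs pass; removed: %d with missing calls, %d HWE, %d low MAF\n",
              sum(r$passed), nrow(r),
              sum(grepl("missing", r$failed_filters)),
              sum(grepl("hwe", r$failed_filters)),
              sum(grepl("\\bmaf\\b", r$failed_filters))))
  invisible(x)
}
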