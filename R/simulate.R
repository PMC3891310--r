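# Synthetic case-control genotype simulator with planted structure.

#' Simulation configuration for synthetic case-control genotype data
#'
#' Defines a cohort of unlinked biallelic SNPs coded 1 (wild-type
#' homozygote), 2 (heterozygote), 3 (variant homozygote). Null SNPs are in
#' Hardy-Weinberg equilibrium (HWE) at a minor allele frequency (MAF) drawn
#' uniformly from `maf_range`, identically in cases and controls. On top of
#' that, four kinds of structure can be planted on disjoint SNP sets:
#'
#' * **effect SNPs** — the variant-allele frequency is shifted upward by
#'   `effect_delta` in cases (capped at 0.999), each group in HWE within
#'   itself; the expected MeanDiff of such a SNP is `2 * effect_delta`
#'   (see [expected_meandiff()]).
#' * **HWE-violating SNPs** — genotypes for *all* subjects are drawn from
#'   inbreeding-distorted proportions
#'   `((1-q)^2 + Fq(1-q), 2q(1-q)(1-F), q^2 + Fq(1-q))` with
#'   `F = hwe_inbreeding_f` (heterozygote deficit).
#' * **low-MAF SNPs** — allele frequency fixed at `low_maf_value`
#'   (below the conventional 5% common-variant cutoff).
#' * **missing-call SNPs** — each genotype is independently replaced by a
#'   missing call with probability `missing_rate` (at least one call is
#'   forced missing so the SNP is guaranteed to trip the missingness
#'   filter).
#'
#' The defaults mirror a single-cohort breast-cancer style study: 302 cases
#' and 321 controls, 10,000 SNPs, common variants only, no planted
#' structure.
#'
#' @param n_cases,n_controls subject counts per class.
#' @param n_snps total SNP count.
#' @param maf_range length-2 numeric, MAF bounds in (0, 0.5] for null and
#'   effect SNPs.
#' @param n_effect_snps,effect_delta count of effect SNPs and the case
#'   allele-frequency shift in `[0, 0.5]`.
#' @param n_hwe_violating,hwe_inbreeding_f count of HWE-violating SNPs and
#'   the inbreeding coefficient `F` in `[0, 1]` used to distort them.
#' @param n_low_maf,low_maf_value count of rare SNPs and their allele
#'   frequency (< 0.05).
#' @param n_missing_snps,missing_rate count of SNPs with missing calls and
#'   the per-genotype missingness probability.
#' @param seed RNG seed; identical configurations produce byte-identical
#'   datasets.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_genotypes()]
#' @export
sim_config <- function(n_cases = 302, n_controls = 321, n_snps = 10000,
                       maf_range = c(0.05, 0.5),
                       n_effect_snps = 0, effect_delta = 0,
                       n_hwe_violating = 0, hwe_inbreeding_f = 0.8,
                       n_low_maf = 0, low_maf_value = 0.01,
                       n_missing_snps = 0, missing_rate = 0.05,
                       seed = 1) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              n_effect_snps = as.integer(n_effect_snps),
              effect_delta = as.numeric(effect_delta),
              n_hwe_violating = as.integer(n_hwe_violating),
              hwe_inbreeding_f = as.numeric(hwe_inbreeding_f),
              n_low_maf = as.integer(n_low_maf),
              low_maf_value = as.numeric(low_maf_value),
              n_missing_snps = as.integer(n_missing_snps),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid '", field, "': ", msg, call. = FALSE)
  }
  chk(cfg$n_cases >= 0, "n_cases", "must be a non-negative count")
  chk(cfg$n_controls >= 0, "n_controls", "must be a non-negative count")
  chk(cfg$n_cases + cfg$n_controls >= 1, "n_cases", "cohort must be non-empty")
  chk(cfg$n_snps >= 1, "n_snps", "must be a positive count")
  chk(length(cfg$maf_range) == 2 && all(cfg$maf_range > 0) &&
        all(cfg$maf_range <= 0.5) && cfg$maf_range[1] <= cfg$maf_range[2],
      "maf_range", "must be an increasing pair in (0, 0.5]")
  chk(cfg$effect_delta >= 0 && cfg$effect_delta <= 0.5,
      "effect_delta", "must lie in [0, 0.5]")
  chk(cfg$hwe_inbreeding_f >= 0 && cfg$hwe_inbreeding_f <= 1,
      "hwe_inbreeding_f", "must lie in [0, 1]")
  chk(cfg$low_maf_value > 0 && cfg$low_maf_value < 0.05,
      "low_maf_value", "must be a frequency below 0.05")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate <= 1,
      "missing_rate", "must be a probability")
  planted <- cfg$n_effect_snps + cfg$n_hwe_violating + cfg$n_low_maf +
    cfg$n_missing_snps
  chk(all(c(cfg$n_effect_snps, cfg$n_hwe_violating, cfg$n_low_maf,
            cfg$n_missing_snps) >= 0),
      "n_effect_snps", "planted counts must be non-negative")
  chk(planted <= cfg$n_snps, "n_snps",
      "planted SNP counts exceed the total SNP count")
  structure(cfg, class = "sim_config")
}

# HWE genotype-code probabilities (codes 1/2/3) at variant allele frequency q.
hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

# Inbreeding-distorted genotype proportions (heterozygote deficit F).
inbred_probs <- function(q, f) {
  c((1 - q)^2 + f * q * (1 - q),
    2 * q * (1 - q) * (1 - f),
    q^2 + f * q * (1 - q))
}

#' Simulate a case-control SNP genotype dataset with known planted structure
#'
#' Draws genotypes per subject and SNP from the group-specific genotype
#' distributions described in [sim_config()]. The returned truth lists name
#' exactly which SNPs carry planted effects or quality-control violations,
#' so downstream filters and selectors can be scored against ground truth.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_dataset`: a list with `genotypes`
#'   (subjects x SNPs integer matrix, codes 1/2/3, `NA` = missing call),
#'   `labels` (factor, see [as_labels()]), `truth` (lists of planted
#'   `effect`, `hwe_violating`, `low_maf`, `missing` SNP ids and the
#'   per-SNP control/case allele frequencies `q_control`, `q_case`), and
#'   `config` (the echoed configuration).
#' @examples
#' d <- simulate_genotypes(sim_config(n_cases = 20, n_controls = 20,
#'                                    n_snps = 50, seed = 7))
#' table(d$genotypes[, 1], useNA = "ifany")
#' @export
simulate_genotypes <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_cases + config$n_controls
  p <- config$n_snps
  subject_ids <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
  snp_ids <- sprintf("snp%0*d", max(4L, nchar(p)), seq_len(p))
  labels <- as_labels(rep(c("case", "control"),
                          c(config$n_cases, config$n_controls)),
                      subject_ids)
  is_case <- labels == "case"

  with_seed(config$seed, {
    planted_total <- config$n_effect_snps + config$n_hwe_violating +
      config$n_low_maf + config$n_missing_snps
    planted_idx <- if (planted_total > 0) {
      sample.int(p, planted_total)
    } else {
      integer(0)
    }
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- planted_idx[seq_len(k)]
      planted_idx <<- planted_idx[-seq_len(k)]
      out
    }
    idx_effect <- sort(take(config$n_effect_snps))
    idx_hwe <- sort(take(config$n_hwe_violating))
    idx_lowmaf <- sort(take(config$n_low_maf))
    idx_missing <- sort(take(config$n_missing_snps))

    q_control <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    q_control[idx_lowmaf] <- config$low_maf_value
    q_case <- q_control
    q_case[idx_effect] <- pmin(q_control[idx_effect] + config$effect_delta,
                               0.999)

    gm <- matrix(NA_integer_, n, p, dimnames = list(subject_ids, snp_ids))
    for (j in seq_len(p)) {
      if (j %in% idx_hwe) {
        gm[, j] <- sample.int(3L, n, replace = TRUE,
                              prob = inbred_probs(q_control[j],
                                                  config$hwe_inbreeding_f))
      } else if (q_case[j] != q_control[j]) {
        col <- integer(n)
        col[!is_case] <- sample.int(3L, sum(!is_case), replace = TRUE,
                                    prob = hwe_probs(q_control[j]))
        col[is_case] <- sample.int(3L, sum(is_case), replace = TRUE,
                                   prob = hwe_probs(q_case[j]))
        gm[, j] <- col
      } else {
        gm[, j] <- sample.int(3L, n, replace = TRUE,
                              prob = hwe_probs(q_control[j]))
      }
    }
    for (j in idx_missing) {
      miss <- stats::runif(n) < config$missing_rate
      if (!any(miss)) miss[sample.int(n, 1L)] <- TRUE
      gm[miss, j] <- NA_integer_
    }

    structure(list(genotypes = gm,
                   labels = labels,
                   truth = list(effect = snp_ids[idx_effect],
                                hwe_violating = snp_ids[idx_hwe],
                                low_maf = snp_ids[idx_lowmaf],
                                missing = snp_ids[idx_missing],
                                q_control = stats::setNames(q_control, snp_ids),
                                q_case = stats::setNames(q_case, snp_ids)),
                   config = config),
              class = "sim_dataset")
  })
}

#' Expected MeanDiff of a SNP from its group allele frequencies
#'
#' Under Hardy-Weinberg proportions the mean genotype code at variant allele
#' frequency `q` is `1 * (1-q)^2 + 2 * 2q(1-q) + 3 * q^2 = 1 + 2q`, so the
#' expected absolute case-control difference of code means is
#' `2 * |q_case - q_control|`. This is the closed form that links the
#' simulator's planted allele-frequency shift to the MeanDiff ranking
#' statistic, used for parameter-recovery tests.
#'
#' @param q_control,q_case variant allele frequencies in (0, 1).
#' @return the expected MeanDiff value.
#' @export
expected_meandiff <- function(q_control, q_case) {
  if (any(q_control <= 0 | q_control >= 1) || any(q_case <= 0 | q_case >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)")
  }
  2 * abs(q_case - q_control)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic case-control SNP dataset\n")
  cat(sprintf("  subjects: %d (%d cases / %d controls)\n",
              nrow(x$genotypes), sum(x$labels == "case"),
              sum(x$labels == "control")))
  cat(sprintf("  SNPs: %d (planted: %d effect, %d HWE-violating, %d low-MAF, %d with missing calls)\n",
              ncol(x$genotypes), length(x$truth$effect),
              length(x$truth$hwe_violating), length(x$truth$low_maf),
              length(x$truth$missing)))
  invisible(x)
}
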