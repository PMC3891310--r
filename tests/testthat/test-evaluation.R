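test_that("confusion-matrix metrics reproduce the published cohort arithmetic", {
  # 623-subject cohort: 302 cases (187 predicted case), 321 controls
  m1 <- metrics(new_confusion(tp = 187, fn = 115, fp = 137, tn = 184))
  expect_equal(unname(m1$percent["accuracy"]), 59.55)
  expect_equal(unname(m1$percent["sensitivity"]), 61.92)
  expect_equal(unname(m1$percent["specificity"]), 57.32)
  # 2287-subject external cohort
  m2 <- metrics(new_confusion(tp = 683, fn = 462, fp = 447, tn = 695))
  expect_equal(unname(m2$percent["accuracy"]), 60.25)
  expect_equal(unname(m2$percent["precision"]), 60.44)
  expect_equal(unname(m2$percent["sensitivity"]), 59.65)
  expect_equal(unname(m2$percent["specificity"]), 60.86)
})

test_that("perfect classifiers and undefined ratios are reported correctly", {
  mp <- metrics(new_confusion(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_true(all(mp$percent == 100))
  # no predicted cases: precision undefined, never silently zero
  m0 <- metrics(new_confusion(tp = 0, fn = 5, fp = 0, tn = 5))
  expect_true(is.na(m0$proportions["precision"]))
  expect_equal(unname(m0$proportions["accuracy"]), 0.5)
  expect_error(metrics(new_confusion(0, 0, 0, 0)), "empty")
})

test_that("majority baseline matches the published cohort compositions", {
  lab1 <- rep(c("control", "case"), c(321, 302))
  expect_equal(as_percent(majority_baseline(lab1)), 51.52)
  lab2 <- rep(c("case", "control"), c(1145, 1142))
  expect_equal(as_percent(majority_baseline(lab2)), 50.07)
  expect_equal(as_percent(majority_baseline(rep(c("case", "control"), 50))),
               50)
})

test_that("nested LOOCV makes exactly one prediction per subject", {
  inst <- random_instance(12, 12, 40, 44)
  res <- nested_loocv(inst$gm, inst$labels, m = 10, r = 5, seed = 2)
  expect_length(res$predictions, 24)
  expect_equal(res$cm$tp + res$cm$fn + res$cm$fp + res$cm$tn, 24L)
  expect_equal(res$cm$tp + res$cm$fn, 12L)   # actual cases
  expect_equal(res$mode, "nested")
  # fold log: one record per held-out subject with its k and SNP panel
  expect_length(res$fold_log, 24)
  expect_equal(res$fold_log[[3]]$held_out, rownames(inst$gm)[3])
  expect_true(res$fold_log[[3]]$chosen_k %in% c(1, 3, 5, 7))
  expect_length(res$fold_log[[3]]$selected_snps, 10)
  # stored metrics are reproducible from the stored confusion matrix
  expect_equal(res$proportions, metrics(res$cm)$proportions)
})

test_that("nested LOOCV tracks truth on separable data and chance on null", {
  strong <- simulate_genotypes(sim_config(n_cases = 30, n_controls = 30,
                                          n_snps = 120, n_effect_snps = 20,
                                          effect_delta = 0.45,
                                          maf_range = c(0.05, 0.3),
                                          seed = 3))
  res_s <- nested_loocv(strong$genotypes, strong$labels, m = 20, r = 5,
                        seed = 4, keep_fold_log = FALSE)
  expect_gte(res_s$proportions[["accuracy"]], 0.8)

  null <- simulate_genotypes(sim_config(n_cases = 20, n_controls = 20,
                                        n_snps = 100, seed = 6))
  res_n <- nested_loocv(null$genotypes, null$labels, m = 20, r = 5,
                        seed = 8, keep_fold_log = FALSE)
  se <- sqrt(0.25 / 40)
  expect_lt(abs(res_n$proportions[["accuracy"]] - 0.5), 4 * se)
})

test_that("with no selection step the biased and nested variants coincide", {
  # m = all SNPs makes full-data selection vacuous, so the two procedures
  # are the same algorithm and must agree exactly under the same seed
  inst <- random_instance(10, 10, 15, 55)
  nb <- nested_loocv(inst$gm, inst$labels, m = 15, r = 5, seed = 9,
                     keep_fold_log = FALSE)
  bb <- biased_loocv(inst$gm, inst$labels, m = 15, r = 5, seed = 9,
                     keep_fold_log = FALSE)
  expect_equal(bb$mode, "biased")
  expect_equal(bb$predictions, nb$predictions)
  expect_equal(bb$proportions, nb$proportions)
})

test_that("full-data feature selection inflates apparent accuracy on null data", {
  # small-scale version of the selection-bias demonstration (the
  # acceptance suite runs the full-size one)
  null <- simulate_genotypes(sim_config(n_cases = 20, n_controls = 20,
                                        n_snps = 2000, seed = 10))
  nb <- nested_loocv(null$genotypes, null$labels, m = 100, r = 5,
                     seed = 11, keep_fold_log = FALSE)
  bb <- biased_loocv(null$genotypes, null$labels, m = 100, r = 5,
                     seed = 11, keep_fold_log = FALSE)
  expect_gt(bb$proportions[["accuracy"]] - nb$proportions[["accuracy"]],
            0.15)
})

test_that("permutation p-value follows the add-one estimator and its bounds", {
  d <- simulate_genotypes(sim_config(n_cases = 10, n_controls = 10,
                                     n_snps = 30, n_effect_snps = 5,
                                     effect_delta = 0.4, seed = 14))
  pt <- permutation_test(d$genotypes, d$labels, m = 10, r = 5, B = 9,
                         seed = 15)
  expect_length(pt$permuted_accuracies, 9)
  expect_equal(pt$exceed_count,
               sum(pt$permuted_accuracies >= pt$observed_accuracy))
  expect_equal(pt$p_value, (pt$exceed_count + 1) / 10)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  # monotonicity: a higher observed accuracy can never raise the p-value
  p_at <- function(obs) (sum(pt$permuted_accuracies >= obs) + 1) / 10
  obs_grid <- sort(c(pt$observed_accuracy, pt$permuted_accuracies))
  expect_true(all(diff(vapply(obs_grid, p_at, numeric(1))) <= 0))
  expect_error(permutation_test(d$genotypes, d$labels, B = 0), "at least 1")
})

test_that("accuracy varies smoothly across the panel-size sweep", {
  d <- simulate_genotypes(sim_config(n_cases = 15, n_controls = 15,
                                     n_snps = 60, n_effect_snps = 10,
                                     effect_delta = 0.4, seed = 16))
  sw <- m_sweep(d$genotypes, d$labels, m_grid = c(10, 20, 30), r = 5,
                seed = 17)
  expect_equal(sw$m, c(10, 20, 30))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
})
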