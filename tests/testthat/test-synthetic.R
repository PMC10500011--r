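test_that("coupling calibration is the closed-form identity and validates input", {
  expect_identical(calibrate_coupling(0), 0)
  expect_identical(calibrate_coupling(1), 1)
  expect_error(calibrate_coupling(1.2), "<= 1")

  # Monte-Carlo check of the construction at target 0.5: the empirical mean
  # Pearson over many simulated pairs matches the closed form.
  rho <- calibrate_coupling(0.5)
  set.seed(11)
  r <- replicate(10000, {
    z <- rnorm(100)
    cor(z, rho * z + sqrt(1 - rho^2) * rnorm(100))
  })
  expect_gt(mean(r), 0.48)
  expect_lt(mean(r), 0.52)
})

test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(cohort_config(seed = 1, n_genes = 200,
                                     n_matched_pairs = 200, n_methylation = 50))
  b <- simulate_cohort(cohort_config(seed = 1, n_genes = 200,
                                     n_matched_pairs = 200, n_methylation = 50))
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$clinical$pfs_time, b$clinical$pfs_time)
  expect_identical(a$true_fractions, b$true_fractions)
  c2 <- simulate_cohort(cohort_config(seed = 2, n_genes = 200,
                                      n_matched_pairs = 200, n_methylation = 50))
  expect_false(identical(a$mrna$values, c2$mrna$values))
})

test_that("cohort structure honors its config invariants", {
  co <- simulate_cohort(cohort_config(seed = 3, n_genes = 300,
                                      n_matched_pairs = 250, n_methylation = 40))
  expect_identical(co$mrna$sample_ids, co$protein$sample_ids)
  expect_identical(co$mrna$sample_ids, co$methylation$sample_ids)
  expect_identical(co$clinical$sample_id, co$mrna$sample_ids)
  expect_identical(nrow(co$protein$values), 250L)
  expect_equal(unname(rowSums(co$true_fractions)), rep(1, 28))
  expect_true(all(co$methylation$values >= 0 & co$methylation$values <= 1))
  expect_identical(as.vector(table(co$true_labels)), c(14L, 14L))
  expect_error(simulate_cohort(cohort_config(n_matched_pairs = 3000)),
               "n_matched_pairs")
})

test_that("null configuration produces no group signal beyond chance", {
  co <- simulate_cohort(null_config(seed = 5))
  de <- differential_features(co$mrna, co$true_labels)
  core <- de[grep("^G", de$feature_id), ]
  # p-value uniformity (Kolmogorov-Smirnov at 0.01) and max |t| in null range
  ks <- suppressWarnings(ks.test(core$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_false(any(core$significant & abs(core$log2_fc) > 2))
})

test_that("planted differential features are recovered at the default effect size", {
  co <- simulate_cohort(cohort_config(seed = 2))
  for (layer in c("mrna", "protein")) {
    de <- differential_features(co[[layer]], co$true_labels)
    hits <- de$feature_id[de$significant]
    rec <- mean(co$true_de_features[[layer]]$feature_id %in% hits)
    expect_gt(rec, 0.9)
  }
})

test_that("median matched-pair correlation tracks coupling_rho", {
  co <- simulate_cohort(cohort_config(seed = 8, coupling_rho = 0.4))
  al <- suppressMessages(align_cohort(list(co$mrna, co$protein)))
  pc <- pair_correlations(match_pairs(al$matrices[[1]], al$matrices[[2]]))
  expect_gt(pc$median_r, 0.37)
  expect_lt(pc$median_r, 0.43)
})

test_that("bulk mixtures are consistent with the planted fractions in the noiseless limit", {
  co <- simulate_cohort(cohort_config(seed = 4, mixture_noise_sd = 0))
  dec <- estimate_fractions(co$mrna, co$signature)
  rmse <- sqrt(mean((dec$fractions - co$true_fractions)^2))
  expect_lt(rmse, 1e-8)
})

test_that("survival simulation has correct null behavior, power and degenerate limits", {
  # equal hazards: log-rank p roughly uniform
  set.seed(21)
  frac_sig <- mean(sapply(1:400, function(i) {
    labels <- rep(c("a", "b"), each = 20)
    s <- simulate_survival(labels, c(0.02, 0.02), censor_rate = 0.005, seed = i)
    logrank_test(s$pfs_time, s$pfs_event, labels)$p <= 0.05
  }))
  expect_gt(frac_sig, 0.02)
  expect_lt(frac_sig, 0.08)

  # hazard ratio 3, n = 100/group, no censoring: near-certain detection
  power <- mean(sapply(1:100, function(i) {
    labels <- rep(c("a", "b"), each = 100)
    s <- simulate_survival(labels, c(0.03, 0.01), censor_rate = 0, seed = i)
    logrank_test(s$pfs_time, s$pfs_event, labels)$p <= 0.05
  }))
  expect_gte(power, 0.95)

  # overwhelming censoring: no events
  s <- simulate_survival(rep(c("a", "b"), each = 5), c(0.01, 0.01),
                         censor_rate = 1e9, seed = 1)
  expect_identical(sum(s$pfs_event), 0)
  expect_error(simulate_survival(rep(c("a", "b"), each = 3), c(0, 0.1)),
               "positive")
})

test_that("cohort writer emits all layers plus ground-truth sidecars", {
  co <- simulate_cohort(cohort_config(seed = 1, n_genes = 100,
                                      n_matched_pairs = 80, n_methylation = 20))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mrna.tsv", "protein.tsv", "methylation.tsv", "clinical.tsv",
      "signature_matrix.tsv", "truth_labels.tsv", "truth_fractions.tsv")))))
  back <- read_omic_matrix(file.path(dir, "protein.tsv"), "protein")
  expect_lt(max(abs(back$values - co$protein$values)), 1e-9)
})
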