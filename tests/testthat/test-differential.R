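labelled_matrix <- function(values, ids = sprintf("g%02d", seq_len(nrow(values)))) {
  omic_matrix(values, "mrna", feature_ids = ids,
              sample_ids = sprintf("s%02d", seq_len(ncol(values))))
}

test_that("differential table has closed-form behavior on constructed features", {
  v <- rbind(c(0, 0, 0, 2, 2, 2),    # FC = 2^-2 = 0.25, clearly significant
             c(1, 1, 1, 1, 1, 1),    # identical: t = 0, FC = 1
             c(5, 6, 4, 5.1, 6.1, 3.9))
  labels <- rep(c("a", "b"), each = 3)
  de <- differential_features(labelled_matrix(v), labels)
  row1 <- de[de$feature_id == "g01", ]
  expect_equal(row1$fold_change, 0.25)
  expect_true(row1$significant)
  row2 <- de[de$feature_id == "g02", ]
  expect_identical(row2$t, 0)
  expect_identical(row2$p, 1)
  expect_equal(row2$fold_change, 1)
  # sorted by p, q >= p, q monotone in p-rank
  expect_true(!is.unsorted(de$p))
  expect_true(all(de$q >= de$p - 1e-12))
  expect_true(!is.unsorted(de$q))
})

test_that("Welch t matches stats::t.test feature by feature", {
  set.seed(31)
  v <- matrix(rnorm(10 * 9), 10, 9)
  m <- labelled_matrix(v)
  labels <- c(rep("a", 4), rep("b", 5))
  de <- differential_features(m, labels)
  for (f in c("g01", "g05", "g10")) {
    i <- match(f, m$feature_ids)
    ref <- t.test(v[i, 1:4], v[i, 5:9])
    expect_equal(de$t[de$feature_id == f], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(de$p[de$feature_id == f], ref$p.value, tolerance = 1e-12)
  }
  expect_error(differential_features(m, c(rep("a", 1), rep("b", 8))), ">= 2")
})

test_that("type-I error of the differential test is nominal on null data", {
  co <- simulate_cohort(null_config(seed = 12))
  de <- differential_features(co$mrna, co$true_labels)
  core <- de[grep("^G", de$feature_id), ]
  frac <- mean(core$p <= 0.05)
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
})

test_that("signatures take the smallest-p significant features per direction", {
  set.seed(7)
  n <- 40
  v <- matrix(rnorm(n * 10, 5), n, 10)
  v[1:10, 1:5] <- v[1:10, 1:5] + 3     # up in group a
  v[11:20, 6:10] <- v[11:20, 6:10] + 3 # down in group a
  m <- labelled_matrix(v)
  de <- differential_features(m, rep(c("a", "b"), each = 5))
  sg <- build_signature(de, n_per_direction = 5)
  expect_length(sg$up_features, 5)
  expect_length(sg$down_features, 5)
  expect_true(all(sg$up_features %in% sprintf("g%02d", 1:10)))
  expect_true(all(sg$down_features %in% sprintf("g%02d", 11:20)))
  # order preserved from the p-sorted table
  sig_up <- de$feature_id[de$significant & de$log2_fc > 0]
  expect_identical(sg$up_features, sig_up[1:5])
  # shortfall warns in each direction
  w <- capture_warnings(big <- build_signature(de, n_per_direction = 15))
  expect_true(all(grepl("significant", w)))
  expect_lte(length(big$up_features), 15)
  # invariant to relabeling of non-significant features
  de2 <- de
  idx <- which(!de2$significant)
  de2$feature_id[idx] <- paste0("x_", de2$feature_id[idx])
  sg2 <- build_signature(de2, n_per_direction = 5)
  expect_identical(sg2$up_features, sg$up_features)
  expect_identical(sg2$down_features, sg$down_features)
})

test_that("signatures on the default synthetic cohort are pure for planted features", {
  co <- simulate_cohort(cohort_config(seed = 9))
  de <- differential_features(co$mrna, co$true_labels)
  sg <- build_signature(de, n_per_direction = 50)
  feats <- c(sg$up_features, sg$down_features)
  # truth includes the immune marker genes whose mixing fractions differ
  purity <- mean(feats %in% co$true_informative_features$mrna)
  expect_gte(purity, 0.9)
})

test_that("group extension reproduces labels for duplicated and separable samples", {
  set.seed(13)
  # core: two clear groups with opposite marker blocks (15 up in A, 15 up in B)
  nf <- 30
  mean_a <- c(rep(3, 15), rep(0, 15))
  mean_b <- c(rep(0, 15), rep(3, 15))
  core_v <- cbind(matrix(rnorm(nf * 4, mean_a), nf, 4),
                  matrix(rnorm(nf * 4, mean_b), nf, 4))
  ext_v <- core_v[, c(1, 2, 5, 6)]  # exact copies of core samples
  v <- cbind(core_v, ext_v)
  colnames(v) <- sprintf("s%02d", 1:12)
  rownames(v) <- sprintf("g%02d", 1:nf)
  m <- omic_matrix(v, "mrna")
  sig <- structure(list(up_features = sprintf("g%02d", 1:15),
                        down_features = sprintf("g%02d", 16:30),
                        n_per_direction = 15, provenance = list()),
                   class = "feature_signature")
  core_labels <- setNames(rep(c("A", "B"), each = 4), sprintf("s%02d", 1:8))
  ext <- extend_groups_hcl(m, sig, core_labels)
  expect_identical(unname(ext[sprintf("s%02d", 9:10)]), c("A", "A"))
  expect_identical(unname(ext[sprintf("s%02d", 11:12)]), c("B", "B"))
  expect_identical(unname(ext[names(core_labels)]), unname(core_labels))
  # determinism
  expect_identical(ext, extend_groups_hcl(m, sig, core_labels))
})

test_that("extension scales to a 28-core / 20-extension synthetic cohort", {
  co <- simulate_cohort(cohort_config(seed = 6, n_samples = 48))
  core_ids <- names(co$true_labels)[c(1:14, 25:38)]
  core_m <- omic_matrix(co$mrna$values[, core_ids], "mrna")
  de <- differential_features(core_m, co$true_labels[core_ids])
  sg <- build_signature(de, 50)
  ext <- extend_groups_hcl(co$mrna, sg, co$true_labels[core_ids])
  expect_equal(ari(ext, co$true_labels), 1)
})
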