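test_that("affinity matrices satisfy their normalization contracts", {
  b <- blob_matrix(n_per = 3)
  a <- build_affinity(b$matrix, snf_params(K = 2))
  n <- length(a$sample_ids)
  expect_lt(max(abs(a$W - t(a$W))), 1e-9)
  expect_true(all(a$W >= 0))
  expect_true(all(diag(a$W) == apply(a$W, 1, max)))
  expect_equal(unname(rowSums(a$P)), rep(1, n), tolerance = 1e-9)
  expect_identical(unname(diag(a$P)), rep(0.5, n))
  expect_equal(unname(rowSums(a$S)), rep(1, n), tolerance = 1e-9)
  # within-blob affinities dominate between-blob ones
  g <- b$labels
  same <- outer(g, g, `==`) & upper.tri(a$W)
  diffr <- outer(g, g, `!=`) & upper.tri(a$W)
  expect_gt(mean(a$W[same]), mean(a$W[diffr]))
})

test_that("identical samples get affinity 1 and K bounds are enforced", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 9, 9), s4 = c(5, 1, 7))
  rownames(v) <- paste0("f", 1:3)
  a <- build_affinity(omic_matrix(v, "mrna"), snf_params(K = 2))
  expect_equal(a$W["s1", "s2"], 1)
  expect_error(build_affinity(omic_matrix(v, "mrna"), snf_params(K = 4)),
               "smaller")
  na_m <- omic_matrix(rbind(v, f4 = c(NA, 1, 2, 3)), "mrna")
  expect_error(build_affinity(na_m, snf_params(K = 2)), "missing")
})

test_that("fusion limits behave as specified", {
  co <- simulate_cohort(cohort_config(seed = 3, n_genes = 200,
                                      n_matched_pairs = 200, n_methylation = 30))
  a1 <- build_affinity(co$mrna)
  a2 <- build_affinity(co$protein)
  # T = 0: fused is the average of the input P matrices (symmetrized)
  f0 <- fuse_networks(list(a1, a2), snf_params(T = 0))
  ref <- (a1$P + t(a1$P) + a2$P + t(a2$P)) / 4
  expect_lt(max(abs(f0$fused - ref)), 1e-12)
  # single layer: that layer's own P
  f1 <- fuse_networks(list(a1))
  expect_lt(max(abs(f1$fused - (a1$P + t(a1$P)) / 2)), 1e-12)
  # self-fusion preserves the ordering of off-diagonal similarities
  fs <- fuse_networks(list(a1, a1))
  od <- upper.tri(fs$fused)
  sym_p <- (a1$P + t(a1$P)) / 2
  expect_equal(cor(fs$fused[od], sym_p[od], method = "spearman"), 1)
  # mismatched samples rejected
  a3 <- build_affinity(omic_matrix(co$mrna$values[, 1:10], "mrna"),
                       snf_params(K = 3))
  expect_error(fuse_networks(list(a1, a3)), "mismatched")
})

test_that("fused output is symmetric, non-negative and permutation-equivariant", {
  co <- simulate_cohort(cohort_config(seed = 5, n_samples = 12, n_genes = 150,
                                      n_matched_pairs = 150, n_methylation = 30))
  a1 <- build_affinity(co$mrna, snf_params(K = 4))
  a2 <- build_affinity(co$protein, snf_params(K = 4))
  f <- fuse_networks(list(a1, a2), snf_params(K = 4))
  expect_lt(max(abs(f$fused - t(f$fused))), 1e-9)
  expect_true(all(f$fused >= 0))

  perm <- c(5, 3, 11, 1, 12, 7, 2, 9, 4, 10, 6, 8)
  pm <- function(m) omic_matrix(m$values[, perm], m$layer_name, is_log = m$is_log)
  fp <- fuse_networks(list(build_affinity(pm(co$mrna), snf_params(K = 4)),
                           build_affinity(pm(co$protein), snf_params(K = 4))),
                      snf_params(K = 4))
  expect_lt(max(abs(fp$fused - f$fused[perm, perm])), 1e-9)
})

test_that("spectral clustering recovers exact blocks and handles degenerate k", {
  W <- block_similarity(c(4, 4), within = 1, between = 0.01)
  lab <- spectral_cluster(W, 2, seed = 42)
  expect_identical(unname(lab), rep(1:2, each = 4))
  # k = n: every sample its own cluster
  expect_identical(unname(spectral_cluster(W, 8, seed = 1)), 1:8)
  # disconnected graph with more components than k
  W3 <- block_similarity(c(3, 3, 2), within = 1, between = 0)
  expect_warning(lab3 <- spectral_cluster(W3, 2, seed = 1), "components")
  expect_identical(unname(lab3), c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
})

test_that("spectral clustering agrees with exhaustive normalized-cut search", {
  set.seed(17)
  agree <- 0
  for (r in 1:100) {
    g <- rep(1:2, each = 4)
    same <- outer(g, g, `==`)
    W <- matrix(runif(64, 0, 0.15), 8, 8)
    W[same] <- W[same] + runif(sum(same), 0.5, 1)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    dimnames(W) <- list(paste0("s", 1:8), paste0("s", 1:8))
    sp <- canonical12(spectral_cluster(W, 2, seed = 1))
    agree <- agree + identical(sp, ncut_exhaustive(W))
  }
  expect_gte(agree, 99)
})

test_that("eigengap selection finds exact block counts and breaks ties low", {
  W3 <- block_similarity(c(3, 4, 3), within = 1, between = 0.02)
  expect_identical(estimate_num_clusters(W3, k_max = 6)$best_k, 3L)
  # identity similarity: no structure, ties broken toward smallest k
  expect_identical(estimate_num_clusters(diag(10), k_max = 5)$best_k, 2L)
  expect_error(estimate_num_clusters(diag(4), k_max = 5), "k_max")
})

test_that("network export covers all samples with the strongest edges", {
  W <- matrix(c(1, .9, .1,
                .9, 1, .2,
                .1, .2, 1), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  e <- export_network(W)
  expect_gte(nrow(e), 2)
  expect_setequal(unique(c(e$source, e$target)), paste0("s", 1:3))

  # star similarity: exactly n - 1 edges
  n <- 6
  S <- matrix(0.05, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  S[1, ] <- S[, 1] <- 0.9
  diag(S) <- 1
  es <- export_network(S)
  expect_identical(nrow(es), 5L)
  expect_true(all(es$source == "s1" | es$target == "s1"))

  # round trip: weights re-read match the matrix exactly
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(W, path)
  back <- read.delim(path)
  expect_equal(back$weight, W[cbind(back$source, back$target)],
               tolerance = 0, ignore_attr = TRUE)
})

test_that("fusing weakly informative layers improves clustering over single layers", {
  wins <- 0
  for (s in 1:6) {
    co <- simulate_cohort(weak_config(s))
    al <- suppressMessages(align_cohort(list(m = co$mrna, p = co$protein)))
    aff <- lapply(al$matrices, build_affinity)
    sym <- function(P) (P + t(P)) / 2
    a_m <- ari(spectral_cluster(sym(aff$m$P), 2, seed = 1), co$true_labels)
    a_p <- ari(spectral_cluster(sym(aff$p$P), 2, seed = 1), co$true_labels)
    a_f <- ari(spectral_cluster(fuse_networks(aff)$fused, 2, seed = 1),
               co$true_labels)
    wins <- wins + (a_f > max(a_m, a_p))
  }
  expect_gte(wins, 4)
})
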