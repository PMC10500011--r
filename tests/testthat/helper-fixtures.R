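# Shared fixtures built in code.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small omic matrix with deterministic values.
tiny_matrix <- function(nf = 6, ns = 4, layer = "mrna", seed = 1) {
  set.seed(seed)
  omic_matrix(matrix(rnorm(nf * ns, 5), nf, ns,
                     dimnames = list(sprintf("g%02d", seq_len(nf)),
                                     sprintf("s%02d", seq_len(ns)))),
              layer_name = layer)
}

# Two well-separated sample blobs in feature space; returns omic_matrix and
# block labels.
blob_matrix <- function(n_per = 3, nf = 30, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, nf), rep(sep / sqrt(nf), nf) * sqrt(nf))
  v <- sapply(seq_len(2 * n_per), function(i) {
    g <- if (i <= n_per) 1 else 2
    rnorm(nf, mean = if (g == 1) 0 else sep / sqrt(nf), sd = 0.3)
  })
  dimnames(v) <- list(sprintf("f%02d", seq_len(nf)), sprintf("s%02d", seq_len(2 * n_per)))
  list(matrix = omic_matrix(v, "mrna"),
       labels = rep(1:2, each = n_per))
}

# Block-diagonal similarity matrix with given block sizes.
block_similarity <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  W <- matrix(between, n, n)
  at <- cumsum(c(0, sizes))
  for (b in seq_along(sizes)) {
    idx <- (at[b] + 1):at[b + 1]
    W[idx, idx] <- within
  }
  dimnames(W) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  W
}

# The weak-separation study regime: layers individually separate the planted
# groups only poorly, no ratio shift, no cell-type contrast.
weak_config <- function(seed) {
  eq <- rbind(g1 = c(tumor = .7, tcell = .1, microglia = .1, macrophage = .1),
              g2 = c(tumor = .7, tcell = .1, microglia = .1, macrophage = .1))
  cohort_config(seed = seed, frac_de = 0.05, effect_size = 0.75,
                ratio_shift_delta = 0, coupling_rho = 0,
                celltype_fractions = eq)
}

# Null configuration: no planted group signal anywhere.
null_config <- function(seed, n_genes = 2000) {
  eq <- rbind(g1 = c(tumor = .7, tcell = .1, microglia = .1, macrophage = .1),
              g2 = c(tumor = .7, tcell = .1, microglia = .1, macrophage = .1))
  cohort_config(seed = seed, n_genes = n_genes, n_matched_pairs = min(n_genes, 2000),
                frac_de = 0, effect_size = 0, ratio_shift_delta = 0,
                coupling_rho = 0, celltype_fractions = eq,
                pfs_hazards = c(0.02, 0.02), age_means = c(9, 9),
                age_sds = c(3, 3), location_probs = c(0.5, 0.5))
}

# Exhaustive minimum-normalized-cut 2-partition of a similarity matrix
# (independent oracle for spectral clustering; n <= 12).
ncut_exhaustive <- function(W) {
  n <- nrow(W)
  best <- Inf
  best_set <- NULL
  for (m in 1:(2^(n - 1) - 1)) {
    A <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    B <- setdiff(seq_len(n), A)
    cutw <- sum(W[A, B])
    val <- cutw / sum(W[A, ]) + cutw / sum(W[B, ])
    if (val < best) { best <- val; best_set <- A }
  }
  lab <- rep(2L, n)
  lab[best_set] <- 1L
  if (lab[1] == 2L) lab <- 3L - lab
  lab
}

canonical12 <- function(lab) {
  lab <- as.integer(factor(lab, levels = unique(lab)))
  lab
}
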