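#' Cross-cohort subclass association (submap)
#'
#' Tests whether groups defined in cohort A correspond to groups in cohort B
#' by mutual marker enrichment. For each group g of A, its top up-regulated
#' markers (smallest p with positive g-vs-rest t, up to `n_markers`) are
#' scored against cohort B's feature ranking by the h-vs-rest t statistic
#' using the weighted Kolmogorov-Smirnov enrichment score; significance comes
#' from shuffling B's sample labels (seeded, `n_permutations` rounds, add-one
#' rule). The procedure is run in both directions (A markers in B rankings
#' and B markers in A rankings), the two one-sided p values are combined by
#' Fisher's method, and the subclass-association matrix is FDR-adjusted by
#' Benjamini-Hochberg over all group pairs.
#'
#' @param matrix_a,matrix_b [omic_matrix()] cohorts (feature spaces are
#'   intersected; >= 50 shared features required).
#' @param labels_a,labels_b Group labels per cohort (2 groups each).
#' @param n_markers Marker cap per group (default 200).
#' @param n_permutations Label permutations per direction (default 1000).
#' @param seed Random seed.
#' @param weight Enrichment-score weight exponent (default 1).
#' @return A `submap_result`: `sa_matrix` (FDR-adjusted p, A groups x B
#'   groups), `fisher_p`, `p_ab`, `p_ba` (raw directional permutation p),
#'   `n_markers`, `n_permutations`, `n_shared_features`, and `provenance`
#'   (notes the Fisher combination rule).
#' @export
submap <- function(matrix_a, labels_a, matrix_b, labels_b,
                   n_markers = 200, n_permutations = 1000, seed = 1,
                   weight = 1) {
  stopifnot(inherits(matrix_a, "omic_matrix"), inherits(matrix_b, "omic_matrix"))
  shared <- intersect(matrix_a$feature_ids, matrix_b$feature_ids)
  if (length(shared) < 50)
    stop("fewer than 50 shared features between the cohorts")
  A <- matrix_a$values[shared, , drop = FALSE]
  B <- matrix_b$values[shared, , drop = FALSE]
  ga <- two_groups(labels_a, ncol(A))
  gb <- two_groups(labels_b, ncol(B))
  seeds <- child_seeds(seed, 2)
  p_ab <- .submap_direction(A, ga, B, gb, n_markers, n_permutations, seeds[1],
                            weight)
  p_ba <- t(.submap_direction(B, gb, A, ga, n_markers, n_permutations, seeds[2],
                              weight))
  chi <- -2 * (log(p_ab) + log(p_ba))
  fisher_p <- stats::pchisq(chi, df = 4, lower.tail = FALSE)
  sa <- matrix(stats::p.adjust(fisher_p, method = "BH"), 2, 2,
               dimnames = dimnames(fisher_p))
  structure(list(sa_matrix = sa, fisher_p = fisher_p, p_ab = p_ab, p_ba = p_ba,
                 n_markers = n_markers, n_permutations = n_permutations,
                 n_shared_features = length(shared),
                 provenance = "directional permutation p combined by Fisher chi-square (4 df), BH-FDR over the SA matrix"),
            class = "submap_result")
}

# One direction: markers from cohort X (groups gx) scored in cohort Y's
# h-vs-rest rankings, null by permuting Y's labels. Returns 2x2 matrix of
# permutation p values (rows = X groups, cols = Y groups).
.submap_direction <- function(X, gx, Y, gy, n_markers, n_perm, seed, weight) {
  markers <- lapply(list(gx$idx1, gx$idx2), function(idx) {
    tt <- row_welch_t(X, idx, setdiff(seq_len(ncol(X)), idx))
    up <- which(tt$t > 0)
    up[order(tt$p[up])][seq_len(min(n_markers, length(up)))]
  })
  score_against <- function(t_y) {
    # rankings for h1 (descending t) and h2 (ascending t = descending -t)
    vapply(1:2, function(h) {
      s <- if (h == 1) t_y else -t_y
      ord <- order(-s, seq_along(s))
      pos_of <- integer(length(s)); pos_of[ord] <- seq_along(s)
      vapply(markers, function(mk)
        gsea_running_score(s[ord], pos_of[mk], weight)$es, numeric(1))
    }, numeric(2))  # rows = X groups, cols = Y groups
  }
  t_obs <- row_welch_t(Y, gy$idx1, gy$idx2)$t
  obs <- score_against(t_obs)
  set.seed(seed)
  exceed <- matrix(0, 2, 2)
  n1 <- length(gy$idx1)
  for (b in seq_len(n_perm)) {
    idx1 <- sample.int(ncol(Y), n1)
    t_null <- row_welch_t(Y, idx1, setdiff(seq_len(ncol(Y)), idx1))$t
    exceed <- exceed + (score_against(t_null) >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  dimnames(p) <- list(paste0("A_", gx$levels), paste0("B_", gy$levels))
  p
}

#' @export
print.submap_result <- function(x, ...) {
  cat(sprintf("submap_result: %d shared features, %d markers/group, %d permutations\n",
              x$n_shared_features, x$n_markers, x$n_permutations))
  cat("FDR-adjusted subclass association matrix:\n")
  print(round(x$sa_matrix, 4))
  invisible(x)
}
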