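#' Similarity network fusion parameters
#'
#' @param K Number of nearest sample neighbors (default 10).
#' @param mu Kernel width hyperparameter alpha (default 0.5); values outside
#'   the recommended 0.3-0.8 band trigger a warning.
#' @param T Number of cross-diffusion iterations (default 10).
#' @return An `snf_params` list.
#' @export
snf_params <- function(K = 10, mu = 0.5, T = 10) {
  if (K < 1) stop("K must be >= 1")
  if (T < 0) stop("T must be >= 0")
  if (mu <= 0) stop("mu must be positive")
  if (mu < 0.3 || mu > 0.8)
    warning("mu outside the recommended [0.3, 0.8] range")
  structure(list(K = as.integer(K), mu = mu, T = as.integer(T)),
            class = "snf_params")
}

#' Per-layer patient affinity graph
#'
#' Computes pairwise Euclidean distances between samples over z-scored
#' features, then a locally scaled Gaussian kernel
#' \deqn{W_{ij} = \exp(-d_{ij}^2 / (\mu\,\varepsilon_{ij})), \quad
#'   \varepsilon_{ij} = (\bar d_K(i) + \bar d_K(j) + d_{ij})/3,}
#' where \eqn{\bar d_K(i)} is the mean distance of sample i to its K nearest
#' neighbors. Two normalizations are derived: the full transition matrix `P`
#' with diagonal fixed at 1/2 and off-diagonal rows summing to 1/2, and the
#' sparse kernel `S` supported on each row's neighborhood (the sample itself
#' plus its K nearest others, distance ties broken by sample order), rows
#' summing to 1.
#'
#' @param matrix [omic_matrix()] without missing values, >= 3 samples.
#' @param params [snf_params()].
#' @return An `affinity_matrix`: list with `sample_ids`, `W`, `P`, `S`.
#' @export
build_affinity <- function(matrix, params = snf_params()) {
  stopifnot(inherits(matrix, "omic_matrix"))
  v <- matrix$values
  if (anyNA(v)) stop("missing values not allowed in affinity construction")
  n <- ncol(v)
  if (n < 3) stop("need >= 3 samples")
  if (params$K >= n) stop("K must be smaller than the number of samples")
  z <- zscore_rows(v)
  d <- as.matrix(stats::dist(t(z)))
  # mean distance to the K nearest other samples (ties by sample order)
  mean_knn <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    mean(di[order(di, seq_along(di))[seq_len(params$K)]])
  }, numeric(1))
  eps <- (outer(mean_knn, mean_knn, `+`) + d) / 3
  W <- exp(-d^2 / (params$mu * eps))
  dimnames(W) <- dimnames(d)
  structure(list(sample_ids = colnames(v), W = W,
                 P = .full_normalize(W),
                 S = .knn_normalize(W, d, params$K)),
            class = "affinity_matrix")
}

# Full transition normalization: diagonal 1/2, off-diagonal rows sum to 1/2.
.full_normalize <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  rs[rs == 0] <- 1
  P <- off / (2 * rs)
  diag(P) <- 0.5
  P
}

# Row-stochastic kernel on the K-nearest neighborhood (self + K nearest
# others; ties in distance broken by sample order).
.knn_normalize <- function(W, d, K) {
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(d[i, others], others)[seq_len(K)]]
    nb <- c(i, nb)
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Fuse per-layer affinity graphs by cross-network diffusion
#'
#' Iteratively diffuses each layer's full transition matrix through its
#' K-nearest-neighbor kernel while averaging over the complementary layers:
#' at every round the status matrix of layer v is updated to
#' \eqn{S^{(v)} \bar P^{(-v)} S^{(v)\top}} (with \eqn{\bar P^{(-v)}} the mean
#' of the other layers' status matrices), then re-normalized to the `P`
#' convention. After `T` rounds the fused network is the average of the layer
#' status matrices, symmetrized. With a single layer the fused network is
#' that layer's own (symmetrized) `P`, so single-omic and multi-omic
#' clustering share one interface; with `T = 0` it is the average of the
#' input `P` matrices.
#'
#' @param affinities List of `affinity_matrix` objects on identical samples.
#' @param params [snf_params()].
#' @return An `snf_fusion` object: `fused` similarity matrix, `per_layer`
#'   input affinities, `trace` (per-round mean absolute update), `params`.
#'   Cluster labels can be attached with [spectral_cluster()].
#' @seealso [spectral_cluster()], [estimate_num_clusters()], [export_network()]
#' @export
fuse_networks <- function(affinities, params = snf_params()) {
  stopifnot(length(affinities) >= 1,
            all(vapply(affinities, inherits, logical(1), "affinity_matrix")))
  ids <- affinities[[1]]$sample_ids
  for (a in affinities)
    if (!identical(a$sample_ids, ids)) stop("affinity matrices on mismatched sample sets")
  m <- length(affinities)
  Ps <- lapply(affinities, `[[`, "P")
  trace <- numeric(0)
  if (m >= 2 && params$T >= 1) {
    Ss <- lapply(affinities, `[[`, "S")
    for (t in seq_len(params$T)) {
      upd <- vector("list", m)
      for (v in seq_len(m)) {
        others <- Reduce(`+`, Ps[-v]) / (m - 1)
        upd[[v]] <- .full_normalize(Ss[[v]] %*% others %*% t(Ss[[v]]))
      }
      trace <- c(trace, mean(abs(mapply(function(a, b) a - b, upd, Ps))))
      Ps <- upd
    }
  }
  fused <- Reduce(`+`, Ps) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  structure(list(fused = fused, per_layer = affinities, trace = trace,
                 params = params, sample_ids = ids, labels = NULL),
            class = "snf_fusion")
}

#' @export
print.snf_fusion <- function(x, ...) {
  cat(sprintf("snf_fusion: %d samples, %d layer(s), K=%d mu=%.2f T=%d\n",
              length(x$sample_ids), length(x$per_layer),
              x$params$K, x$params$mu, x$params$T))
  if (!is.null(x$labels))
    cat("  cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' @export
summary.snf_fusion <- function(object, k_max = 6, ...) {
  eg <- estimate_num_clusters(object$fused, k_max = k_max)
  cat(sprintf("Fused similarity network over %d samples (%d layers)\n",
              length(object$sample_ids), length(object$per_layer)))
  cat(sprintf("Eigengap-selected number of clusters: %d\n", eg$best_k))
  cat("Eigengaps:", paste(sprintf("k=%d: %.4f", seq_along(eg$eigengaps) + 1,
                                  eg$eigengaps), collapse = ", "), "\n")
  if (length(object$trace))
    cat(sprintf("Final diffusion update norm: %.3e\n", utils::tail(object$trace, 1)))
  invisible(eg)
}

#' @export
plot.snf_fusion <- function(x, order_by_labels = TRUE, ...) {
  M <- x$fused
  if (order_by_labels && !is.null(x$labels)) {
    o <- order(x$labels)
    M <- M[o, o]
  }
  graphics::image(t(M)[, nrow(M):1], axes = FALSE,
                  main = "Fused patient similarity", ...)
  invisible(x)
}

#' Spectral clustering of a similarity network
#'
#' Normalized spectral clustering: eigenvectors of the k smallest eigenvalues
#' of the symmetric normalized Laplacian \eqn{L = I - D^{-1/2} W D^{-1/2}},
#' rows unit-normalized, partitioned by k-means with multiple restarts under
#' a fixed seed. Labels are returned in canonical order (group ids numbered
#' by first occurrence along the sample order).
#'
#' @param fused Symmetric non-negative similarity matrix.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param seed Random seed for k-means restarts.
#' @param nstart k-means restarts (default 50).
#' @return Integer vector of cluster labels (named when input has dimnames).
#' @export
spectral_cluster <- function(fused, k, seed = 1, nstart = 50) {
  W <- as.matrix(fused)
  n <- nrow(W)
  if (max(abs(W - t(W))) > 1e-8) stop("similarity matrix must be symmetric")
  W <- (W + t(W)) / 2
  if (any(W < 0)) stop("similarity matrix must be non-negative")
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  lab <- if (k == n) seq_len(n) else .spectral_labels(W, k, seed, nstart)
  comp <- .graph_components(W)
  if (max(comp) > k && k < n) {
    warning(sprintf("graph has %d components but k = %d; assigning components deterministically",
                    max(comp), k))
    lab <- pmin(comp, k)
  }
  lab <- .canonical_labels(lab)
  names(lab) <- rownames(W)
  lab
}

.spectral_labels <- function(W, k, seed, nstart) {
  n <- nrow(W)
  dg <- rowSums(W)
  dg[dg == 0] <- 1e-12
  Dn <- 1 / sqrt(dg)
  L <- diag(n) - (Dn * W) * rep(Dn, each = n)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, n:(n - k + 1), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  set.seed(seed)
  stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)$cluster
}

# Connected components of the positive-weight graph, numbered by smallest
# member index.
.graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

.canonical_labels <- function(lab) {
  map <- stats::setNames(seq_along(unique(lab)), unique(lab))
  unname(map[as.character(lab)])
}

#' Choose the number of clusters by the Laplacian eigengap
#'
#' Computes the eigenvalues of the symmetric normalized Laplacian of the
#' fused network and returns the k in `[2, k_max]` maximizing the gap
#' \eqn{\lambda_{k+1} - \lambda_k}. Ties (including the fully degenerate
#' case of no structure) are broken toward the smallest k.
#'
#' @param fused Symmetric non-negative similarity matrix.
#' @param k_max Largest candidate k (default 6; must be < n).
#' @return List with `best_k` and the named vector `eigengaps`.
#' @export
estimate_num_clusters <- function(fused, k_max = 6) {
  W <- as.matrix(fused)
  n <- nrow(W)
  if (k_max >= n) stop("k_max must be < number of samples")
  W <- (W + t(W)) / 2
  dg <- rowSums(W)
  dg[dg == 0] <- 1e-12
  Dn <- 1 / sqrt(dg)
  L <- diag(n) - (Dn * W) * rep(Dn, each = n)
  lambda <- sort(eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  ks <- 2:k_max
  gaps <- lambda[ks + 1] - lambda[ks]
  names(gaps) <- paste0("k", ks)
  best <- ks[which.max(gaps)]  # which.max takes the first maximum: ties -> smallest k
  list(best_k = best, eigengaps = gaps)
}

#' Export a fused network as a minimal covering edge list
#'
#' Edges (upper triangle) are sorted by descending similarity and retained
#' greedily, in that order, until every sample has degree >= 1 — the smallest
#' prefix of the strongest relations that contains all samples. Written as a
#' 3-column tab-separated edge list (source, target, weight) consumable by
#' graph-visualization tools.
#'
#' @param fused Symmetric similarity matrix with sample dimnames.
#' @param path Optional output file; when `NULL` nothing is written.
#' @return Data frame of retained edges (source, target, weight), invisibly
#'   when writing.
#' @export
export_network <- function(fused, path = NULL) {
  W <- as.matrix(fused)
  if (max(abs(W - t(W))) > 1e-8) stop("similarity matrix must be symmetric")
  n <- nrow(W)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  ord <- order(-W[ut], ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  covered <- logical(n)
  keep <- integer(0)
  for (e in seq_len(nrow(ut))) {
    keep <- c(keep, e)
    covered[ut[e, ]] <- TRUE
    if (all(covered)) break
  }
  edges <- data.frame(source = ids[ut[keep, 1]], target = ids[ut[keep, 2]],
                      weight = W[ut[keep, , drop = FALSE]],
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    writeLines(c("source\ttarget\tweight",
                 sprintf("%s\t%s\t%.17g", edges$source, edges$target, edges$weight)),
               con)
    close(con)
    return(invisible(edges))
  }
  edges
}
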