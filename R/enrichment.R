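#' Rank features by a statistic for preranked enrichment
#'
#' Descending order (group-1-high features first when the statistic is a
#' group-1-minus-group-2 t value); ties broken by feature id so the ranking
#' is strictly ordered and deterministic.
#'
#' @param statistics Named numeric vector (e.g. the `t` column of a
#'   [differential_features()] table named by `feature_id`).
#' @return Named numeric vector sorted for enrichment analysis.
#' @export
rank_features <- function(statistics) {
  if (is.null(names(statistics))) stop("statistics must be named by feature id")
  statistics[order(-statistics, names(statistics))]
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' The primitive behind [preranked_gsea()], [ssgsea_score()] and [submap()]:
#' hit increments proportional to `|stat|^weight`, uniform miss decrements,
#' ES = the running sum's maximum deviation from zero. When the positive and
#' negative extremes coincide to within 1e-12 the tie is resolved toward the
#' positive extreme (documented tie-break; `weight = 0` gives the classic
#' unweighted KS statistic).
#'
#' @param stats_sorted Statistic values in ranking order (descending).
#' @param hit_pos Integer positions of the set members in that ranking.
#' @param weight Hit-weight exponent.
#' @return List with `es`, the full `running` sum, and `arg` (position of
#'   the extremum).
#' @export
gsea_running_score <- function(stats_sorted, hit_pos, weight = 1) {
  n <- length(stats_sorted)
  nh <- length(hit_pos)
  hit <- logical(n)
  hit[hit_pos] <- TRUE
  w <- abs(stats_sorted)^weight
  w[!hit] <- 0
  denom <- sum(w)
  p_hit <- if (denom > 0) cumsum(w) / denom else cumsum(hit) / nh
  p_miss <- cumsum(!hit) / (n - nh)
  running <- p_hit - p_miss
  mx <- max(running)
  mn <- min(running)
  arg <- if (mx >= -mn - 1e-12) which.max(running) else which.min(running)
  list(es = running[arg], running = running, arg = arg)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment on a ranked statistic list: hit
#' increments proportional to `|stat|^weight`, uniform miss decrements; the
#' enrichment score (ES) is the maximum deviation of the running sum. The
#' null distribution is obtained by gene-label permutation (random member
#' sets of the same size), the nominal p uses the add-one rule among nulls of
#' matching sign, NES divides ES by the mean |null ES| of matching sign, and
#' q is Benjamini-Hochberg within each sign.
#'
#' @param ranked A [rank_features()] vector.
#' @param sets A `gene_set_collection`.
#' @param weight Hit-weight exponent (default 1).
#' @param n_permutations Gene-label permutations (default 1000).
#' @param seed Random seed for the permutation null.
#' @param p_cut,q_cut Report-filter cutoffs; `filter = FALSE` returns all
#'   tested sets.
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranked features (defaults 10 and 500); undersized/oversized sets are
#'   skipped with a message.
#' @param filter Apply the p/q cutoffs to the returned table.
#' @return An `enrichment_result` data.frame: `set_name`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (comma-separated members).
#' @export
preranked_gsea <- function(ranked, sets, weight = 1, n_permutations = 1000,
                           seed = 1, p_cut = 0.0005, q_cut = 0.03,
                           min_size = 10, max_size = 500, filter = TRUE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  feats <- names(ranked)
  n <- length(feats)
  members <- lapply(sets$sets, function(s) which(feats %in% s))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message(sprintf("preranked_gsea: skipping %d set(s) outside size [%d, %d]",
                    sum(!keep), min_size, max_size))
  members <- members[keep]
  if (!length(members))
    return(structure(data.frame(set_name = character(), size = integer(),
                                es = numeric(), nes = numeric(), p = numeric(),
                                q = numeric(), leading_edge = character()),
                     class = c("enrichment_result", "data.frame")))
  set.seed(seed)
  res <- lapply(names(members), function(nm) {
    pos <- members[[nm]]
    obs <- gsea_running_score(ranked, pos, weight)
    null_es <- vapply(seq_len(n_permutations), function(i)
      gsea_running_score(ranked, sample.int(n, length(pos)), weight)$es,
      numeric(1))
    same <- null_es * sign(obs$es) > 0
    p <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + sum(same))
    nes <- if (any(same)) obs$es / mean(abs(null_es[same])) else NA_real_
    le <- if (obs$es >= 0) pos[pos <= obs$arg] else pos[pos >= obs$arg]
    data.frame(set_name = nm, size = length(pos), es = obs$es, nes = nes,
               p = p, leading_edge = paste(feats[le], collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- NA_real_
  for (sgn in c(TRUE, FALSE)) {
    idx <- (tab$es >= 0) == sgn
    if (any(idx)) tab$q[idx] <- stats::p.adjust(tab$p[idx], method = "BH")
  }
  tab <- tab[order(tab$p, tab$set_name),
             c("set_name", "size", "es", "nes", "p", "q", "leading_edge")]
  if (filter) tab <- tab[tab$p <= p_cut & tab$q <= q_cut, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_result", "data.frame")
  tab
}

#' Enrichment-map edges between retained gene sets
#'
#' Connects pairs of sets whose overlap coefficient
#' `|A intersect B| / min(|A|, |B|)` reaches the similarity cutoff — i.e.
#' sets sharing at least half of the terms defining the smaller one at the
#' default 0.5.
#'
#' @param results An `enrichment_result` (or data.frame with `set_name`).
#' @param sets The `gene_set_collection` the results refer to.
#' @param similarity_cutoff Minimum overlap coefficient (default 0.5).
#' @return Data frame of edges: `source`, `target`, `weight` (the overlap
#'   coefficient), in the same 3-column layout as [export_network()].
#' @export
enrichment_map_edges <- function(results, sets, similarity_cutoff = 0.5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  nms <- results$set_name
  if (!all(nms %in% names(sets$sets)))
    stop("results reference sets absent from the collection")
  out <- list()
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      a <- sets$sets[[nms[i]]]; b <- sets$sets[[nms[j]]]
      ov <- length(intersect(a, b)) / min(length(a), length(b))
      if (ov >= similarity_cutoff)
        out[[length(out) + 1]] <- data.frame(source = nms[i], target = nms[j],
                                             weight = ov, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(source = character(), target = character(),
                      weight = numeric()))
  do.call(rbind, out)
}

#' Single-sample gene-set score (ssGSEA-like)
#'
#' For each sample, features are ranked by expression (descending, ties by
#' feature id) and the score integrates the difference between the weighted
#' cumulative distribution of in-set features (rank weights raised to `tau`)
#' and the uniform cumulative distribution of out-of-set features over all
#' ranks. Higher means more set activity; scores are comparable within one
#' run only.
#'
#' @param matrix [omic_matrix()] without missing values.
#' @param set Character vector of feature ids (>= 5 must be present).
#' @param tau Rank-weight exponent (default 0.25).
#' @return Named numeric score per sample.
#' @export
ssgsea_score <- function(matrix, set, tau = 0.25) {
  stopifnot(inherits(matrix, "omic_matrix"))
  feats <- matrix$feature_ids
  inset <- feats %in% set
  if (sum(inset) < 5) stop("fewer than 5 set members present in the matrix")
  n <- length(feats)
  nh <- sum(inset)
  apply_one <- function(v) {
    ord <- order(-v, feats)
    hit <- inset[ord]
    w <- (n:1)^tau
    w[!hit] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hit) / (n - nh)
    sum(p_in - p_out) / n
  }
  scores <- apply(matrix$values, 2, apply_one)
  stats::setNames(scores, matrix$sample_ids)
}
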