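#' Per-feature two-group differential expression
#'
#' Welch (unequal-variance) unpaired t-test per feature between two groups,
#' with fold changes computed on the linear scale from log2 group means
#' (`FC = 2^(mean1 - mean2)`). Features are flagged significant when
#' `p <= p_thresh` and `|FC| >= fc_thresh` (i.e. `FC >= fc_thresh` or
#' `FC <= 1/fc_thresh`). The table is sorted by ascending p value and carries
#' Benjamini-Hochberg adjusted q values.
#'
#' @param matrix [omic_matrix()] on log2 scale without missing values.
#' @param labels Group label per sample (exactly 2 levels; the level that
#'   appears first is "group 1" and positive fold changes mean higher there).
#' @param p_thresh,fc_thresh Significance thresholds (defaults 0.05 and 2).
#' @return A `differential_table` (data.frame subclass) with columns
#'   `feature_id`, `mean1`, `mean2`, `log2_fc`, `fold_change`, `t`, `p`, `q`,
#'   `significant`.
#' @export
differential_features <- function(matrix, labels, p_thresh = 0.05, fc_thresh = 2) {
  stopifnot(inherits(matrix, "omic_matrix"))
  if (!matrix$is_log) stop("differential_features expects log2-scale values")
  if (anyNA(matrix$values)) stop("missing values present")
  g <- two_groups(labels, n = length(matrix$sample_ids))
  if (length(g$idx1) < 2 || length(g$idx2) < 2)
    stop("each group needs >= 2 samples")
  tt <- row_welch_t(matrix$values, g$idx1, g$idx2)
  lfc <- tt$mean1 - tt$mean2
  tab <- data.frame(feature_id = matrix$feature_ids,
                    mean1 = tt$mean1, mean2 = tt$mean2,
                    log2_fc = lfc, fold_change = 2^lfc,
                    t = tt$t, p = tt$p,
                    q = stats::p.adjust(tt$p, method = "BH"),
                    stringsAsFactors = FALSE)
  tab$significant <- tab$p <= p_thresh &
    (tab$fold_change >= fc_thresh | tab$fold_change <= 1 / fc_thresh)
  tab <- tab[order(tab$p, tab$feature_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "groups") <- g$levels
  attr(tab, "thresholds") <- c(p = p_thresh, fc = fc_thresh)
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' Extract a top-N up/down feature signature
#'
#' Among significant features only, takes the `n_per_direction` smallest-p
#' up-regulated and smallest-p down-regulated features (order preserved from
#' the p-sorted table). Shorter lists are returned with a warning when fewer
#' features pass.
#'
#' @param table A [differential_features()] result (p-sorted).
#' @param n_per_direction Features to keep per direction. A published
#'   "100-feature signature" corresponds to `n_per_direction = 50`
#'   (50 up + 50 down).
#' @return A `feature_signature`: list with `up_features`, `down_features`,
#'   `n_per_direction`, `provenance`.
#' @export
build_signature <- function(table, n_per_direction = 50) {
  stopifnot(inherits(table, "differential_table"))
  sig <- table[table$significant, , drop = FALSE]
  up <- sig$feature_id[sig$log2_fc > 0]
  down <- sig$feature_id[sig$log2_fc < 0]
  if (length(up) < n_per_direction)
    warning(sprintf("only %d significant up-regulated feature(s) (requested %d)",
                    length(up), n_per_direction))
  if (length(down) < n_per_direction)
    warning(sprintf("only %d significant down-regulated feature(s) (requested %d)",
                    length(down), n_per_direction))
  structure(list(up_features = utils::head(up, n_per_direction),
                 down_features = utils::head(down, n_per_direction),
                 n_per_direction = n_per_direction,
                 provenance = list(groups = attr(table, "groups"),
                                   thresholds = attr(table, "thresholds"))),
            class = "feature_signature")
}

#' @export
print.feature_signature <- function(x, ...) {
  cat(sprintf("feature_signature: %d up + %d down (requested %d per direction)\n",
              length(x$up_features), length(x$down_features), x$n_per_direction))
  invisible(x)
}

#' Write a signature as a 2-column feature/direction table
#' @param x A `feature_signature`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(x, path) {
  utils::write.table(
    data.frame(feature_id = c(x$up_features, x$down_features),
               direction = rep(c("up", "down"),
                               c(length(x$up_features), length(x$down_features)))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extend core group labels to all samples by signature clustering
#'
#' Semi-supervised group extension: restrict the expression matrix to the
#' signature features, z-score each feature, compute sample-sample Pearson
#' dissimilarity (1 - r), agglomerate by average linkage, cut the tree into
#' two clusters, and name each cluster after the group holding the majority
#' of its core-labeled samples. Deterministic: the linkage has no random
#' component.
#'
#' @param matrix [omic_matrix()] covering core and extension samples.
#' @param signature A [build_signature()] result.
#' @param core_labels Named vector of group labels on a subset of samples
#'   (>= 2 samples per group).
#' @return Named group labels for every sample in `matrix`.
#' @export
extend_groups_hcl <- function(matrix, signature, core_labels) {
  stopifnot(inherits(matrix, "omic_matrix"), inherits(signature, "feature_signature"))
  feats <- intersect(c(signature$up_features, signature$down_features),
                     matrix$feature_ids)
  if (length(feats) < 2) stop("signature features not present in the matrix")
  core <- names(core_labels)
  if (is.null(core) || !all(core %in% matrix$sample_ids))
    stop("core_labels must be named with sample ids present in the matrix")
  lv <- unique(as.character(core_labels))
  if (length(lv) != 2 || any(table(factor(core_labels, lv)) < 2))
    stop("core_labels must cover 2 groups with >= 2 samples each")
  z <- zscore_rows(matrix$values[feats, , drop = FALSE])
  dis <- 1 - stats::cor(z)
  hc <- stats::hclust(stats::as.dist(dis), method = "average")
  cl <- stats::cutree(hc, k = 2)
  assign_group <- function(members) {
    cl_core <- core_labels[intersect(members, core)]
    if (!length(cl_core))
      stop("a cluster contains no core-labeled samples; add cores or shrink the signature")
    names(which.max(table(factor(cl_core, lv))))
  }
  ids <- matrix$sample_ids
  g_of_cl <- vapply(1:2, function(k) assign_group(ids[cl == k]), character(1))
  if (g_of_cl[1] == g_of_cl[2])
    stop("both clusters map to the same core group; groups are not separable")
  out <- stats::setNames(g_of_cl[cl], ids)
  out
}
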