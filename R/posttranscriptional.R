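#' Per-pair transcript-protein Pearson correlations
#'
#' Pearson correlation across samples for every matched pair, with a
#' two-sided p value from the t transform of r on n - 2 degrees of freedom,
#' and the cohort-level summary median of r. Zero-variance pairs yield an
#' undefined correlation, recorded as `NA` with a warning.
#'
#' @param pairs A [match_pairs()] table (>= 3 samples).
#' @return List with `table` (data.frame: `pair_id`, `r`, `p`) and
#'   `median_r`.
#' @export
pair_correlations <- function(pairs) {
  stopifnot(inherits(pairs, "matched_pair_table"))
  n <- length(pairs$sample_ids)
  if (n < 3) stop("need >= 3 samples")
  mv <- pairs$mrna_values
  pv <- pairs$protein_values
  mv_c <- mv - rowMeans(mv)
  pv_c <- pv - rowMeans(pv)
  sx <- sqrt(rowSums(mv_c^2))
  sy <- sqrt(rowSums(pv_c^2))
  bad <- sx == 0 | sy == 0
  if (any(bad)) warning(sum(bad), " zero-variance pair(s): correlation undefined")
  r <- rowSums(mv_c * pv_c) / (sx * sy)
  r[bad] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) == 1] <- 0
  list(table = data.frame(pair_id = pairs$pair_ids, r = r, p = p,
                          stringsAsFactors = FALSE),
       median_r = stats::median(r, na.rm = TRUE))
}

#' Group-wise protein/mRNA ratios
#'
#' Per pair and group, the log protein/mRNA ratio
#' `r_g = median(log protein) - median(log mRNA)` over the group's samples
#' (positive = protein-dominant). `ratio_mode = "literal-div"` instead
#' divides the two medians, which is numerically degenerate on centered data
#' but kept available. Per-sample median ratios (median over pairs of
#' `log protein - log mRNA` per sample) are also returned for dot plots.
#'
#' @param pairs A [match_pairs()] table.
#' @param labels Group label per sample (2 groups).
#' @param ratio_mode `"log-diff"` (default) or `"literal-div"`.
#' @return A `ratio_table`: list with `per_pair` (data.frame: `pair_id`,
#'   one ratio column per group), `per_sample` (data.frame: `sample_id`,
#'   `group`, `median_ratio`) and `groups`.
#' @export
group_ratio <- function(pairs, labels, ratio_mode = c("log-diff", "literal-div")) {
  stopifnot(inherits(pairs, "matched_pair_table"))
  ratio_mode <- match.arg(ratio_mode)
  g <- two_groups(labels, length(pairs$sample_ids))
  row_median <- function(m) apply(m, 1, stats::median)
  per_pair <- data.frame(pair_id = pairs$pair_ids, stringsAsFactors = FALSE)
  for (k in 1:2) {
    idx <- if (k == 1) g$idx1 else g$idx2
    mp <- row_median(pairs$protein_values[, idx, drop = FALSE])
    mm <- row_median(pairs$mrna_values[, idx, drop = FALSE])
    per_pair[[g$levels[k]]] <- if (ratio_mode == "log-diff") mp - mm else mp / mm
  }
  diff_sample <- pairs$protein_values - pairs$mrna_values
  per_sample <- data.frame(sample_id = pairs$sample_ids,
                           group = as.character(labels),
                           median_ratio = apply(diff_sample, 2, stats::median),
                           stringsAsFactors = FALSE)
  structure(list(per_pair = per_pair, per_sample = per_sample,
                 groups = g$levels, ratio_mode = ratio_mode),
            class = "ratio_table")
}

#' Mann-Whitney rank-sum test
#'
#' U statistic from midrank sums. The two-sided p value is exact — computed
#' by full enumeration of the rank assignments, which remains valid under
#' ties — whenever `min(n1, n2) <= 8`, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return List with `U` (for sample `x`), `p` and `method`
#'   (`"exact"`/`"normal"`).
#' @export
ratio_shift_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (min(n1, n2) <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}
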