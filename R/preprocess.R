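#' Construct a protein quantification table
#'
#' Raw proteomics quantification prior to the retention filter: abundances may
#' contain missing values and each protein carries the number of detected
#' peptide ratios supporting it.
#'
#' @param abundances Numeric matrix, proteins x samples (may contain `NA`).
#' @param peptide_counts Integer vector, one count per protein row.
#' @param is_log Whether abundances are on log scale.
#' @return A `protein_quant_table`.
#' @export
protein_quant_table <- function(abundances, peptide_counts, is_log = TRUE) {
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop("abundances need dimnames")
  if (length(peptide_counts) != nrow(abundances))
    stop("peptide_counts must align to protein rows")
  if (any(peptide_counts < 0) || any(peptide_counts != round(peptide_counts)))
    stop("peptide_counts must be non-negative integers")
  structure(list(feature_ids = rownames(abundances),
                 sample_ids = colnames(abundances),
                 abundances = abundances,
                 peptide_counts = as.integer(peptide_counts),
                 is_log = isTRUE(is_log)),
            class = "protein_quant_table")
}

#' Proteomics retention filter
#'
#' Retains proteins supported by at least `min_peptides` detected peptide
#' ratios and, when `require_complete`, quantified in every sample (no
#' missing values). This is the stringency criterion applied before any
#' integrative analysis.
#'
#' @param raw A [protein_quant_table()].
#' @param min_peptides Minimum detected peptide ratios (default 3).
#' @param require_complete Drop proteins with any missing abundance.
#' @return An [omic_matrix()] with layer `"protein"`.
#' @export
filter_proteins <- function(raw, min_peptides = 3, require_complete = TRUE) {
  stopifnot(inherits(raw, "protein_quant_table"))
  keep <- raw$peptide_counts >= min_peptides
  if (require_complete) keep <- keep & rowSums(is.na(raw$abundances)) == 0
  message(sprintf("filter_proteins: %d of %d proteins retained", sum(keep),
                  length(keep)))
  if (!any(keep)) warning("no proteins pass the retention filter")
  omic_matrix(raw$abundances[keep, , drop = FALSE], "protein",
              feature_ids = raw$feature_ids[keep],
              sample_ids = raw$sample_ids, is_log = raw$is_log)
}

#' Log-transform and z-score an omic layer
#'
#' Applies `log2(x + pseudocount)` when the layer is on linear scale, then
#' scales every feature to mean 0 and standard deviation 1. The population
#' (divide by n) standard deviation is used so results are exactly
#' reproducible and idempotent. Constant features become all-zero with a
#' warning.
#'
#' @param matrix An [omic_matrix()] without missing values.
#' @param pseudocount Added before the log for linear-scale input (default 1).
#' @return An [omic_matrix()] with `is_log = TRUE` and standardized rows.
#' @export
log_and_zscore <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "omic_matrix"))
  v <- matrix$values
  if (anyNA(v)) stop("missing values present; apply the retention filter first")
  if (!matrix$is_log) {
    if (any(v < 0)) stop("negative values on linear scale")
    v <- log2(v + pseudocount)
  }
  z <- zscore_rows(v, warn_constant = TRUE)
  omic_matrix(z, matrix$layer_name, is_log = TRUE)
}

#' Align matched transcript-protein pairs
#'
#' Forms one row per gene product measured in both layers (optionally through
#' an id map translating protein ids to gene ids). Both blocks are
#' log2-transformed if needed and centered per pair across samples, the
#' normalization under which pairwise correlations and protein/mRNA
#' log-ratios are computed.
#'
#' @param mrna,protein [omic_matrix()] layers on a shared sample set (use
#'   [align_cohort()] first).
#' @param id_map Optional named character vector mapping protein feature ids
#'   to mRNA feature ids.
#' @param pseudocount Pseudocount for linear-scale input.
#' @return A `matched_pair_table`: list with `pair_ids`, `sample_ids`, and
#'   pair-by-sample matrices `mrna_values`, `protein_values` (centered log2).
#' @export
match_pairs <- function(mrna, protein, id_map = NULL, pseudocount = 1) {
  stopifnot(inherits(mrna, "omic_matrix"), inherits(protein, "omic_matrix"))
  if (!identical(mrna$sample_ids, protein$sample_ids))
    stop("layers must share an identical sample order; run align_cohort first")
  prot_ids <- protein$feature_ids
  if (!is.null(id_map)) {
    hit <- prot_ids %in% names(id_map)
    prot_ids[hit] <- unname(id_map[prot_ids[hit]])
  }
  common <- intersect(mrna$feature_ids, prot_ids)
  if (!length(common)) stop("no gene products shared between the two layers")
  to_log <- function(m) {
    v <- m$values
    if (!m$is_log) {
      if (any(v < 0)) stop("negative values on linear scale")
      v <- log2(v + pseudocount)
    }
    v
  }
  mv <- to_log(mrna)[common, , drop = FALSE]
  pv <- to_log(protein)[match(common, prot_ids), , drop = FALSE]
  if (anyNA(mv) || anyNA(pv)) stop("matched pairs must be free of missing values")
  mv <- mv - rowMeans(mv)
  pv <- pv - rowMeans(pv)
  rownames(pv) <- common
  structure(list(pair_ids = common, sample_ids = mrna$sample_ids,
                 mrna_values = mv, protein_values = pv),
            class = "matched_pair_table")
}

#' @export
print.matched_pair_table <- function(x, ...) {
  cat(sprintf("matched_pair_table: %d pairs x %d samples\n",
              length(x$pair_ids), length(x$sample_ids)))
  invisible(x)
}
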