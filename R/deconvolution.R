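#' Estimate cell-type fractions by non-negative least squares
#'
#' Regresses each bulk sample (linear abundance scale; log-scale layers are
#' de-logged internally) on the signature-matrix profiles over the shared
#' features using non-negative least squares, then normalizes the
#' coefficients to sum to 1 (relative fractions). The per-sample residual
#' norm is recorded.
#'
#' @param matrix [omic_matrix()] bulk expression.
#' @param sig A [signature_matrix()] (>= 5 shared features; must be full
#'   column rank over the shared features).
#' @return A `deconvolution_result`: `fractions` (samples x cell types, rows
#'   sum to 1), `residuals` (per-sample residual norm).
#' @export
estimate_fractions <- function(matrix, sig) {
  stopifnot(inherits(matrix, "omic_matrix"), inherits(sig, "signature_matrix"))
  shared <- intersect(matrix$feature_ids, sig$feature_ids)
  if (length(shared) < 5) stop("fewer than 5 features shared with the signature matrix")
  S <- sig$profiles[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S)) {
    cm <- stats::cor(S)
    coll <- which(abs(cm) > 1 - 1e-8 & upper.tri(cm), arr.ind = TRUE)
    types <- if (nrow(coll)) {
      unique(c(sig$cell_types[coll[, 1]], sig$cell_types[coll[, 2]]))
    } else sig$cell_types
    stop("signature matrix is rank-deficient; collinear cell types: ",
         paste(types, collapse = ", "))
  }
  X <- matrix$values[shared, , drop = FALSE]
  if (matrix$is_log) X <- 2^X
  n <- ncol(X)
  fr <- matrix(NA_real_, n, ncol(S),
               dimnames = list(matrix$sample_ids, sig$cell_types))
  resid <- numeric(n)
  for (j in seq_len(n)) {
    fit <- pracma::lsqnonneg(S, X[, j])
    coefs <- fit$x
    if (sum(coefs) == 0) {
      warning("sample ", matrix$sample_ids[j], ": all-zero fit; uniform fractions")
      coefs <- rep(1, ncol(S))
    }
    fr[j, ] <- coefs / sum(coefs)
    resid[j] <- sqrt(sum((X[, j] - S %*% fit$x)^2))
  }
  structure(list(fractions = fr,
                 residuals = stats::setNames(resid, matrix$sample_ids)),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution_result (nnls): %d samples x %d cell types\n",
              nrow(x$fractions), ncol(x$fractions)))
  print(round(colMeans(x$fractions), 3))
  invisible(x)
}

#' Group contrasts of estimated cell-type fractions
#'
#' Mann-Whitney rank-sum test per cell type between the two groups (via
#' [ratio_shift_test()]), Benjamini-Hochberg adjusted across cell types.
#'
#' @param result An [estimate_fractions()] result.
#' @param labels Group label per sample (2 groups).
#' @return Data frame: `cell_type`, `mean1`, `mean2`, `U`, `p`, `q`.
#' @export
compare_fractions <- function(result, labels) {
  stopifnot(inherits(result, "deconvolution_result"))
  g <- two_groups(labels, nrow(result$fractions))
  rows <- lapply(colnames(result$fractions), function(ct) {
    f <- result$fractions[, ct]
    mw <- ratio_shift_test(f[g$idx1], f[g$idx2])
    data.frame(cell_type = ct, mean1 = mean(f[g$idx1]), mean2 = mean(f[g$idx2]),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab
}
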